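#' Pipeline settings
#'
#' Collects every tunable of the screening pipeline with the defaults
#' used throughout: AHI threshold 15 events/hour, feature extraction
#' restricted to AHI <= 10 / >= 20, Welch segments of 1024 samples with
#' 50% overlap, indirect bispectra to lag 128 with Parzen window,
#' SNR screening at 10 dB, reduction per [reduction_control()], forests
#' of `n_trees` trees scored over 3 and finalised over 5 repetitions
#' with the 0.7 floor / 2% selection window.
#'
#' @param threshold AHI severity threshold, events/hour.
#' @param fe_bounds feature-extraction AHI bounds `(low, high)`.
#' @param train_frac training fraction per severity group (when the
#'   manifest does not fix the split).
#' @param welch_window,welch_overlap Welch segment length (samples) and
#'   overlap fraction.
#' @param bis_max_lag,bis_record,bis_max_records indirect-bispectrum
#'   cumulant lag, record length and record cap.
#' @param snr_db,clip_frac quality-screening thresholds.
#' @param segment [segment_control()] settings.
#' @param reduction [reduction_control()] settings.
#' @param min_bw minimum discovered-band width, Hz.
#' @param max_extra_bands discovered bands kept per maneuver/phase.
#' @param n_trees trees per random forest (1200).
#' @param reps_score,reps_final repetitions in the scoring and final
#'   selection stages.
#' @param min_metric per-repetition floor on every OOB metric.
#' @param window minimum accuracy selection window.
#' @param exclusive_pairs feature pairs never allowed to co-occur in a
#'   combination.
#' @return list of settings.
#' @export
awakeosa_control <- function(threshold = 15, fe_bounds = c(10, 20),
                             train_frac = 113 / 199,
                             welch_window = 1024, welch_overlap = 0.5,
                             bis_max_lag = 128, bis_record = 1024,
                             bis_max_records = 8,
                             snr_db = 10, clip_frac = 0.01,
                             segment = segment_control(),
                             reduction = reduction_control(),
                             min_bw = 100, max_extra_bands = 2,
                             n_trees = 1200, reps_score = 3, reps_final = 5,
                             min_metric = 0.7, window = 0.02,
                             exclusive_pairs = NULL) {
  as.list(environment())
}

#' Per-subject cycle-aggregated spectral summaries
#'
#' Segments one subject's mouth and nose recordings into breath phases,
#' screens quality, and computes per maneuver/phase: the cycle-averaged
#' Welch PSD (linear power averaged across clean cycles), the indirect
#' bispectrum estimated on records pooled across clean cycles (cumulant
#' averaging is the aggregation), and cycle-averaged fractal features.
#'
#' @param recordings named list `mouth`/`nose`, each with `samples`,
#'   `sample_rate` and optionally `boundaries` (ground-truth or manual
#'   segmentation override).
#' @param control [awakeosa_control()] settings.
#' @return named list `mouth_inspiration`, ... each with `psd`, `bis`,
#'   `fractal`; attribute `include` says whether the subject passes the
#'   two-clean-cycles rule for every available maneuver.
#' @export
compute_subject_spectra <- function(recordings, control = awakeosa_control()) {
  out <- list()
  include <- TRUE
  for (mv in names(recordings)) {
    rec <- recordings[[mv]]
    seg <- segment_phases(rec$samples, rec$sample_rate,
                          control = control$segment,
                          boundaries = rec$boundaries)
    phases <- screen_quality(seg$phases, seg$silent,
                             snr_db = control$snr_db,
                             clip_frac = control$clip_frac)
    include <- include && isTRUE(attr(phases, "include"))
    for (ph in c("inspiration", "expiration")) {
      clean <- Filter(function(p) p$phase == ph && p$quality == "clean",
                      phases)
      if (length(clean) < 2L) next
      psds <- lapply(clean, function(p)
        welch_psd(p$samples, p$sample_rate, window = control$welch_window,
                  overlap = control$welch_overlap))
      avg <- psds[[1L]]
      avg$power <- Reduce(`+`, lapply(psds, `[[`, "power")) / length(psds)
      pooled <- unlist(lapply(clean, `[[`, "samples"))
      bis <- indirect_bispectrum(pooled, clean[[1L]]$sample_rate,
                                 max_lag = control$bis_max_lag,
                                 record = control$bis_record,
                                 max_records = control$bis_max_records)
      fr <- rowMeans(vapply(clean, function(p) fractal_features(p$samples),
                            c(katz = 0, higuchi = 0, hurst = 0)), na.rm = TRUE)
      out[[paste0(mv, "_", ph)]] <- list(psd = avg, bis = bis,
                                         fractal = as.list(fr))
    }
  }
  attr(out, "include") <- include
  out
}

#' @keywords internal
cohort_recordings <- function(cohort, subject_id) {
  audio <- attr(cohort, "audio")
  i <- match(subject_id, cohort$subject_id)
  out <- list()
  for (mv in c("mouth", "nose")) {
    if (!is.null(audio)) {
      out[[mv]] <- audio[[subject_id]][[mv]]
    } else {
      path <- cohort[[paste0(mv, "_wav")]][i]
      if (is.na(path) || !nzchar(path)) next
      a <- load_audio(path)
      out[[mv]] <- list(samples = a$samples, sample_rate = a$sample_rate,
                        boundaries = NULL)
    }
  }
  out
}

#' Fit the wakefulness OSA screening ensemble
#'
#' Runs the full pipeline on a cohort: breath-phase segmentation and
#' quality screening; cycle-aggregated Welch PSD, indirect bispectrum
#' and fractal features; discriminative-band discovery by 95%-CI
#' non-overlap on the feature-extraction groups; feature-matrix
#' assembly and \[0, 1\] scaling (training rows only); per
#' anthropometric subset, feature reduction (significance ->
#' robustness -> redundancy -> effect size), boxplot outlier fences,
#' 3-/4-feature combination search with repeated out-of-bag random
#' forest validation, and final-combination selection; and the
#' sensitivity/specificity-weighted voting ensemble, evaluated on the
#' training (out-of-bag votes) and blind-test sets.
#'
#' @param cohort an `osa_cohort` with audio (file paths or in-memory
#'   attribute), e.g. from [load_manifest()] or [generate_cohort()].
#' @param control settings from [awakeosa_control()].
#' @param seed integer seed driving every stochastic step.
#' @param subsets subset specification data frame ([subset_specs()]).
#' @param quiet suppress progress messages.
#' @return object of class `awakeosa`; see [predict.awakeosa()],
#'   [summary.awakeosa()], [plot.awakeosa()].
#' @export
awakeosa <- function(cohort, control = awakeosa_control(), seed = 1,
                     subsets = subset_specs(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)

  say("segmenting and summarising ", nrow(cohort), " subjects ...")
  spectra <- list()
  excluded <- character()
  for (s in cohort$subject_id) {
    cache <- compute_subject_spectra(cohort_recordings(cohort, s), control)
    if (!isTRUE(attr(cache, "include"))) {
      excluded <- c(excluded, s)
      next
    }
    spectra[[s]] <- cache
  }
  if (length(excluded)) {
    warning(length(excluded), " subject(s) excluded by quality screening: ",
            paste(utils::head(excluded, 5), collapse = ", "))
    cohort <- cohort[!cohort$subject_id %in% excluded, , drop = FALSE]
  }

  cohort <- split_cohort(cohort, threshold = control$threshold,
                         fe_bounds = control$fe_bounds,
                         train_frac = control$train_frac, seed = seed)
  fe_ids <- cohort$subject_id[cohort$feature_extraction]
  fe_lab <- droplevels(cohort$group[cohort$feature_extraction])

  say("discovering discriminative bands ...")
  extra <- list()
  for (mv in c("mouth", "nose")) for (ph in c("inspiration", "expiration")) {
    key <- paste0(mv, "_", ph)
    have <- fe_ids[vapply(fe_ids, function(s) !is.null(spectra[[s]][[key]]),
                          logical(1))]
    if (length(have) < 4L) next
    pw <- t(vapply(have, function(s) spectra[[s]][[key]]$psd$power,
                   spectra[[have[1L]]][[key]]$psd$power))
    fr <- spectra[[have[1L]]][[key]]$psd$freq
    lab <- cohort$group[match(have, cohort$subject_id)]
    if (min(table(lab)) < 2L) next
    ga <- group_average_spectrum(pw[lab == "non_osa", , drop = FALSE], fr)
    gb <- group_average_spectrum(pw[lab == "osa", , drop = FALSE], fr)
    bands <- find_discriminative_bands(ga, gb, min_bw = control$min_bw)
    if (nrow(bands)) {
      bands <- utils::head(bands[order(bands$f_lo), , drop = FALSE],
                           control$max_extra_bands)
      bands$maneuver <- mv
      bands$phase <- ph
      extra[[key]] <- bands
    }
  }
  extra_bands <- if (length(extra)) do.call(rbind, extra) else NULL

  nyq <- spectra[[1L]][[1L]]$psd$params$sample_rate / 2
  catalog <- feature_catalog(extra_bands = extra_bands, nyquist = nyq)
  say("computing ", nrow(catalog), " features ...")
  raw <- build_feature_matrix(spectra, catalog)

  train_ids <- cohort$subject_id[cohort$split == "train"]
  test_ids <- cohort$subject_id[cohort$split == "test"]
  scaled <- scale_unit_interval(raw, train_ids)

  # neck circumference as an auxiliary classification feature, scaled
  # on the training rows like every other feature
  nc_raw <- stats::setNames(cohort$nc, cohort$subject_id)
  nc_rng <- range(nc_raw[train_ids])
  nc_sc <- pmin(1, pmax(0, (nc_raw - nc_rng[1]) / diff(nc_rng)))
  values <- cbind(scaled$values,
                  nc = nc_sc[rownames(scaled$values)])

  membership <- build_subsets(cohort, subsets)
  models <- list()
  reductions <- list()
  for (k in seq_len(nrow(subsets))) {
    spec_k <- subsets[k, ]
    say("subset ", spec_k$name, ": reducing and training ...")
    mem <- membership[[spec_k$name]]$members
    fe_k <- intersect(fe_ids, mem)
    lab_fe <- droplevels(cohort$group[match(fe_k, cohort$subject_id)])
    if (nlevels(lab_fe) < 2L || min(table(lab_fe)) < 10L) {
      warning("subset ", spec_k$name, " skipped: feature-extraction groups ",
              "too small")
      next
    }
    red_ctrl <- control$reduction
    # robustness subgroups cannot exceed the smaller severity group
    red_ctrl$group_size <- min(red_ctrl$group_size, min(table(lab_fe)))
    red <- run_reduction(values[fe_k, colnames(scaled$values), drop = FALSE],
                         lab_fe, control = red_ctrl,
                         seed = seed + 100 * k)
    reductions[[spec_k$name]] <- red
    if (length(red$selected) < 3L) {
      warning("subset ", spec_k$name, " skipped: fewer than 3 features ",
              "survive reduction")
      next
    }
    tr_k <- intersect(train_ids, mem)
    lab_tr <- droplevels(cohort$group[match(tr_k, cohort$subject_id)])
    cand <- c(red$selected, if (spec_k$include_nc) "nc")
    fences <- outlier_fences(values[tr_k, cand, drop = FALSE], lab_tr)
    fenced <- apply_fences(values[, cand, drop = FALSE], fences)
    combos <- enumerate_combinations(red$selected,
                                     include_nc = spec_k$include_nc,
                                     exclusive_pairs = control$exclusive_pairs)
    sc <- score_combinations(fenced[tr_k, , drop = FALSE], lab_tr, combos,
                             reps = control$reps_score,
                             num_trees = control$n_trees,
                             min_metric = control$min_metric,
                             window = control$window,
                             seed = seed + 100 * k)
    if (!length(sc$shortlist)) {
      warning("subset ", spec_k$name, " skipped: no combination reaches the ",
              control$min_metric, " floor")
      next
    }
    models[[spec_k$name]] <- select_final_combination(
      fenced[tr_k, , drop = FALSE], lab_tr, sc$shortlist,
      spec = spec_k, fences = fences, reps = control$reps_final,
      num_trees = control$n_trees, seed = seed + 100 * k + 50)
  }
  if (!length(models))
    stop("no subset produced a usable classifier")

  say("voting ...")
  dec_train <- classify_cohort(models, values[train_ids, , drop = FALSE],
                               use_oob = TRUE)
  dec_test <- classify_cohort(models, values[test_ids, , drop = FALSE],
                              use_oob = FALSE)
  truth <- stats::setNames(as.character(cohort$group), cohort$subject_id)
  structure(list(
    models = models,
    scaling = list(min = c(scaled$scaling$min, nc = nc_rng[1]),
                   max = c(scaled$scaling$max, nc = nc_rng[2])),
    catalog = catalog,
    extra_bands = extra_bands,
    reductions = reductions,
    values = values,
    cohort = cohort[, setdiff(names(cohort), c("mouth_wav", "nose_wav"))],
    train_ids = train_ids, test_ids = test_ids,
    decisions_train = dec_train,
    decisions_test = dec_test,
    metrics_train = evaluate_decisions(dec_train, truth[train_ids]),
    metrics_test = evaluate_decisions(dec_test, truth[test_ids]),
    control = control, seed = seed
  ), class = "awakeosa")
}

#' Screen new subjects with a fitted ensemble
#'
#' `newdata` may be an `osa_cohort` with audio (features are recomputed
#' with the fitted catalog and scaled with the training parameters) or
#' a ready-made scaled feature matrix with subject-id rownames.
#'
#' @param object a fitted `awakeosa` model.
#' @param newdata cohort or feature matrix; omitted = the fitted blind
#'   test set.
#' @param ... unused.
#' @return decision data frame (see [classify_cohort()]).
#' @export
predict.awakeosa <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(object$decisions_test)
  if (is.matrix(newdata))
    return(classify_cohort(object$models, newdata, use_oob = FALSE))
  spectra <- list()
  for (s in newdata$subject_id)
    spectra[[s]] <- compute_subject_spectra(cohort_recordings(newdata, s),
                                            object$control)
  raw <- build_feature_matrix(spectra, object$catalog)
  values <- apply_scaling(raw$values, object$scaling)
  rng <- c(object$scaling$min["nc"], object$scaling$max["nc"])
  nc <- pmin(1, pmax(0, (newdata$nc - rng[1]) / (rng[2] - rng[1])))
  values <- cbind(values, nc = nc)
  classify_cohort(object$models, values, use_oob = FALSE)
}

#' @export
print.awakeosa <- function(x, ...) {
  cat("Wakefulness OSA screening ensemble (", length(x$models),
      " anthropometric subset classifiers)\n", sep = "")
  cat("  cohort: ", length(x$train_ids), " training / ",
      length(x$test_ids), " blind-test subjects\n", sep = "")
  cat(sprintf("  training (OOB votes): accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$metrics_train["accuracy"], x$metrics_train["sensitivity"],
              x$metrics_train["specificity"]))
  cat(sprintf("  blind test:           accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$metrics_test["accuracy"], x$metrics_test["sensitivity"],
              x$metrics_test["specificity"]))
  invisible(x)
}

#' @export
summary.awakeosa <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$models, function(m) data.frame(
    subset = m$name,
    combination = paste(m$combination, collapse = " + "),
    oob_accuracy = m$oob_accuracy,
    oob_sensitivity = m$oob_sensitivity,
    oob_specificity = m$oob_specificity,
    row.names = NULL)))
  out <- list(subsets = tab, metrics_train = object$metrics_train,
              metrics_test = object$metrics_test)
  class(out) <- "summary.awakeosa"
  out
}

#' @export
print.summary.awakeosa <- function(x, ...) {
  cat("Per-subset classifiers:\n")
  print(x$subsets, digits = 3)
  cat("\nVoted metrics:\n")
  print(rbind(train_oob = x$metrics_train, blind_test = x$metrics_test),
        digits = 3)
  invisible(x)
}

#' Decision scatter of a fitted ensemble
#'
#' Plots the final weighted decision `d` per subject, coloured by true
#' severity group, for the training (out-of-bag) and blind-test sets;
#' the dashed line is the decision boundary `d = 0`, the dotted lines
#' the high-confidence levels at +/- 0.7.
#'
#' @param x a fitted `awakeosa` model.
#' @param ... unused.
#' @export
plot.awakeosa <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  truth <- stats::setNames(as.character(x$cohort$group), x$cohort$subject_id)
  panel <- function(dec, ids, main) {
    col <- ifelse(truth[dec$subject_id] == "osa", "red3", "dodgerblue3")
    graphics::plot(seq_len(nrow(dec)), dec$d, col = col, pch = 19,
                   ylim = c(-1, 1), xlab = "subject", ylab = "decision d",
                   main = main)
    graphics::abline(h = 0, lty = 2)
    graphics::abline(h = c(-0.7, 0.7), lty = 3, col = "grey50")
  }
  panel(x$decisions_train, x$train_ids, "training (out-of-bag votes)")
  panel(x$decisions_test, x$test_ids, "blind test")
  invisible(x)
}
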