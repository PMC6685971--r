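#' Read and validate a cohort manifest
#'
#' The manifest is a CSV with header
#' `subject_id,ahi,age,sex,bmi,nc,mps,mouth_wav,nose_wav[,split]`:
#' one row per participant carrying the apnea/hypopnea index (AHI,
#' events/hour), age (years), sex (`male`/`female`), body mass index
#' (kg/m2), neck circumference (cm), Mallampati score (1-4) and paths to
#' the mouth- and nose-breathing WAV recordings. An optional `split`
#' column (`train`/`test`) pins the train/test partition.
#'
#' Severity groups follow the clinical threshold: `osa` when
#' `ahi >= threshold` (default 15 events/hour), `non_osa` otherwise.
#'
#' @param path path to the manifest CSV.
#' @param threshold AHI severity threshold in events/hour.
#' @return an `osa_cohort`: a data frame with the manifest columns plus
#'   `group` (factor `non_osa`/`osa`) and `split`
#'   (`train`/`test`/`unassigned`). Group counts are reported via
#'   `message()`.
#' @export
load_manifest <- function(path, threshold = 15) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("manifest is not readable as CSV: ", conditionMessage(e))
  )
  required <- c("subject_id", "ahi", "age", "sex", "bmi", "nc", "mps",
                "mouth_wav", "nose_wav")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("manifest is empty: ", path)
  if (!"split" %in% names(df)) df$split <- "unassigned"
  df$split[is.na(df$split) | df$split == ""] <- "unassigned"
  validate_cohort_fields(df)
  as_osa_cohort(df, threshold = threshold)
}

#' @keywords internal
validate_cohort_fields <- function(df) {
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop("invalid ", what, " in manifest row(s) ",
           paste(rows, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df$subject_id)
  if (any(dup))
    stop("duplicate subject_id in manifest row(s) ",
         paste(which(dup), collapse = ", "), ": ",
         paste(unique(df$subject_id[dup]), collapse = ", "), call. = FALSE)
  bad(!is.finite(df$ahi) | df$ahi < 0, "ahi (must be >= 0)")
  bad(!is.finite(df$age) | df$age <= 0, "age (must be > 0)")
  bad(!df$sex %in% c("male", "female"), "sex (must be male/female)")
  bad(!is.finite(df$bmi) | df$bmi <= 0, "bmi (must be > 0)")
  bad(!is.finite(df$nc) | df$nc <= 0, "nc (must be > 0)")
  bad(!df$mps %in% 1:4, "mps (must be 1, 2, 3 or 4)")
  bad(!df$split %in% c("train", "test", "unassigned"), "split")
  invisible(df)
}

#' @keywords internal
as_osa_cohort <- function(df, threshold = 15) {
  df$group <- factor(ifelse(df$ahi >= threshold, "osa", "non_osa"),
                     levels = c("non_osa", "osa"))
  attr(df, "threshold") <- threshold
  class(df) <- c("osa_cohort", "data.frame")
  message("cohort: ", sum(df$group == "non_osa"), " non-OSA, ",
          sum(df$group == "osa"), " OSA (AHI threshold ", threshold, ")")
  df
}

#' Segmentation settings
#'
#' Short-time-energy segmentation of a breathing recording into
#' alternating inspiratory/expiratory bursts plus a silent (breath-hold)
#' reference period. Frames of `frame_s` seconds are advanced by
#' `hop_s`; the activity threshold is the midpoint (in dB) between the
#' median energies of the quiet and loud frame populations.
#'
#' @param frame_s analysis frame length, seconds.
#' @param hop_s frame hop, seconds.
#' @param min_burst_s bursts shorter than this are discarded, seconds.
#' @param merge_gap_s active runs separated by less than this are merged.
#' @param min_silent_s minimum usable silent-period length, seconds.
#' @return list of settings.
#' @export
segment_control <- function(frame_s = 0.05, hop_s = 0.01, min_burst_s = 0.25,
                            merge_gap_s = 0.1, min_silent_s = 0.3) {
  list(frame_s = frame_s, hop_s = hop_s, min_burst_s = min_burst_s,
       merge_gap_s = merge_gap_s, min_silent_s = min_silent_s)
}

#' Segment a recording into breath phases and a silent period
#'
#' The recording protocol is five deep breath cycles through one route
#' (nose or mouth) followed by a breath hold. Bursts of short-time
#' energy are detected against an adaptive threshold; burst labels
#' alternate starting with inspiration (the protocol marks the first
#' inspiratory phase), and the longest sub-threshold stretch is taken as
#' the silent period. Manually supplied boundaries override detection.
#'
#' @param samples amplitude vector.
#' @param sample_rate sampling rate, Hz (>= 4800 so the 2100-2400 Hz
#'   band is resolved).
#' @param control settings from [segment_control()].
#' @param boundaries optional data frame `phase,cycle,start_s,end_s`
#'   overriding automatic detection (e.g. from a manual-annotation CSV).
#' @return list with `phases` (list of breath-phase signals: `samples`,
#'   `sample_rate`, `phase`, `cycle`, `start_s`, `end_s`, `quality`),
#'   `silent` (list `samples,start_s,end_s` or `NULL` with a warning
#'   flag), and `boundaries` (data frame of detected phase boundaries).
#' @export
segment_phases <- function(samples, sample_rate, control = segment_control(),
                           boundaries = NULL) {
  if (sample_rate < 4800)
    stop("sample_rate must be >= 4800 Hz to resolve the 2100-2400 Hz band")

  if (!is.null(boundaries)) {
    runs <- data.frame(start_s = boundaries$start_s, end_s = boundaries$end_s,
                       phase = boundaries$phase, cycle = boundaries$cycle)
  } else {
    frame <- max(1L, round(control$frame_s * sample_rate))
    hop <- max(1L, round(control$hop_s * sample_rate))
    n_frames <- max(0L, (length(samples) - frame) %/% hop + 1L)
    if (n_frames < 3L || all(samples == 0)) {
      warning("no breath burst found; returning zero phases")
      return(list(phases = list(), silent = NULL,
                  boundaries = data.frame(phase = character(), cycle = integer(),
                                          start_s = numeric(), end_s = numeric())))
    }
    starts <- (seq_len(n_frames) - 1L) * hop + 1L
    e <- vapply(starts, function(s) mean(samples[s:(s + frame - 1L)]^2), 0)
    e_db <- 10 * log10(e + .Machine$double.xmin)
    thr <- (stats::quantile(e_db, 0.95, names = FALSE) +
            stats::quantile(e_db, 0.05, names = FALSE)) / 2
    active <- e_db > thr
    # refine: midpoint of the medians of the two frame populations
    if (any(active) && any(!active)) {
      thr <- (stats::median(e_db[active]) + stats::median(e_db[!active])) / 2
      active <- e_db > thr
    }
    if (!any(active)) {
      warning("no breath burst found; returning zero phases")
      return(list(phases = list(), silent = NULL,
                  boundaries = data.frame(phase = character(), cycle = integer(),
                                          start_s = numeric(), end_s = numeric())))
    }
    r <- rle(active)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    seg <- data.frame(start_f = starts_i, end_f = ends_i, active = r$values)
    # merge active runs separated by short gaps
    gap_frames <- control$merge_gap_s / control$hop_s
    act <- seg[seg$active, , drop = FALSE]
    if (nrow(act) > 1L) {
      keep <- rep(TRUE, nrow(act))
      for (i in 2:nrow(act)) {
        if (act$start_f[i] - act$end_f[i - 1L] <= gap_frames) {
          act$end_f[i - 1L] <- act$end_f[i]
          act$start_f[i] <- act$start_f[i - 1L]
          keep[i - 1L] <- FALSE
        }
      }
      act <- act[keep, , drop = FALSE]
    }
    frame_time <- function(f, edge) ((f - 1L) * hop + if (edge == "end") frame else 1L) / sample_rate
    runs <- data.frame(start_s = frame_time(act$start_f, "start"),
                       end_s = frame_time(act$end_f, "end"))
    runs <- runs[runs$end_s - runs$start_s >= control$min_burst_s, , drop = FALSE]
    if (nrow(runs) == 0L) {
      warning("no breath burst found; returning zero phases")
      return(list(phases = list(), silent = NULL,
                  boundaries = data.frame(phase = character(), cycle = integer(),
                                          start_s = numeric(), end_s = numeric())))
    }
    runs$phase <- rep(c("inspiration", "expiration"), length.out = nrow(runs))
    runs$cycle <- (seq_len(nrow(runs)) + 1L) %/% 2L
  }

  clip <- function(s) max(1L, min(length(samples), round(s * sample_rate)))
  phases <- lapply(seq_len(nrow(runs)), function(i) {
    idx <- clip(runs$start_s[i]):clip(runs$end_s[i])
    list(samples = samples[idx], sample_rate = sample_rate,
         phase = runs$phase[i], cycle = runs$cycle[i],
         start_s = runs$start_s[i], end_s = runs$end_s[i],
         quality = "clean", reason = NA_character_)
  })

  # silent period: longest stretch not covered by any burst
  marks <- sort(c(0, runs$start_s, runs$end_s, length(samples) / sample_rate))
  gaps <- data.frame(start_s = marks[seq(1, length(marks), 2)],
                     end_s = marks[seq(2, length(marks), 2)])
  gaps$len <- gaps$end_s - gaps$start_s
  silent <- NULL
  if (nrow(gaps) && max(gaps$len) >= control$min_silent_s) {
    g <- gaps[which.max(gaps$len), ]
    silent <- list(samples = samples[clip(g$start_s):clip(g$end_s)],
                   sample_rate = sample_rate,
                   start_s = g$start_s, end_s = g$end_s)
  } else {
    warning("no silent period found; SNR screening will be skipped")
  }
  list(phases = phases, silent = silent,
       boundaries = runs[, c("phase", "cycle", "start_s", "end_s")])
}

#' Quality-screen segmented breath phases
#'
#' A phase is rejected when its signal-to-noise ratio against the silent
#' (breath-hold) period falls below `snr_db`, or when more than
#' `clip_frac` of its samples sit at full scale. A subject's recording
#' of one maneuver is usable only with at least two clean cycles per
#' phase type (the "at least two clean breathing cycles" inclusion
#' rule); the result carries an `include` flag.
#'
#' @param phases list of breath-phase signals from [segment_phases()].
#' @param silent silent-period list from [segment_phases()], or `NULL`
#'   (SNR check skipped with a warning).
#' @param snr_db rejection threshold in dB.
#' @param clip_frac maximum tolerated fraction of clipped samples.
#' @param full_scale amplitude treated as full scale (1 for WAV input).
#' @return `phases` with `quality`/`reason` set, plus attributes
#'   `include` (logical) and `n_clean` (clean cycles per phase type).
#' @export
screen_quality <- function(phases, silent, snr_db = 10, clip_frac = 0.01,
                           full_scale = 1) {
  if (is.null(silent)) warning("no silent period: SNR screening skipped")
  noise_pow <- if (is.null(silent)) NA_real_ else mean(silent$samples^2)
  phases <- lapply(phases, function(p) {
    clipped <- mean(abs(p$samples) >= 0.999 * full_scale)
    if (clipped > clip_frac) {
      p$quality <- "rejected"; p$reason <- "clipping"
      return(p)
    }
    if (!is.na(noise_pow) && noise_pow > 0) {
      snr <- 10 * log10(mean(p$samples^2) / noise_pow)
      if (snr < snr_db) {
        p$quality <- "rejected"; p$reason <- "low_snr"
        return(p)
      }
    }
    p$quality <- "clean"; p$reason <- NA_character_
    p
  })
  n_clean <- table(factor(vapply(Filter(function(p) p$quality == "clean", phases),
                                 function(p) p$phase, ""),
                          levels = c("inspiration", "expiration")))
  attr(phases, "n_clean") <- n_clean
  attr(phases, "include") <- all(n_clean >= 2L)
  phases
}

#' Partition a cohort into training, blind-test and feature-extraction sets
#'
#' The train/test partition honours an explicit `split` column when one
#' is present; otherwise it is drawn at random, stratified by severity
#' group, with `train_frac` of each group assigned to training. Within
#' the training set, the feature-extraction subset keeps only subjects
#' with unambiguous severity (`ahi <= fe_bounds[1]` or
#' `ahi >= fe_bounds[2]`); intermediate subjects stay in classifier
#' training but are excluded from feature extraction and reduction.
#'
#' @param cohort an `osa_cohort`.
#' @param threshold AHI severity threshold (events/hour).
#' @param fe_bounds length-2 numeric `(low, high)` with
#'   `low < threshold < high`.
#' @param train_frac fraction of each severity group assigned to
#'   training when no `split` column decides it.
#' @param seed integer seed for the stratified draw.
#' @return the cohort with `split` filled in and a logical
#'   `feature_extraction` column.
#' @export
split_cohort <- function(cohort, threshold = 15, fe_bounds = c(10, 20),
                         train_frac = 113 / 199, seed = 1) {
  stopifnot(fe_bounds[1] < threshold, threshold < fe_bounds[2])
  if (any(cohort$split == "unassigned")) {
    set.seed(seed)
    for (g in levels(cohort$group)) {
      idx <- which(cohort$group == g & cohort$split == "unassigned")
      n_tr <- round(length(idx) * train_frac)
      tr <- sample(idx, n_tr)
      cohort$split[tr] <- "train"
      cohort$split[setdiff(idx, tr)] <- "test"
    }
  }
  for (g in levels(cohort$group))
    if (!any(cohort$split == "train" & cohort$group == g))
      stop("severity group ", g, " has no training subjects")
  cohort$feature_extraction <- cohort$split == "train" &
    (cohort$ahi <= fe_bounds[1] | cohort$ahi >= fe_bounds[2])
  attr(cohort, "fe_bounds") <- fe_bounds
  cohort
}
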