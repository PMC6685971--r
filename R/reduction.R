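#' Vectorised Welch two-sample t-test p-values
#'
#' Unequal-variance (Welch) unpaired t-test applied column-wise.
#' Columns with fewer than 2 non-missing values in a group, or zero
#' variance in both groups, get `NA`.
#'
#' @param values numeric matrix (rows = subjects).
#' @param labels factor with two levels aligned to rows.
#' @return numeric vector of two-sided p-values per column.
#' @keywords internal
welch_t_pvalues <- function(values, labels) {
  g <- levels(labels)
  a <- values[labels == g[1L], , drop = FALSE]
  b <- values[labels == g[2L], , drop = FALSE]
  na <- colSums(!is.na(a)); nb <- colSums(!is.na(b))
  ma <- colMeans(a, na.rm = TRUE); mb <- colMeans(b, na.rm = TRUE)
  va <- apply(a, 2, stats::var, na.rm = TRUE)
  vb <- apply(b, 2, stats::var, na.rm = TRUE)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[na < 2 | nb < 2 | !is.finite(p)] <- NA_real_
  p
}

#' Significance filter
#'
#' Per-feature unpaired (Welch) t-test between the two severity groups;
#' features with `p > alpha` (default 0.05) are excluded. Degenerate
#' features (constant or too many missing values) are excluded with a
#' flag.
#'
#' @param values subjects x features numeric matrix.
#' @param labels two-level factor (`non_osa`/`osa`) aligned to rows.
#' @param alpha significance level.
#' @return list with `p_values` (named vector) and `survivors`
#'   (character vector of feature ids with `p <= alpha`).
#' @export
significance_filter <- function(values, labels, alpha = 0.05) {
  p <- welch_t_pvalues(values, labels)
  names(p) <- colnames(values)
  list(p_values = p, survivors = colnames(values)[!is.na(p) & p <= alpha])
}

#' Robustness scores by repeated small-group testing
#'
#' Each feature starts at score 0. Per round, each severity group is
#' randomly partitioned into subgroups of `group_size` (a shuffled
#' coverage pass; the last subgroup draws its members from the
#' remainder pool). For every cross-group pairing of subgroups and
#' every feature, the score gains one point iff the Welch t-test
#' between the paired subgroups has `p <= alpha` AND the Lilliefors
#' normality test holds (`p > alpha`) in both subgroups. After `rounds`
#' rounds, survivors are the features whose total exceeds
#' `frac * max(score)`.
#'
#' @inheritParams significance_filter
#' @param group_size subgroup size (15).
#' @param rounds number of rounds (20).
#' @param frac survivor threshold as a fraction of the maximum observed
#'   score.
#' @param seed integer seed.
#' @return list with `scores` (integer per feature), `max_score`
#'   (maximum observed), `survivors`.
#' @export
robustness_scores <- function(values, labels, group_size = 15, rounds = 20,
                              alpha = 0.05, frac = 0.6, seed = 1) {
  g <- levels(labels)
  idx <- lapply(g, function(l) which(labels == l))
  if (any(lengths(idx) < group_size))
    stop("severity group smaller than group_size (", group_size, ")")
  p_feat <- ncol(values)
  scores <- integer(p_feat)
  names(scores) <- colnames(values)
  if (rounds < 1L)
    return(list(scores = scores, max_score = 0L, survivors = character()))
  set.seed(seed)
  lillie_ok <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 5L || stats::sd(x) == 0) return(FALSE)
    nortest::lillie.test(x)$p.value > alpha
  }
  for (r in seq_len(rounds)) {
    subgroups <- lapply(idx, function(members) {
      perm <- sample(members)
      k <- length(members) %/% group_size
      sg <- lapply(seq_len(max(k - 1L, 0L)),
                   function(i) perm[((i - 1L) * group_size + 1L):(i * group_size)])
      pool <- perm[(max(k - 1L, 0L) * group_size + 1L):length(perm)]
      c(sg, list(sample(pool, group_size)))
    })
    normal <- lapply(subgroups, function(sgs) lapply(sgs, function(s)
      vapply(seq_len(p_feat), function(j) lillie_ok(values[s, j]), logical(1))))
    for (a in seq_along(subgroups[[1L]])) for (b in seq_along(subgroups[[2L]])) {
      sa <- subgroups[[1L]][[a]]
      sb <- subgroups[[2L]][[b]]
      p <- welch_t_pvalues(values[c(sa, sb), , drop = FALSE],
                           factor(rep(g, c(length(sa), length(sb))), levels = g))
      hit <- !is.na(p) & p <= alpha & normal[[1L]][[a]] & normal[[2L]][[b]]
      scores <- scores + hit
    }
  }
  max_score <- max(scores)
  list(scores = scores, max_score = max_score,
       survivors = names(scores)[scores > frac * max_score & scores > 0L])
}

#' Glass's delta effect size
#'
#' `(mean_OSA - mean_nonOSA) / SD_nonOSA`: the group-mean difference in
#' units of the control (non-OSA) group's standard deviation.
#'
#' @param x numeric feature values.
#' @param labels two-level factor (`non_osa` is the control group).
#' @return Glass's delta.
#' @export
glass_delta <- function(x, labels) {
  ctrl <- x[labels == "non_osa"]
  s <- stats::sd(ctrl, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("control-group SD is zero")
  (mean(x[labels == "osa"], na.rm = TRUE) - mean(ctrl, na.rm = TRUE)) / s
}

#' Single-feature SVM training performance
#' @keywords internal
svm_single_feature <- function(x, labels) {
  ok <- !is.na(x)
  d <- data.frame(y = labels[ok], x = x[ok])
  fit <- e1071::svm(y ~ x, data = d, kernel = "linear")
  pred <- stats::predict(fit, d)
  c(accuracy = mean(pred == d$y),
    sensitivity = mean(pred[d$y == "osa"] == "osa"),
    specificity = mean(pred[d$y == "non_osa"] == "non_osa"))
}

#' Redundancy filter
#'
#' Clusters the surviving features by transitive absolute correlation
#' `|r| >= corr_threshold` and keeps, per cluster, the single feature
#' with the best single-feature linear-SVM training accuracy
#' (sensitivity + specificity breaks ties, then feature id). Glass's
#' delta is reported for every kept feature.
#'
#' @inheritParams significance_filter
#' @param survivors character vector of candidate feature ids.
#' @param corr_threshold absolute-correlation threshold (0.9).
#' @return list with `kept` (feature ids), `clusters` (membership),
#'   `svm` (per-feature training metrics), `delta` (Glass's delta of
#'   kept features).
#' @export
redundancy_filter <- function(values, labels, survivors, corr_threshold = 0.9) {
  if (!length(survivors))
    return(list(kept = character(), clusters = integer(),
                svm = NULL, delta = numeric()))
  v <- values[, survivors, drop = FALSE]
  cm <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  cm[!is.finite(cm)] <- 0
  adj <- abs(cm) >= corr_threshold
  # transitive closure by union-find
  parent <- seq_along(survivors)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(survivors)) for (j in seq_len(i - 1L))
    if (adj[i, j]) parent[find(i)] <- find(j)
  comp <- vapply(seq_along(survivors), find, 0L)
  svm_perf <- t(vapply(survivors,
                       function(f) svm_single_feature(values[, f], labels),
                       c(accuracy = 0, sensitivity = 0, specificity = 0)))
  kept <- character()
  for (cl in unique(comp)) {
    members <- survivors[comp == cl]
    perf <- svm_perf[members, , drop = FALSE]
    ord <- order(-perf[, "accuracy"],
                 -(perf[, "sensitivity"] + perf[, "specificity"]), members)
    kept <- c(kept, members[ord[1L]])
  }
  kept <- sort(kept)
  delta <- vapply(kept, function(f) glass_delta(values[, f], labels), 0)
  list(kept = kept, clusters = stats::setNames(comp, survivors),
       svm = svm_perf, delta = delta)
}

#' Reduction settings
#' @param alpha significance level for the t-test stages.
#' @param group_size robustness subgroup size.
#' @param rounds robustness rounds.
#' @param robustness_frac robustness survivor threshold (fraction of
#'   the maximum score).
#' @param corr_threshold redundancy correlation threshold.
#' @param delta_min minimum |Glass's delta| kept after redundancy.
#' @param min_keep keep at least this many features (topped up by
#'   |delta| when the delta filter is too aggressive).
#' @param max_keep cap on the final feature count (strongest |delta|
#'   first).
#' @return list of settings.
#' @export
reduction_control <- function(alpha = 0.05, group_size = 15, rounds = 20,
                              robustness_frac = 0.6, corr_threshold = 0.9,
                              delta_min = 0.8, min_keep = 3, max_keep = 15) {
  list(alpha = alpha, group_size = group_size, rounds = rounds,
       robustness_frac = robustness_frac, corr_threshold = corr_threshold,
       delta_min = delta_min, min_keep = min_keep, max_keep = max_keep)
}

#' Run the full feature-reduction pipeline
#'
#' Significance -> robustness -> redundancy (with SVM tie-breaking)
#' -> effect-size filter, in order; later stages never resurrect a
#' rejected feature. The report records the stage at which each
#' feature was rejected.
#'
#' @inheritParams significance_filter
#' @param control settings from [reduction_control()].
#' @param seed integer seed (drives the robustness subsampling).
#' @return list with `selected` (final feature ids) and `report` (data
#'   frame: feature, p_value, robustness_score, glass_delta, kept,
#'   rejection_stage) plus `max_score`.
#' @export
run_reduction <- function(values, labels, control = reduction_control(),
                          seed = 1) {
  feats <- colnames(values)
  report <- data.frame(feature = feats, p_value = NA_real_,
                       robustness_score = NA_integer_,
                       glass_delta = NA_real_, kept = FALSE,
                       rejection_stage = NA_character_,
                       stringsAsFactors = FALSE)
  sig <- significance_filter(values, labels, control$alpha)
  report$p_value <- sig$p_values[feats]
  report$rejection_stage[!feats %in% sig$survivors] <- "significance"
  if (!length(sig$survivors)) {
    warning("no feature survives the significance stage")
    return(list(selected = character(), report = report, max_score = 0L))
  }
  rob <- robustness_scores(values[, sig$survivors, drop = FALSE], labels,
                           group_size = control$group_size,
                           rounds = control$rounds, alpha = control$alpha,
                           frac = control$robustness_frac, seed = seed)
  report$robustness_score[match(sig$survivors, feats)] <- rob$scores
  rejected_rob <- setdiff(sig$survivors, rob$survivors)
  report$rejection_stage[feats %in% rejected_rob] <- "robustness"
  if (!length(rob$survivors)) {
    warning("no feature survives the robustness stage")
    return(list(selected = character(), report = report,
                max_score = rob$max_score))
  }
  red <- redundancy_filter(values, labels, rob$survivors,
                           control$corr_threshold)
  report$rejection_stage[feats %in% setdiff(rob$survivors, red$kept)] <-
    "redundancy"
  delta_all <- vapply(red$kept, function(f)
    tryCatch(glass_delta(values[, f], labels), error = function(e) NA_real_), 0)
  report$glass_delta[match(red$kept, feats)] <- delta_all
  strong <- red$kept[!is.na(delta_all) & abs(delta_all) > control$delta_min]
  if (length(strong) < control$min_keep) {
    ord <- red$kept[order(-abs(delta_all))]
    strong <- utils::head(ord, control$min_keep)
  }
  if (length(strong) > control$max_keep) {
    d <- abs(delta_all[match(strong, red$kept)])
    strong <- strong[order(-d)][seq_len(control$max_keep)]
  }
  report$rejection_stage[feats %in% setdiff(red$kept, strong)] <- "effect_size"
  report$kept <- feats %in% strong
  list(selected = sort(strong), report = report, max_score = rob$max_score)
}
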