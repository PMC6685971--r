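#' Default anthropometric subset specifications
#'
#' The six subgroups in which subset-specific features are selected and
#' classifiers trained: BMI < 35, age > 50, age <= 50, male, NC > 40
#' and MpS <= 2. Neck circumference joins the candidate feature pool
#' (`include_nc`) in every subset except its own.
#'
#' @return data frame with columns `name`, `field`, `op`, `threshold`,
#'   `include_nc`.
#' @export
subset_specs <- function() {
  data.frame(
    name = c("bmi_lt_35", "age_gt_50", "age_le_50", "male", "nc_gt_40",
             "mps_le_2"),
    field = c("bmi", "age", "age", "sex", "nc", "mps"),
    op = c("<", ">", "<=", "==", ">", "<="),
    threshold = c("35", "50", "50", "male", "40", "2"),
    include_nc = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Evaluate a subset predicate on a cohort
#' @keywords internal
subset_members <- function(cohort, spec) {
  if (!spec$field %in% names(cohort))
    stop("unknown anthropometric field in subset predicate: ", spec$field)
  x <- cohort[[spec$field]]
  thr <- spec$threshold
  sel <- switch(spec$op,
    "<"  = x < as.numeric(thr),
    "<=" = x <= as.numeric(thr),
    ">"  = x > as.numeric(thr),
    ">=" = x >= as.numeric(thr),
    "==" = x == thr,
    stop("unknown predicate operator: ", spec$op))
  cohort$subject_id[sel]
}

#' Build anthropometric subset memberships
#'
#' A subject may belong to several subsets. A warning is emitted when a
#' subset's feature-extraction severity groups fall below 30 (non-OSA)
#' or 20 (OSA) members, the minimum the selection procedure assumes.
#'
#' @param cohort an `osa_cohort` (after [split_cohort()]).
#' @param specs subset specification data frame ([subset_specs()]).
#' @param min_sizes minimum feature-extraction group sizes
#'   `(non_osa, osa)` before a warning.
#' @return named list: per subset, `members` (subject ids) and
#'   `n_fe` (feature-extraction group counts).
#' @export
build_subsets <- function(cohort, specs = subset_specs(),
                          min_sizes = c(non_osa = 30, osa = 20)) {
  out <- list()
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i, ]
    members <- subset_members(cohort, spec)
    fe <- cohort$subject_id %in% members & isTRUE_v(cohort$feature_extraction)
    n_fe <- table(cohort$group[fe])
    if (length(members) && any(n_fe < min_sizes[names(n_fe)]))
      warning("subset ", spec$name, " has small feature-extraction groups (",
              paste(names(n_fe), n_fe, sep = "=", collapse = ", "), ")")
    out[[spec$name]] <- list(spec = spec, members = members, n_fe = n_fe)
  }
  out
}

#' @keywords internal
isTRUE_v <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' Boxplot adjacent values (outlier fences)
#'
#' Per feature and severity group, the adjacent values are the most
#' extreme observations inside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
#' (linear-interpolation quartiles); the merged fence per feature is
#' the lowest lower adjacent value and the highest upper adjacent value
#' across the two groups.
#'
#' @param values subjects x features numeric matrix (training rows).
#' @param labels two-level severity factor aligned to rows.
#' @return object of class `outlier_fences`: list with `lower`, `upper`
#'   (named vectors) and `per_group` (group-wise adjacent values).
#' @export
outlier_fences <- function(values, labels) {
  adjacent <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(c(NA_real_, NA_real_))
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    inside <- x[x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr]
    range(inside)
  }
  groups <- levels(labels)
  per_group <- lapply(groups, function(g) {
    apply(values[labels == g, , drop = FALSE], 2, adjacent)
  })
  names(per_group) <- groups
  lower <- pmin(per_group[[1]][1, ], per_group[[2]][1, ], na.rm = TRUE)
  upper <- pmax(per_group[[1]][2, ], per_group[[2]][2, ], na.rm = TRUE)
  structure(list(lower = lower, upper = upper, per_group = per_group),
            class = "outlier_fences")
}

#' Apply outlier fences
#'
#' Values outside the merged fence are marked missing. Idempotent.
#'
#' @param values numeric matrix whose columns (a subset of the fence
#'   features) are screened.
#' @param fences an `outlier_fences` object.
#' @return `values` with out-of-bound entries set to `NA`.
#' @export
apply_fences <- function(values, fences) {
  for (f in intersect(colnames(values), names(fences$lower))) {
    bad <- !is.na(values[, f]) &
      (values[, f] < fences$lower[f] | values[, f] > fences$upper[f])
    values[bad, f] <- NA_real_
  }
  values
}

#' Enumerate 3- and 4-feature combinations
#'
#' All size-3 and size-4 subsets of the candidate features; with
#' `include_nc`, neck circumference (`"nc"`) joins the pool as an
#' ordinary feature. Pairs listed in `exclusive_pairs` never co-occur
#' in one combination (features flagged as alternatives of each other).
#'
#' @param features character vector of candidate feature ids (>= 3).
#' @param include_nc add `"nc"` to the pool.
#' @param exclusive_pairs optional list of length-2 character vectors.
#' @return list of character vectors (the combinations).
#' @export
enumerate_combinations <- function(features, include_nc = FALSE,
                                   exclusive_pairs = NULL) {
  pool <- if (include_nc) c(features, "nc") else features
  if (length(pool) < 3L) stop("need at least 3 candidate features")
  combos <- c(
    utils::combn(pool, 3L, simplify = FALSE),
    if (length(pool) >= 4L) utils::combn(pool, 4L, simplify = FALSE)
  )
  if (!is.null(exclusive_pairs)) {
    ok <- vapply(combos, function(cb)
      !any(vapply(exclusive_pairs, function(pr) all(pr %in% cb), logical(1))),
      logical(1))
    combos <- combos[ok]
  }
  combos
}

#' Random forest with out-of-bag validation
#'
#' Trains a random forest (bootstrap resampling, so about 2/3 of the
#' rows are in the bag per tree; Gini splitting) with misclassification
#' costs inversely proportional to class prevalence
#' (`cost_k = n / (2 n_k)`), and evaluates out-of-bag accuracy,
#' sensitivity (OSA recall) and specificity (non-OSA recall).
#' Deterministic given `seed`.
#'
#' @param x data frame or matrix of predictors (rows with missing
#'   values are dropped).
#' @param y two-level severity factor (`non_osa`/`osa`).
#' @param num_trees number of trees.
#' @param seed integer seed.
#' @return list with `fit` (a `ranger` object), `oob_accuracy`,
#'   `oob_sensitivity`, `oob_specificity`, `rows` (row names used).
#' @export
train_random_forest_oob <- function(x, y, num_trees = 1200, seed = 1) {
  x <- as.data.frame(x)
  ok <- stats::complete.cases(x)
  x <- x[ok, , drop = FALSE]
  y <- droplevels(y[ok])
  if (nlevels(y) < 2L) stop("both severity classes must be present")
  n <- length(y)
  w <- n / (2 * table(y))
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                        class.weights = as.numeric(w[levels(y)]),
                        seed = seed, num.threads = 1)
  pred <- fit$predictions
  keep <- !is.na(pred)
  list(fit = fit,
       oob_accuracy = mean(pred[keep] == y[keep]),
       oob_sensitivity = mean(pred[keep & y == "osa"] == "osa"),
       oob_specificity = mean(pred[keep & y == "non_osa"] == "non_osa"),
       rows = rownames(x))
}

#' Score feature combinations by repeated OOB validation
#'
#' Each combination is trained `reps` times (seeds `seed + 1 .. seed +
#' reps`), yielding `reps` values of OOB accuracy, sensitivity and
#' specificity. Combinations with any value below `min_metric` are
#' dropped. Among the survivors, the per-metric maximum
#' (max - min over repetitions) spread is recorded and the shortlist
#' keeps the combinations whose average accuracy lies within
#' `max(max_spread_accuracy, window)` of the best average.
#'
#' @param values subjects x features matrix (fenced, scaled; may
#'   contain `NA`).
#' @param labels severity factor aligned to rows.
#' @param combinations list of feature-id vectors.
#' @param reps repetitions (3).
#' @param num_trees trees per forest.
#' @param min_metric per-repetition floor on every metric (0.7).
#' @param window minimum selection window below the best average (2%).
#' @param seed integer seed.
#' @param min_class_n skip a combination when fencing leaves fewer
#'   complete rows than this in either class.
#' @return list with `shortlist` (combinations kept), `scores` (data
#'   frame of per-combination averages and spreads).
#' @export
score_combinations <- function(values, labels, combinations, reps = 3,
                               num_trees = 1200, min_metric = 0.7,
                               window = 0.02, seed = 1, min_class_n = 5) {
  if (!length(combinations)) stop("no combinations to score")
  res <- lapply(combinations, function(cb) {
    v <- values[, cb, drop = FALSE]
    ok <- stats::complete.cases(v)
    if (min(table(labels[ok])) < min_class_n) return(NULL)
    m <- vapply(seq_len(reps), function(r) {
      tr <- train_random_forest_oob(v, labels, num_trees, seed = seed + r)
      c(tr$oob_accuracy, tr$oob_sensitivity, tr$oob_specificity)
    }, numeric(3))
    list(combo = cb, metrics = m)
  })
  keep <- !vapply(res, is.null, logical(1))
  res <- res[keep]
  if (!length(res)) {
    warning("no combination could be scored")
    return(list(shortlist = list(), scores = NULL))
  }
  pass <- vapply(res, function(r) all(r$metrics >= min_metric), logical(1))
  scores <- data.frame(
    combination = vapply(res, function(r) paste(r$combo, collapse = "+"), ""),
    mean_accuracy = vapply(res, function(r) mean(r$metrics[1, ]), 0),
    mean_sensitivity = vapply(res, function(r) mean(r$metrics[2, ]), 0),
    mean_specificity = vapply(res, function(r) mean(r$metrics[3, ]), 0),
    spread_accuracy = vapply(res, function(r) diff(range(r$metrics[1, ])), 0),
    pass_floor = pass,
    stringsAsFactors = FALSE
  )
  if (!any(pass)) {
    warning("no combination keeps all repetition metrics >= ", min_metric)
    return(list(shortlist = list(), scores = scores))
  }
  surv <- scores[pass, ]
  best <- max(surv$mean_accuracy)
  lower <- best - max(max(surv$spread_accuracy), window)
  sel <- pass & scores$mean_accuracy >= lower
  list(shortlist = lapply(res[sel], function(r) r$combo), scores = scores)
}

#' Select the final combination for one subset
#'
#' Each shortlisted combination is retrained `reps` times
#' (seeds `seed + 1 .. seed + reps`); the combination with the highest
#' mean OOB validation accuracy wins (ties: higher mean sensitivity +
#' specificity, then lexicographic feature ids). The returned model
#' holds the forest retrained on all usable subset training rows and
#' the mean OOB sensitivity/specificity used as voting weights.
#'
#' @inheritParams score_combinations
#' @param shortlist list of candidate combinations (non-empty).
#' @param spec one-row subset specification (carried in the model).
#' @param fences `outlier_fences` used for this subset (carried in the
#'   model and applied at screening time).
#' @param reps repetitions (5).
#' @return object of class `subset_model`: list with `name`, `spec`,
#'   `combination`, `fences`, `fit`, `oob_accuracy`, `oob_sensitivity`,
#'   `oob_specificity`, `oob_predictions` (named OOB votes on the
#'   training rows), `seed`.
#' @export
select_final_combination <- function(values, labels, shortlist,
                                     spec = NULL, fences = NULL, reps = 5,
                                     num_trees = 1200, seed = 1) {
  if (!length(shortlist)) stop("empty shortlist")
  stats_all <- lapply(shortlist, function(cb) {
    m <- vapply(seq_len(reps), function(r) {
      tr <- train_random_forest_oob(values[, cb, drop = FALSE], labels,
                                    num_trees, seed = seed + r)
      c(tr$oob_accuracy, tr$oob_sensitivity, tr$oob_specificity)
    }, numeric(3))
    rowMeans(m)
  })
  acc <- vapply(stats_all, `[`, 0, 1L)
  ss <- vapply(stats_all, function(s) s[2L] + s[3L], 0)
  ids <- vapply(shortlist, function(cb) paste(cb, collapse = "+"), "")
  ord <- order(-acc, -ss, ids)
  win <- ord[1L]
  cb <- shortlist[[win]]
  final <- train_random_forest_oob(values[, cb, drop = FALSE], labels,
                                   num_trees, seed = seed)
  structure(list(name = if (is.null(spec)) ids[win] else spec$name,
                 spec = spec, combination = cb, fences = fences,
                 fit = final$fit,
                 oob_accuracy = stats_all[[win]][1L],
                 oob_sensitivity = stats_all[[win]][2L],
                 oob_specificity = stats_all[[win]][3L],
                 oob_predictions = stats::setNames(
                   as.character(final$fit$predictions), final$rows),
                 seed = seed),
            class = "subset_model")
}
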