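#' Weighted vote of one subset classifier
#'
#' The raw class vote is mapped to the labels +1 (OSA) and -1
#' (non-OSA) and weighted by the classifier's out-of-bag performance:
#' `+1 x oob_sensitivity` for an OSA vote, `-1 x oob_specificity` for a
#' non-OSA vote. A subject whose combination features are missing
#' (after fencing) yields an abstention (`NA`).
#'
#' @param model a `subset_model`.
#' @param feature_row named numeric vector (scaled feature values, may
#'   contain `NA`).
#' @param use_oob use the stored out-of-bag prediction when the subject
#'   was one of the model's training rows (named `feature_row` rows).
#' @param subject_id optional subject id for the OOB lookup.
#' @return weighted vote in `[-1, 1]`, or `NA` for abstention.
#' @export
subset_vote <- function(model, feature_row, use_oob = TRUE,
                        subject_id = NULL) {
  v <- feature_row[model$combination]
  if (anyNA(v)) return(NA_real_)
  raw <- NULL
  if (use_oob && !is.null(subject_id) &&
      subject_id %in% names(model$oob_predictions))
    raw <- model$oob_predictions[[subject_id]]
  if (is.null(raw) || is.na(raw)) {
    d <- as.data.frame(as.list(v))
    names(d) <- model$combination
    raw <- as.character(stats::predict(model$fit, data = d,
                                       num.threads = 1)$predictions)
  }
  if (raw == "osa") model$oob_sensitivity else -model$oob_specificity
}

#' Fuse weighted votes into the final decision
#'
#' The final decision is the average of the non-abstaining weighted
#' votes: `d in [-1, 1]`. A subject is called OSA iff `d > 0`; `d = 0`
#' exactly is called non-OSA with a tie flag. `|d| > 0.7` sets the
#' high-confidence flag. With every classifier at 100%
#' sensitivity/specificity, unanimous OSA votes give `d = 1` and
#' unanimous non-OSA votes give `d = -1`.
#'
#' @param votes numeric vector of weighted votes (`NA` = abstain).
#' @return list with `d`, `call` (`"osa"`/`"non_osa"`/`NA`), `tie`,
#'   `high_confidence`, `n_votes`, `unclassifiable`.
#' @export
weighted_decision <- function(votes) {
  v <- votes[!is.na(votes)]
  if (!length(v))
    return(list(d = NA_real_, call = NA_character_, tie = FALSE,
                high_confidence = FALSE, n_votes = 0L, unclassifiable = TRUE))
  d <- mean(v)
  list(d = d, call = if (d > 0) "osa" else "non_osa", tie = d == 0,
       high_confidence = abs(d) > 0.7, n_votes = length(v),
       unclassifiable = FALSE)
}

#' Classify a cohort with a subset-classifier ensemble
#'
#' Every subset model votes on every subject regardless of the
#' subject's own subset membership (universal voting; restrict with
#' `membership_only`). Per-model fences are applied to the subject's
#' combination features first; out-of-fence values abstain that model.
#'
#' @param models list of `subset_model` objects.
#' @param values subjects x features matrix of scaled feature values
#'   (training-set scaling), possibly with an `nc` column.
#' @param membership_only optional named list of subject-id vectors per
#'   model; when given, a model only votes on its own members.
#' @param use_oob use stored out-of-bag votes for training subjects.
#' @return data frame (one row per subject): per-model weighted votes,
#'   `d`, `call`, `tie`, `high_confidence`, `unclassifiable`.
#' @export
classify_cohort <- function(models, values, membership_only = NULL,
                            use_oob = TRUE) {
  if (is.null(rownames(values))) stop("values must have subject-id rownames")
  subjects <- rownames(values)
  vote_mat <- matrix(NA_real_, length(subjects), length(models),
                     dimnames = list(subjects, names(models)))
  for (mn in names(models)) {
    model <- models[[mn]]
    fenced <- values
    if (!is.null(model$fences)) {
      cols <- intersect(model$combination, colnames(values))
      fenced[, cols] <- apply_fences(values[, cols, drop = FALSE],
                                     model$fences)
    }
    for (s in subjects) {
      if (!is.null(membership_only) && !s %in% membership_only[[mn]]) next
      row <- stats::setNames(fenced[s, ], colnames(fenced))
      vote_mat[s, mn] <- subset_vote(model, row, use_oob = use_oob,
                                     subject_id = s)
    }
  }
  dec <- lapply(subjects, function(s) weighted_decision(vote_mat[s, ]))
  out <- data.frame(subject_id = subjects,
                    d = vapply(dec, `[[`, 0, "d"),
                    call = vapply(dec, function(x)
                      if (is.na(x$call)) NA_character_ else x$call, ""),
                    tie = vapply(dec, `[[`, FALSE, "tie"),
                    high_confidence = vapply(dec, `[[`, FALSE, "high_confidence"),
                    unclassifiable = vapply(dec, `[[`, FALSE, "unclassifiable"),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(vote_mat))
}

#' Classification metrics of a decision report
#'
#' Sensitivity is OSA recall, specificity non-OSA recall, accuracy the
#' overall fraction correct; unclassifiable subjects count as errors.
#'
#' @param report decision data frame from [classify_cohort()].
#' @param truth factor/character of true groups aligned to report rows.
#' @return named numeric vector `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_decisions <- function(report, truth) {
  if (!nrow(report)) stop("empty decision report")
  truth <- as.character(truth)
  correct <- !is.na(report$call) & report$call == truth
  c(accuracy = mean(correct),
    sensitivity = mean(correct[truth == "osa"]),
    specificity = mean(correct[truth == "non_osa"]))
}

#' Subset-ablation analysis
#'
#' Recomputes the voted metrics with each subset model removed in turn
#' and reports the deltas against the full ensemble (negative delta =
#' removing the model hurts).
#'
#' @param models list of >= 2 `subset_model` objects.
#' @param values scaled feature matrix (as in [classify_cohort()]).
#' @param truth true groups aligned to rows of `values`.
#' @param use_oob use stored out-of-bag votes for training subjects.
#' @return data frame: one row per left-out model with the metric
#'   deltas (ablated minus full).
#' @export
subset_ablation <- function(models, values, truth, use_oob = TRUE) {
  if (length(models) < 2L) stop("need at least 2 models to ablate")
  full <- evaluate_decisions(classify_cohort(models, values,
                                             use_oob = use_oob), truth)
  out <- lapply(names(models), function(mn) {
    m <- evaluate_decisions(
      classify_cohort(models[setdiff(names(models), mn)], values,
                      use_oob = use_oob), truth)
    data.frame(left_out = mn, d_accuracy = m["accuracy"] - full["accuracy"],
               d_sensitivity = m["sensitivity"] - full["sensitivity"],
               d_specificity = m["specificity"] - full["specificity"],
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Correlation of a feature combination with AHI
#'
#' Least-squares regression of AHI (or log AHI) on the combination's
#' features; returns the Pearson correlation between fitted and
#' observed values (the multiple correlation coefficient).
#'
#' @param values subjects x features matrix.
#' @param combination character vector of feature ids.
#' @param ahi numeric AHI per subject (events/hour).
#' @param scale `"linear"` or `"log"`; on the log scale subjects with
#'   `ahi <= 0` are dropped with a warning.
#' @return correlation coefficient in \[0, 1\].
#' @export
combination_ahi_correlation <- function(values, combination, ahi,
                                        scale = c("linear", "log")) {
  scale <- match.arg(scale)
  y <- ahi
  keep <- rep(TRUE, length(y))
  if (scale == "log") {
    keep <- y > 0
    if (any(!keep)) warning(sum(!keep), " subject(s) with AHI <= 0 dropped ",
                            "from the log-scale fit")
    y <- log(y[keep])
  }
  x <- as.data.frame(values[keep, combination, drop = FALSE])
  ok <- stats::complete.cases(x) & is.finite(y)
  if (sum(ok) < 10L) stop("need at least 10 usable subjects")
  fit <- stats::lm(y[ok] ~ ., data = x[ok, , drop = FALSE])
  stats::cor(stats::fitted(fit), y[ok])
}
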