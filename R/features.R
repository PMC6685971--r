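#' Local maxima with prominence
#'
#' Strict local maxima of `y`; the prominence of a peak is its height
#' above the higher of the two deepest valleys separating it from
#' higher ground (or from the series edge).
#'
#' @param y numeric vector.
#' @param min_prominence minimum prominence to report a peak.
#' @return integer indices of qualifying peaks, in order.
#' @keywords internal
find_peaks <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3L) return(integer())
  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  keep <- vapply(cand, function(i) {
    left <- y[1:i]
    higher <- which(left > y[i])
    lmin <- if (length(higher)) min(left[max(higher):i]) else min(left)
    right <- y[i:n]
    higher <- which(right > y[i])
    rmin <- if (length(higher)) min(right[1:min(higher)]) else min(right)
    (y[i] - max(lmin, rmin)) >= min_prominence
  }, logical(1))
  cand[keep]
}

#' @keywords internal
band_index <- function(freq, band) {
  which(freq >= band[1] & freq <= band[2])
}

#' Band statistics of a power spectrum
#'
#' Computes one named statistic of a Welch PSD over a closed frequency
#' band (a grid point belongs to the band iff `f1 <= f <= f2`):
#' \describe{
#'   \item{band_mean}{arithmetic mean of power over the band}
#'   \item{geometric_mean}{`exp(mean(log power))` (always on linear power)}
#'   \item{slope_mean}{mean of the first differences of power with
#'     respect to frequency (per Hz)}
#'   \item{centroid}{power-weighted mean frequency}
#'   \item{centroid_bandwidth}{spectral spread: root of the power-weighted
#'     second central moment about the centroid}
#'   \item{first_peak_freq}{frequency of the first local maximum at or
#'     below `cutoff` with prominence >= `p_min` dB}
#'   \item{mean_max_peak_freq}{mean frequency of all local maxima in the
#'     band with prominence >= `p_min` dB}
#' }
#'
#' @param spectrum a `welch_psd`.
#' @param band numeric `(f1, f2)` in Hz, or `NULL` for `first_peak_freq`.
#' @param operator statistic name (see above).
#' @param scale `"dB"` (10 log10 power) or `"linear"`; peak and
#'   centroid operators measure frequency, mean/slope operators are
#'   scale-sensitive.
#' @param cutoff upper frequency bound for `first_peak_freq`, Hz.
#' @param p_min minimum peak prominence, dB.
#' @return a single numeric value; `NA` (with a `"no_peak"` attribute)
#'   when a peak operator finds no peak.
#' @export
psd_band_statistic <- function(spectrum, band, operator = "band_mean",
                               scale = "dB", cutoff = 550, p_min = 3) {
  f <- spectrum$freq
  p_lin <- spectrum$power
  if (operator == "first_peak_freq") {
    idx <- which(f <= cutoff)
    pk <- find_peaks(10 * log10(p_lin[idx]), min_prominence = p_min)
    if (!length(pk)) return(structure(NA_real_, reason = "no_peak"))
    return(f[idx][pk[1L]])
  }
  idx <- band_index(f, band)
  if (length(idx) < 3L)
    stop("band [", band[1], ", ", band[2], "] Hz intersects fewer than 3 grid points")
  fi <- f[idx]
  pl <- p_lin[idx]
  pv <- if (identical(scale, "dB")) 10 * log10(pl) else pl
  switch(operator,
    band_mean = mean(pv),
    geometric_mean = exp(mean(log(pl))),
    slope_mean = mean(diff(pv) / diff(fi)),
    centroid = sum(fi * pl) / sum(pl),
    centroid_bandwidth = {
      c0 <- sum(fi * pl) / sum(pl)
      sqrt(sum((fi - c0)^2 * pl) / sum(pl))
    },
    mean_max_peak_freq = {
      pk <- find_peaks(10 * log10(pl), min_prominence = p_min)
      if (!length(pk)) structure(NA_real_, reason = "no_peak") else mean(fi[pk])
    },
    stop("unknown PSD operator: ", operator)
  )
}

#' Difference of two band means
#'
#' `mean(P) over band_a - mean(P) over band_b`, each computed by
#' [psd_band_statistic()] on the same scale.
#'
#' @inheritParams psd_band_statistic
#' @param band_a,band_b numeric `(f1, f2)` bands in Hz.
#' @export
band_mean_difference <- function(spectrum, band_a, band_b, scale = "dB") {
  psd_band_statistic(spectrum, band_a, "band_mean", scale) -
    psd_band_statistic(spectrum, band_b, "band_mean", scale)
}

#' Line statistics of a bispectrum
#'
#' Extracts the bispectral magnitude `m(f) = |B|` along a line
#' parameterised by `f` in `band` — `main_diagonal` is `(f, f)`,
#' `half_f_line` is `(f, f/2)`, `two_f_line` is `(f, 2f)`, and
#' `negative_diagonal` is the anti-diagonal `(f, f_lo + f_hi - f)` of
#' the band square — with both coordinates mapped to the nearest grid
#' bin, then computes:
#' \describe{
#'   \item{bis_mean}{`mean(m)`}
#'   \item{bis_weight_center}{normalised centroid `sum(f m) / sum(m)`}
#'   \item{bis_moment1}{unnormalised first moment `sum(f m) / N`}
#'   \item{bis_moment2}{unnormalised second moment `sum(f^2 m) / N`}
#' }
#' Line points falling outside the stored grid are dropped.
#'
#' @param bispec a `bispec` estimate.
#' @param line one of `"main_diagonal"`, `"negative_diagonal"`,
#'   `"half_f_line"`, `"two_f_line"`.
#' @param band numeric `(f1, f2)` in Hz.
#' @param operator statistic name (see above).
#' @return a single numeric value.
#' @export
bispectrum_line_statistic <- function(bispec, line, band,
                                      operator = "bis_mean") {
  f <- bispec$freq
  fi <- f[band_index(f, band)]
  if (!length(fi)) stop("band does not intersect the bispectral grid")
  f2 <- switch(line,
    main_diagonal = fi,
    half_f_line = fi / 2,
    two_f_line = fi * 2,
    negative_diagonal = band[1] + band[2] - fi,
    stop("unknown bispectral line: ", line)
  )
  ok <- f2 >= 0 & f2 <= max(f)
  fi <- fi[ok]; f2 <- f2[ok]
  if (length(fi) < 2L)
    stop("line ", line, " has fewer than 2 points in band [",
         band[1], ", ", band[2], "] Hz")
  nearest <- function(v) pmin(length(f), pmax(1L, round(v / (f[2] - f[1])) + 1L))
  m <- Mod(bispec$values[cbind(nearest(fi), nearest(f2))])
  n <- length(m)
  switch(operator,
    bis_mean = mean(m),
    bis_weight_center = sum(fi * m) / sum(m),
    bis_moment1 = sum(fi * m) / n,
    bis_moment2 = sum(fi^2 * m) / n,
    stop("unknown bispectral operator: ", operator)
  )
}

#' Katz fractal dimension
#'
#' Treats the series as a planar curve with unit abscissa steps:
#' `FD = log10(n) / (log10(n) + log10(d / L))` with `L` the total path
#' length and `d` the maximum distance from the first point. A straight
#' line (and a constant signal) has FD exactly 1.
#'
#' @param x numeric signal (length >= 2).
#' @return Katz fractal dimension (>= 1).
#' @export
katz_fd <- function(x) {
  n <- length(x) - 1L
  if (n < 1L) stop("need at least 2 samples")
  L <- sum(sqrt(1 + diff(x)^2))
  d <- max(sqrt((seq_along(x) - 1)^2 + (x - x[1])^2))
  log10(n) / (log10(n) + log10(d / L))
}

#' Higuchi fractal dimension
#'
#' Curve lengths `L(k)` over decimated sub-series for `k = 1..k_max`;
#' the fractal dimension is the slope of `log L(k)` against
#' `log(1/k)`. White noise has FD close to 2, a smooth curve close
#' to 1.
#'
#' @param x numeric signal (length >= 128).
#' @param k_max maximum delay.
#' @return Higuchi fractal dimension.
#' @export
higuchi_fd <- function(x, k_max = 16) {
  n <- length(x)
  if (n < 128L) stop("need at least 128 samples")
  lk <- vapply(seq_len(k_max), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2L) return(NA_real_)
      sum(abs(diff(x[idx]))) * (n - 1) / (floor((n - m) / k) * k) / k
    }, 0)
    mean(lm_k, na.rm = TRUE)
  }, 0)
  ks <- seq_len(k_max)
  stats::coef(stats::lm(log(lk) ~ log(1 / ks)))[[2L]]
}

#' Hurst exponent by rescaled-range analysis
#'
#' Classic R/S estimation over dyadic window sizes with the
#' Anis-Lloyd-Peters small-sample correction: the corrected exponent is
#' `0.5 + (empirical slope - expected slope under independence)`, which
#' centres white noise at 0.5. Operates on a (stationary) noise-like
#' series; pass increments for motion-like signals.
#'
#' @param x numeric signal (length >= 128).
#' @param min_window smallest window size used in the regression.
#' @return list with `hurst` (corrected), `hurst_raw` (uncorrected
#'   slope). A constant signal yields `NA` with a flag.
#' @export
hurst_rs <- function(x, min_window = 16) {
  n <- length(x)
  if (n < 128L) stop("need at least 128 samples")
  if (stats::sd(x) == 0)
    return(list(hurst = structure(NA_real_, reason = "constant_signal"),
                hurst_raw = NA_real_))
  sizes <- 2^seq(floor(log2(min_window)), floor(log2(n / 2)))
  rs <- vapply(sizes, function(w) {
    k <- n %/% w
    vals <- vapply(seq_len(k), function(b) {
      seg <- x[((b - 1L) * w + 1L):(b * w)]
      dev <- cumsum(seg - mean(seg))
      s <- stats::sd(seg)
      if (s == 0) return(NA_real_)
      (max(dev) - min(dev)) / s
    }, 0)
    mean(vals, na.rm = TRUE)
  }, 0)
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 3L)
    return(list(hurst = structure(NA_real_, reason = "degenerate"),
                hurst_raw = NA_real_))
  emp <- stats::coef(stats::lm(log2(rs[ok]) ~ log2(sizes[ok])))[[2L]]
  # expected R/S of an i.i.d. series (Anis-Lloyd with Peters correction)
  e_rs <- vapply(sizes, function(w) {
    i <- seq_len(w - 1L)
    (w - 0.5) / w * sum(sqrt((w - i) / i)) / sqrt(w * pi / 2)
  }, 0)
  th <- stats::coef(stats::lm(log2(e_rs[ok]) ~ log2(sizes[ok])))[[2L]]
  list(hurst = 0.5 + emp - th, hurst_raw = emp)
}

#' Fractal features of a breath-phase signal
#'
#' @param x numeric signal (length >= 128).
#' @param k_max Higuchi maximum delay.
#' @return named numeric vector `katz`, `higuchi`, `hurst`.
#' @export
fractal_features <- function(x, k_max = 16) {
  if (stats::sd(x) == 0)
    return(c(katz = 1, higuchi = NA_real_, hurst = NA_real_))
  c(katz = katz_fd(x), higuchi = higuchi_fd(x, k_max),
    hurst = hurst_rs(x)$hurst[[1L]])
}

#' The four fixed discriminative frequency bands
#'
#' 100-300, 350-600, 1000-1700 and 2100-2400 Hz: the bands in which
#' nose/mouth breathing-sound spectra separate the severity groups.
#'
#' @return data frame with columns `f_lo`, `f_hi`.
#' @export
fixed_bands <- function() {
  data.frame(f_lo = c(100, 350, 1000, 2100),
             f_hi = c(300, 600, 1700, 2400))
}

#' Default feature-definition catalog
#'
#' Enumerates the exploratory feature set: for every maneuver
#' (mouth/nose) and phase (inspiration/expiration), PSD band statistics
#' and bispectral line statistics over the four fixed bands (plus any
#' `extra_bands`, e.g. discovered by CI non-overlap), a first-peak
#' frequency (550 Hz cutoff), a low-vs-mid band-mean difference, and
#' the three fractal features. The `two_f_line` is omitted for bands
#' whose tripled frequency leaves the principal bispectral domain.
#'
#' @param bands data frame `f_lo,f_hi` of analysis bands.
#' @param extra_bands optional additional bands data frame with a
#'   `maneuver` and `phase` column (band applies to that signal only).
#' @param nyquist Nyquist frequency, Hz.
#' @return data frame, one row per feature definition, with columns
#'   `feature_id, maneuver, phase, source, operator, f_lo, f_hi,
#'   b_lo, b_hi, line, scale`.
#' @export
feature_catalog <- function(bands = fixed_bands(), extra_bands = NULL,
                            nyquist = 5120) {
  rows <- list()
  add <- function(maneuver, phase, source, operator, f_lo = NA, f_hi = NA,
                  b_lo = NA, b_hi = NA, line = NA_character_, scale = "dB") {
    rows[[length(rows) + 1L]] <<- data.frame(
      maneuver = maneuver, phase = phase, source = source,
      operator = operator, f_lo = f_lo, f_hi = f_hi,
      b_lo = b_lo, b_hi = b_hi, line = line, scale = scale)
  }
  psd_ops <- c(band_mean = "dB", slope_mean = "dB", geometric_mean = "linear",
               centroid = "linear", centroid_bandwidth = "linear",
               mean_max_peak_freq = "linear")
  bis_lines <- list(main_diagonal = c("bis_mean", "bis_weight_center",
                                      "bis_moment1", "bis_moment2"),
                    negative_diagonal = c("bis_moment1", "bis_moment2"),
                    half_f_line = c("bis_weight_center", "bis_moment1"),
                    two_f_line = c("bis_weight_center", "bis_moment1"))
  for (m in c("mouth", "nose")) for (p in c("inspiration", "expiration")) {
    for (b in seq_len(nrow(bands))) {
      lo <- bands$f_lo[b]; hi <- bands$f_hi[b]
      for (op in names(psd_ops))
        add(m, p, "psd", op, lo, hi, scale = psd_ops[[op]])
      for (ln in names(bis_lines)) {
        if (ln == "two_f_line" && 3 * lo > nyquist) next
        for (op in bis_lines[[ln]])
          add(m, p, "bispectrum", op, lo, hi, line = ln, scale = "linear")
      }
    }
    add(m, p, "psd", "first_peak_freq", scale = "linear")
    add(m, p, "psd", "band_mean_difference",
        bands$f_lo[1], bands$f_hi[1], bands$f_lo[3], bands$f_hi[3])
    for (fr in c("katz", "higuchi", "hurst"))
      add(m, p, "fractal", fr, scale = "linear")
  }
  if (!is.null(extra_bands) && nrow(extra_bands)) {
    for (i in seq_len(nrow(extra_bands))) {
      eb <- extra_bands[i, ]
      for (op in c("band_mean", "slope_mean", "centroid"))
        add(eb$maneuver, eb$phase, "psd", op, eb$f_lo, eb$f_hi,
            scale = if (op == "centroid") "linear" else "dB")
    }
  }
  out <- do.call(rbind, rows)
  band_tag <- ifelse(is.na(out$f_lo), "",
                     paste0("_", out$f_lo, "_", out$f_hi))
  line_tag <- ifelse(is.na(out$line), "", paste0("_", out$line))
  out$feature_id <- paste0(substr(out$maneuver, 1, 1),
                           substr(out$phase, 1, 3), "_",
                           out$operator, band_tag, line_tag)
  out$feature_id <- make.unique(out$feature_id, sep = "_")
  out[, c("feature_id", "maneuver", "phase", "source", "operator",
          "f_lo", "f_hi", "b_lo", "b_hi", "line", "scale")]
}

#' Evaluate one feature definition on a subject's spectral summaries
#' @keywords internal
eval_feature <- function(def, mp) {
  if (is.null(mp)) return(NA_real_)
  v <- tryCatch(switch(def$source,
    psd = if (def$operator == "band_mean_difference")
      band_mean_difference(mp$psd, c(def$f_lo, def$f_hi), c(def$b_lo, def$b_hi),
                           scale = def$scale)
    else if (def$operator == "first_peak_freq")
      psd_band_statistic(mp$psd, NULL, "first_peak_freq")
    else
      psd_band_statistic(mp$psd, c(def$f_lo, def$f_hi), def$operator, def$scale),
    bispectrum = bispectrum_line_statistic(mp$bis, def$line,
                                           c(def$f_lo, def$f_hi), def$operator),
    fractal = mp$fractal[[def$operator]],
    stop("unknown source ", def$source)
  ), error = function(e) NA_real_)
  as.numeric(v)[1L]
}

#' Assemble the subjects x features matrix
#'
#' Features are computed on each subject's cycle-averaged spectrum /
#' bispectrum (and cycle-averaged fractal estimates) of the relevant
#' maneuver and phase; subjects lacking a maneuver keep their row with
#' missing entries and a warning.
#'
#' @param subject_spectra named list (one element per subject) of
#'   per-maneuver-phase summaries as produced by
#'   [compute_subject_spectra()]: elements named
#'   `"mouth_inspiration"`, ..., each holding `psd`, `bis`, `fractal`.
#' @param definitions feature catalog data frame ([feature_catalog()]).
#' @return object of class `feature_table`: list with `values`
#'   (numeric matrix, rows = subjects, columns = feature ids),
#'   `definitions`, `scaling` (`NULL` until scaled), `provenance`
#'   (`"raw"`).
#' @export
build_feature_matrix <- function(subject_spectra, definitions) {
  subjects <- names(subject_spectra)
  vals <- matrix(NA_real_, length(subjects), nrow(definitions),
                 dimnames = list(subjects, definitions$feature_id))
  missing_any <- FALSE
  for (s in seq_along(subjects)) {
    cache <- subject_spectra[[s]]
    for (j in seq_len(nrow(definitions))) {
      def <- definitions[j, ]
      key <- paste0(def$maneuver, "_", def$phase)
      if (is.null(cache[[key]])) { missing_any <- TRUE; next }
      vals[s, j] <- eval_feature(def, cache[[key]])
    }
  }
  if (missing_any)
    warning("some subjects lack a maneuver/phase; missing entries retained")
  structure(list(values = vals, definitions = definitions,
                 scaling = NULL, provenance = "raw"),
            class = "feature_table")
}

#' Scale features to the unit interval
#'
#' Per-feature min-max scaling learned on the training rows:
#' `v' = (v - min_train) / (max_train - min_train)`. Non-training rows
#' are transformed with the training parameters and clipped to
#' \[0, 1\]. Features constant on the training rows are dropped with a
#' warning. Applying the scaling to an already-scaled table with its
#' own parameters is the identity.
#'
#' @param table a `feature_table`.
#' @param train_rows character vector of training subject ids (or
#'   logical/integer row index).
#' @return the scaled `feature_table` (provenance `"scaled"`, scaling
#'   parameters stored).
#' @export
scale_unit_interval <- function(table, train_rows) {
  v <- table$values
  tr <- v[train_rows, , drop = FALSE]
  mins <- apply(tr, 2, min, na.rm = TRUE)
  maxs <- apply(tr, 2, max, na.rm = TRUE)
  const <- !is.finite(mins) | !is.finite(maxs) | maxs - mins == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant feature(s) on training rows: ",
            paste(utils::head(colnames(v)[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ...")
    v <- v[, !const, drop = FALSE]
    mins <- mins[!const]; maxs <- maxs[!const]
  }
  sc <- sweep(sweep(v, 2, mins), 2, maxs - mins, "/")
  is_train <- rownames(v) %in% rownames(tr)
  sc[!is_train, ] <- pmin(1, pmax(0, sc[!is_train, , drop = FALSE]))
  structure(list(values = sc,
                 definitions = table$definitions[
                   table$definitions$feature_id %in% colnames(sc), , drop = FALSE],
                 scaling = list(min = mins, max = maxs),
                 provenance = "scaled"),
            class = "feature_table")
}

#' Apply stored scaling parameters to new raw feature values
#' @param values numeric matrix with feature columns.
#' @param scaling list with `min`, `max` named vectors.
#' @return matrix scaled and clipped to \[0, 1\].
#' @export
apply_scaling <- function(values, scaling) {
  keep <- intersect(colnames(values), names(scaling$min))
  v <- values[, keep, drop = FALSE]
  sc <- sweep(sweep(v, 2, scaling$min[keep]), 2,
              scaling$max[keep] - scaling$min[keep], "/")
  out <- pmin(1, pmax(0, sc))           # pmin/pmax drop dim attributes
  matrix(out, nrow(v), ncol(v), dimnames = dimnames(v))
}
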