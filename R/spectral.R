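#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann window. The estimate is
#' one-sided and density-scaled (amplitude^2/Hz) so that the integral of
#' `power` over `freq` recovers the signal variance (Parseval).
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate, Hz.
#' @param window segment length, samples (default 1024: 10 Hz
#'   resolution at 10240 Hz).
#' @param overlap fractional overlap between segments.
#' @param nfft transform length (>= `window`).
#' @return object of class `welch_psd`: list with `freq`, `power`,
#'   `params`.
#' @export
welch_psd <- function(x, sample_rate, window = 1024, overlap = 0.5,
                      nfft = window) {
  if (stats::var(x) == 0) stop("zero-variance signal")
  if (length(x) < window) window <- 2^floor(log2(length(x)))
  if (window < 16) stop("signal too short for spectral estimation")
  if (nfft < window) nfft <- window
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / (window + 1))  # Hann
  hop <- max(1L, round(window * (1 - overlap)))
  starts <- seq(1L, length(x) - window + 1L, by = hop)
  u <- sum(w^2)
  acc <- numeric(nfft %/% 2 + 1L)
  for (s in starts) {
    seg <- x[s:(s + window - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(c(seg, numeric(nfft - window)))
    acc <- acc + Mod(X[seq_len(nfft %/% 2 + 1L)])^2
  }
  p <- acc / (length(starts) * u * sample_rate)
  # one-sided scaling: double everything except DC and Nyquist
  p[2:(length(p) - 1L)] <- 2 * p[2:(length(p) - 1L)]
  structure(list(freq = (0:(nfft %/% 2)) * sample_rate / nfft,
                 power = p,
                 params = list(window = window, overlap = overlap, nfft = nfft,
                               sample_rate = sample_rate,
                               n_segments = length(starts))),
            class = "welch_psd")
}

#' Parzen lag window
#' @keywords internal
parzen_window <- function(u) {
  a <- abs(u)
  ifelse(a <= 0.5, 1 - 6 * a^2 + 6 * a^3,
         ifelse(a <= 1, 2 * (1 - a)^3, 0))
}

#' Indirect (third-cumulant) bispectrum estimate
#'
#' Estimates the bispectrum by the indirect route: the third-order
#' cumulant sequence `c3(i, j)` is estimated on demeaned records
#' (unbiased: every lag pair is averaged over the same number of
#' products), averaged across records, tapered by a Parzen lag window
#' in its product form `w(i) w(j) w(i - j)`, and transformed by a 2-D
#' DFT. The returned grid covers the first quadrant
#' `f1, f2 in [0, Nyquist]`; `B(f1, f2) = B(f2, f1)` holds exactly
#' because the cumulant sequence is symmetric.
#'
#' @param x numeric signal.
#' @param sample_rate sampling rate, Hz.
#' @param max_lag maximum cumulant lag `L`; the frequency grid spacing
#'   is `sample_rate / (2 L)`.
#' @param record record length, samples (must exceed `2 * max_lag`).
#' @param max_records at most this many evenly spaced records enter the
#'   cumulant average (variance/compute trade-off).
#' @return object of class `bispec`: list with `freq` (axis grid, Hz),
#'   `values` (complex matrix, `values[i, j] = B(freq[i], freq[j])`),
#'   `params`.
#' @export
indirect_bispectrum <- function(x, sample_rate, max_lag = 128, record = 1024,
                                max_records = 8) {
  L <- as.integer(max_lag)
  if (record <= 2 * L) stop("record length must exceed 2 * max_lag")
  if (length(x) < record)
    stop("signal shorter than one record (", record, " samples)")
  n_val <- record - 2L * L
  starts <- seq(1L, length(x) - record + 1L, by = record)
  if (length(starts) > max_records)
    starts <- starts[unique(round(seq(1, length(starts), length.out = max_records)))]
  idx <- outer(seq_len(n_val) + L, (-L):L, "+")
  C <- matrix(0, 2L * L + 1L, 2L * L + 1L)
  for (s in starts) {
    xs <- x[s:(s + record - 1L)]
    xs <- xs - mean(xs)
    A <- matrix(xs[idx], n_val)
    C <- C + crossprod(A * xs[(L + 1L):(L + n_val)], A) / n_val
  }
  C <- C / length(starts)
  lw <- parzen_window((-L:L) / L)
  W <- outer(lw, lw) * parzen_window(outer(-L:L, -L:L, "-") / L)
  CW <- C * W
  # wrap lags into DFT order for an nfft = 2L transform; the Parzen
  # window vanishes at |lag| = L, so lags -(L-1)..(L-1) carry everything
  nfft <- 2L * L
  buf <- matrix(0, nfft, nfft)
  pos <- c((L + 1L):(2L * L), 2L:L)             # lag 0..L-1, then -(L-1)..-1
  dst <- c(1L:L, (nfft - L + 2L):nfft)
  buf[dst, dst] <- CW[pos, pos]
  B <- stats::fft(buf)
  q <- seq_len(nfft %/% 2 + 1L)
  structure(list(freq = (q - 1L) * sample_rate / nfft,
                 values = B[q, q],
                 params = list(max_lag = L, record = record,
                               n_records = length(starts),
                               sample_rate = sample_rate, nfft = nfft)),
            class = "bispec")
}

#' Group average spectrum with 95% confidence envelope
#'
#' Per-frequency mean and normal-approximation 95% confidence interval
#' of the group mean (`mean +/- 1.96 SE`), computed on the dB scale.
#'
#' @param power_matrix subjects x frequencies matrix of linear PSD
#'   values (rows on a common grid).
#' @param freq frequency grid, Hz.
#' @param db average on the dB scale (default) or linear.
#' @return object of class `group_spectrum`: list with `freq`, `mean`,
#'   `lower`, `upper`, `n`.
#' @export
group_average_spectrum <- function(power_matrix, freq, db = TRUE) {
  if (is.null(dim(power_matrix)) || nrow(power_matrix) < 2L)
    stop("need at least 2 subjects to form a confidence interval")
  if (ncol(power_matrix) != length(freq))
    stop("frequency grid mismatch: ", ncol(power_matrix), " columns vs ",
         length(freq), " frequencies")
  m <- if (db) 10 * log10(power_matrix) else power_matrix
  mu <- colMeans(m)
  se <- apply(m, 2, stats::sd) / sqrt(nrow(m))
  structure(list(freq = freq, mean = mu,
                 lower = mu - 1.96 * se, upper = mu + 1.96 * se,
                 n = nrow(m), db = db),
            class = "group_spectrum")
}

#' Discover discriminative frequency bands by CI non-overlap
#'
#' Finds maximal contiguous frequency runs where the 95% confidence
#' envelopes of two group spectra are disjoint, and keeps runs at least
#' `min_bw` wide (the minimum bandwidth to accept a band is 100 Hz).
#' Symmetric in its two arguments.
#'
#' @param group_a,group_b `group_spectrum` objects on a common grid.
#' @param min_bw minimum bandwidth, Hz.
#' @return data frame with columns `f_lo`, `f_hi` (possibly 0 rows),
#'   sorted and non-overlapping.
#' @export
find_discriminative_bands <- function(group_a, group_b, min_bw = 100) {
  if (!isTRUE(all.equal(group_a$freq, group_b$freq)))
    stop("frequency grid mismatch between groups")
  disjoint <- group_a$upper < group_b$lower | group_b$upper < group_a$lower
  disjoint[is.na(disjoint)] <- FALSE
  r <- rle(disjoint)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(f_lo = numeric(), f_hi = numeric())
  for (k in which(r$values)) {
    f_lo <- group_a$freq[starts[k]]
    f_hi <- group_a$freq[ends[k]]
    if (f_hi - f_lo >= min_bw)
      out <- rbind(out, data.frame(f_lo = f_lo, f_hi = f_hi))
  }
  out[order(out$f_lo), , drop = FALSE]
}
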