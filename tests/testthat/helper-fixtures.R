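# Shared fixtures: all built in code at test time.

# Direct FFT-product bispectrum: the independent oracle for the indirect
# estimator. Density normalisation (1/nfft) so magnitudes are comparable.
direct_bispectrum <- function(x, sample_rate, nfft = 256) {
  n_seg <- floor(length(x) / nfft)
  q <- nfft %/% 2 + 1L
  B <- matrix(0 + 0i, q, q)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * nfft + 1):(s * nfft)]
    X <- stats::fft(seg - mean(seg))
    for (i in seq_len(q)) {
      k <- i + seq_len(q) - 2L
      ok <- k <= nfft %/% 2
      B[i, ok] <- B[i, ok] + X[i] * X[which(ok)] * Conj(X[k[ok] + 1L])
    }
  }
  list(freq = (seq_len(q) - 1L) * sample_rate / nfft,
       values = B / (n_seg * nfft))
}

# Quadratically phase-coupled test signal: f3 = f1 + f2, phi3 = phi1 + phi2.
qpc_signal <- function(n, sample_rate, f1 = 320, f2 = 416, noise_sd = 0.1,
                       seed = 1) {
  set.seed(seed)
  t <- (0:(n - 1)) / sample_rate
  p1 <- stats::runif(1, 0, 2 * pi)
  p2 <- stats::runif(1, 0, 2 * pi)
  cos(2 * pi * f1 * t + p1) + cos(2 * pi * f2 * t + p2) +
    cos(2 * pi * (f1 + f2) * t + p1 + p2) + noise_sd * stats::rnorm(n)
}

# Fractional Gaussian noise by circulant embedding (exact covariance).
fgn_sim <- function(n, H, seed = 1) {
  set.seed(seed)
  k <- 0:(n - 1)
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  lambda <- Re(stats::fft(c(g, g[n:2][-(n - 1)])))
  lambda[lambda < 0] <- 0
  m <- length(lambda)
  z <- stats::rnorm(m) + 1i * stats::rnorm(m)
  Re(stats::fft(sqrt(lambda / m) * z))[1:n]
}

# Minimal manifest data frame with valid fields.
make_manifest_df <- function(n = 6, ahi = NULL) {
  if (is.null(ahi)) ahi <- seq(2, 40, length.out = n)
  data.frame(
    subject_id = sprintf("T%02d", seq_len(n)),
    ahi = ahi,
    age = seq(35, 65, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    bmi = seq(24, 40, length.out = n),
    nc = seq(35, 46, length.out = n),
    mps = rep(1:3, length.out = n),
    mouth_wav = sprintf("m%02d.wav", seq_len(n)),
    nose_wav = sprintf("n%02d.wav", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

write_manifest <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Burst/gap recording with known boundaries (per the recording protocol:
# alternating bursts starting with inspiration, terminal silence).
make_burst_recording <- function(n_bursts = 10, burst_s = 0.8, gap_s = 0.4,
                                 silence_s = 2, fs = 10240, burst_amp = 0.2,
                                 floor_amp = 0.002, seed = 1) {
  set.seed(seed)
  pieces <- list()
  bounds <- list()
  t0 <- 0
  for (b in seq_len(n_bursts)) {
    nb <- round(burst_s * fs)
    edge <- round(0.02 * fs)
    taper <- c(seq(0, 1, length.out = edge), rep(1, nb - 2 * edge),
               seq(1, 0, length.out = edge))
    pieces[[length(pieces) + 1]] <- burst_amp * stats::rnorm(nb) * taper
    bounds[[b]] <- data.frame(
      phase = if (b %% 2 == 1) "inspiration" else "expiration",
      cycle = (b + 1) %/% 2, start_s = t0, end_s = t0 + burst_s)
    t0 <- t0 + burst_s
    pieces[[length(pieces) + 1]] <- floor_amp * stats::rnorm(round(gap_s * fs))
    t0 <- t0 + gap_s
  }
  pieces[[length(pieces) + 1]] <- floor_amp * stats::rnorm(round(silence_s * fs))
  list(samples = unlist(pieces), sample_rate = fs,
       boundaries = do.call(rbind, bounds))
}

# A fake subset model whose votes are fully determined by stored
# out-of-bag predictions (no forest needed).
fake_model <- function(name, combination, sens, spec, votes) {
  structure(list(name = name, spec = NULL, combination = combination,
                 fences = NULL, fit = NULL,
                 oob_accuracy = (sens + spec) / 2,
                 oob_sensitivity = sens, oob_specificity = spec,
                 oob_predictions = votes, seed = 1),
            class = "subset_model")
}

# Flat white PSD object for feature-operator tests.
flat_psd <- function(value = 1, fs = 10240, nfft = 1024) {
  structure(list(freq = (0:(nfft / 2)) * fs / nfft,
                 power = rep(value, nfft / 2 + 1),
                 params = list(window = nfft, overlap = 0.5, nfft = nfft,
                               sample_rate = fs)),
            class = "welch_psd")
}
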