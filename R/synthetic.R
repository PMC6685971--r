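#' Synthetic-cohort specification
#'
#' Defaults reproduce the shape of the clinical screening cohort the
#' method targets: 109 non-OSA (AHI < 15) and 90 OSA (AHI >= 15)
#' subjects; group AHI moments 3.59 +/- 3.95 and 42.85 +/- 32.72
#' events/hour (truncated normal); anthropometrics coupled to AHI
#' through a Gaussian copula calibrated so the sampled Pearson
#' correlations approach `r = 0.44` (BMI), `0.43` (NC) and `0.26`
#' (MpS); and breathing-sound spectra whose 250-350 Hz slope is
#' negative for non-OSA and positive for OSA subjects, with OSA
#' resonances shifted upward.
#'
#' @param n_non_osa,n_osa group sizes.
#' @param ahi_non,ahi_osa `(mean, sd)` of the truncated-normal AHI
#'   distributions (truncated to `[0, threshold)` and
#'   `[threshold, Inf)`).
#' @param threshold severity threshold, events/hour.
#' @param anthro_link target Pearson correlations
#'   `(bmi_ahi, nc_ahi, mps_ahi)`.
#' @param male_frac probability of male sex per group `(non_osa, osa)`.
#' @param age_non,age_osa `(mean, sd)` of age per group, years.
#' @param bmi_marg,nc_marg `(mean, sd)` cohort marginals of BMI and NC.
#' @param mps_probs cohort Mallampati class probabilities (I..IV).
#' @param sample_rate audio sampling rate, Hz.
#' @param n_cycles breath cycles per maneuver.
#' @param burst_s,gap_s,silence_s phase / pause / breath-hold durations,
#'   seconds.
#' @param contrast_band band carrying the slope contrast, Hz.
#' @param slope_magnitude group slope magnitude over the contrast band,
#'   dB/Hz (non-OSA negative, OSA positive).
#' @param slope_jitter between-subject SD of the slope, dB/Hz.
#' @param resonance_shift upward shift of the OSA resonances, Hz.
#' @param noise_floor_db silent-period level relative to burst level, dB.
#' @return list of settings (class `synthetic_spec`).
#' @export
synthetic_spec <- function(n_non_osa = 109, n_osa = 90,
                           ahi_non = c(3.59, 3.95), ahi_osa = c(42.85, 32.72),
                           threshold = 15,
                           anthro_link = c(bmi_ahi = 0.44, nc_ahi = 0.43,
                                           mps_ahi = 0.26),
                           male_frac = c(non_osa = 50 / 109, osa = 66 / 90),
                           age_non = c(48.60, 12.69), age_osa = c(52.18, 11.55),
                           bmi_marg = c(33.9, 7.8), nc_marg = c(41.7, 5.0),
                           mps_probs = c(81, 55, 37, 26) / 199,
                           sample_rate = 10240, n_cycles = 5,
                           burst_s = 0.8, gap_s = 0.4, silence_s = 2,
                           contrast_band = c(250, 350),
                           slope_magnitude = 0.06, slope_jitter = 0.022,
                           resonance_shift = 70, noise_floor_db = -35) {
  stopifnot(n_non_osa > 0, n_osa > 0, ahi_non[2] > 0, ahi_osa[2] > 0,
            contrast_band[1] > 0, contrast_band[2] < sample_rate / 2)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' @keywords internal
rtruncnorm_q <- function(u, mean, sd, lo, hi) {
  pl <- stats::pnorm(lo, mean, sd)
  ph <- stats::pnorm(hi, mean, sd)
  stats::qnorm(pl + u * (ph - pl), mean, sd)
}

#' Sample anthropometrics coupled to AHI
#'
#' AHI is drawn per severity group from truncated normals (exact group
#' counts); BMI and NC arise from latent Gaussians correlated with the
#' AHI latent (the latent correlation is inflated to undo the
#' attenuation of the non-linear AHI marginal, computed on a
#' quadrature grid); the Mallampati score thresholds a latent normal
#' into classes I-IV. Sex and age are drawn per group. An infeasible
#' (non positive-definite) latent correlation matrix is an error.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return an `osa_cohort` data frame (no audio references), with
#'   `split = "unassigned"`.
#' @export
sample_anthropometrics <- function(spec = synthetic_spec(), seed = 1) {
  n <- spec$n_non_osa + spec$n_osa
  w <- spec$n_non_osa / n

  # mixture quantile of AHI as a function of the uniform rank
  ahi_q <- function(u) {
    out <- numeric(length(u))
    lo <- u < w
    out[lo] <- rtruncnorm_q(u[lo] / w, spec$ahi_non[1], spec$ahi_non[2],
                            0, spec$threshold)
    out[!lo] <- rtruncnorm_q((u[!lo] - w) / (1 - w), spec$ahi_osa[1],
                             spec$ahi_osa[2], spec$threshold, Inf)
    out
  }
  # attenuation of a latent-normal correlation through the AHI marginal
  zg <- stats::qnorm(stats::ppoints(4096))
  ag <- ahi_q(stats::pnorm(zg))
  atten_ahi <- stats::cor(zg, ag)
  mps_cut <- stats::qnorm(cumsum(spec$mps_probs)[1:3])

  infl <- function(target, atten) min(target / atten, 0.97)
  r_bmi <- infl(spec$anthro_link[["bmi_ahi"]], atten_ahi)
  r_nc <- infl(spec$anthro_link[["nc_ahi"]], atten_ahi)
  r_mps <- infl(spec$anthro_link[["mps_ahi"]], atten_ahi)
  R <- rbind(c(1, r_bmi, r_nc, r_mps),
             c(r_bmi, 1, 0.55, 0.10),
             c(r_nc, 0.55, 1, 0.10),
             c(r_mps, 0.10, 0.10, 1))
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8)
    stop("infeasible anthropometric correlation targets ",
         "(latent matrix not positive definite)")

  set.seed(seed)
  z <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = R)
  u_ahi <- (rank(z[, 1], ties.method = "first") - 0.5) / n
  ahi <- ahi_q(u_ahi)
  group <- ifelse(ahi >= spec$threshold, "osa", "non_osa")
  bmi <- spec$bmi_marg[1] + spec$bmi_marg[2] * z[, 2]
  bmi <- pmax(16, bmi)
  nc <- spec$nc_marg[1] + spec$nc_marg[2] * z[, 3]
  nc <- pmax(28, nc)
  mps <- findInterval(z[, 4], mps_cut) + 1L
  sex <- ifelse(stats::runif(n) < spec$male_frac[group], "male", "female")
  age_par <- cbind(ifelse(group == "osa", spec$age_osa[1], spec$age_non[1]),
                   ifelse(group == "osa", spec$age_osa[2], spec$age_non[2]))
  age <- rtruncnorm_q(stats::runif(n), age_par[, 1], age_par[, 2], 18, 90)

  df <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    ahi = ahi, age = age, sex = sex, bmi = bmi, nc = nc, mps = mps,
    mouth_wav = NA_character_, nose_wav = NA_character_,
    split = "unassigned", stringsAsFactors = FALSE
  )
  suppressMessages(as_osa_cohort(df, threshold = spec$threshold))
}

#' Group-dependent spectral envelope (dB) on a frequency grid
#'
#' Sum of a low-frequency plateau, a cumulative slope term over the
#' contrast band (negative for non-OSA, positive for OSA), resonant
#' peaks (OSA resonances shifted upward), a high-band tilt, and a
#' gentle broadband decay. `params` carries the per-subject jittered
#' values.
#' @keywords internal
spectral_envelope_db <- function(freq, params) {
  p <- params
  env <- rep(-60, length(freq))
  rise <- pmin(freq / 60, 1)                  # onset below 60 Hz
  env <- -25 * rise - 55 * (1 - rise)
  ramp <- pmin(pmax(freq - p$band[1], 0), p$band[2] - p$band[1])
  env <- env + p$slope * ramp
  env <- env - 0.012 * pmax(freq - p$band[2], 0)   # broadband decay
  env <- env + p$r1_height * exp(-0.5 * ((freq - p$r1) / 60)^2)
  env <- env + p$r2_height * exp(-0.5 * ((freq - p$r2) / 140)^2)
  env <- env + 6 * exp(-0.5 * ((freq - 2250) / 100)^2)
  hi <- pmin(pmax(freq - 2100, 0), 300)
  env <- env + p$hi_tilt * hi
  pmax(env, -75)
}

#' @keywords internal
shaped_noise <- function(n, sample_rate, env_db_fun) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * sample_rate / n
  H <- 10^(env_db_fun(abs(f)) / 20)
  Re(stats::fft(X * H, inverse = TRUE)) / n
}

#' Synthesize one breathing-sound recording
#'
#' Shapes Gaussian noise through a group-dependent spectral envelope
#' and amplitude-modulates it into `n_cycles` inspiration/expiration
#' cycles separated by pauses, followed by a breath-hold (silent)
#' tail at the noise-floor level. Expiration is softer and its
#' resonances sit slightly lower; the mouth route lowers the first
#' resonance. The OSA envelope rises across the contrast band and its
#' resonances are shifted up; severity adds a mild log(AHI) gradient to
#' the contrast slope.
#'
#' @param group `"non_osa"` or `"osa"`.
#' @param spec a [synthetic_spec()].
#' @param maneuver `"mouth"` or `"nose"`.
#' @param seed integer seed (per subject/maneuver).
#' @param ahi subject AHI (drives the within-group severity gradient).
#' @return list with `samples`, `sample_rate`, and `boundaries`
#'   (data frame `phase,cycle,start_s,end_s` of ground truth).
#' @export
synthesize_breath_sound <- function(group, spec = synthetic_spec(),
                                    maneuver = "nose", seed = 1, ahi = NULL) {
  set.seed(seed)
  fs <- spec$sample_rate
  sgn <- if (group == "osa") 1 else -1
  sev <- if (is.null(ahi)) 0 else 0.008 * (log1p(ahi) - log1p(spec$threshold))
  slope <- sgn * spec$slope_magnitude + sev +
    stats::rnorm(1, 0, spec$slope_jitter)
  shift <- if (group == "osa") spec$resonance_shift else 0
  params <- list(
    band = spec$contrast_band,
    slope = slope,
    r1 = 480 + shift + stats::rnorm(1, 0, 18) -
      if (maneuver == "mouth") 40 else 0,
    r1_height = 12,
    r2 = 1250 + 2 * shift + stats::rnorm(1, 0, 45),
    r2_height = 8,
    hi_tilt = sgn * 0.008 + stats::rnorm(1, 0, 0.002)
  )
  n_burst <- round(spec$burst_s * fs)
  n_gap <- round(spec$gap_s * fs)
  n_sil <- round(spec$silence_s * fs)
  edge <- round(0.02 * fs)
  taper <- c(0.5 - 0.5 * cos(pi * seq_len(edge) / edge),
             rep(1, n_burst - 2 * edge),
             0.5 + 0.5 * cos(pi * seq_len(edge) / edge))

  floor_amp <- 10^(spec$noise_floor_db / 20)
  pieces <- list()
  bounds <- list()
  t_cursor <- 0
  for (cy in seq_len(spec$n_cycles)) {
    for (ph in c("inspiration", "expiration")) {
      amp <- if (ph == "inspiration") 1 else 0.7
      p2 <- params
      if (ph == "expiration") { p2$r1 <- p2$r1 - 30; p2$r2 <- p2$r2 - 60 }
      burst <- shaped_noise(n_burst, fs, function(f) spectral_envelope_db(f, p2))
      burst <- amp * burst / stats::sd(burst) * 0.05 * taper
      pieces[[length(pieces) + 1L]] <- burst
      bounds[[length(bounds) + 1L]] <- data.frame(
        phase = ph, cycle = cy, start_s = t_cursor,
        end_s = t_cursor + spec$burst_s)
      t_cursor <- t_cursor + spec$burst_s
      pieces[[length(pieces) + 1L]] <- stats::rnorm(n_gap, 0, 0.05 * floor_amp)
      t_cursor <- t_cursor + spec$gap_s
    }
  }
  pieces[[length(pieces) + 1L]] <- stats::rnorm(n_sil, 0, 0.05 * floor_amp)
  list(samples = unlist(pieces), sample_rate = fs,
       boundaries = do.call(rbind, bounds))
}

#' Generate a full synthetic cohort
#'
#' Samples anthropometrics, synthesizes mouth and nose recordings per
#' subject, and either keeps the audio in memory (`dir = NULL`) or
#' writes WAV files plus a `manifest.csv` in the cohort-manifest
#' dialect. Deterministic given `seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory for WAVs + manifest, or `NULL` to keep
#'   audio in memory (attribute `audio`).
#' @param seed integer seed.
#' @return an `osa_cohort`; with in-memory audio, attribute `audio` is
#'   a named list `subject_id -> list(mouth, nose)` of
#'   `samples`/`sample_rate`/`boundaries`, and attribute `boundaries`
#'   carries the ground-truth phase boundaries.
#' @export
generate_cohort <- function(spec = synthetic_spec(), dir = NULL, seed = 1) {
  cohort <- sample_anthropometrics(spec, seed = seed)
  audio <- vector("list", nrow(cohort))
  names(audio) <- cohort$subject_id
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  for (i in seq_len(nrow(cohort))) {
    rec <- list()
    for (mv in c("mouth", "nose")) {
      s <- synthesize_breath_sound(
        as.character(cohort$group[i]), spec, maneuver = mv,
        seed = seed + 7919L * i + (mv == "nose") * 104729L,
        ahi = cohort$ahi[i])
      rec[[mv]] <- s
      if (!is.null(dir)) {
        path <- file.path(dir, paste0(cohort$subject_id[i], "_", mv, ".wav"))
        write_wav(s$samples, path, s$sample_rate)
        cohort[[paste0(mv, "_wav")]][i] <- path
      }
    }
    audio[[i]] <- rec
  }
  if (!is.null(dir)) {
    utils::write.csv(
      cohort[, c("subject_id", "ahi", "age", "sex", "bmi", "nc", "mps",
                 "mouth_wav", "nose_wav", "split")],
      file.path(dir, "manifest.csv"), row.names = FALSE)
  } else {
    attr(cohort, "audio") <- audio
  }
  cohort
}
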