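test_that("PSD band statistics are exact on constant and linear spectra", {
  ps <- flat_psd(2)  # flat PSD of linear value 2
  band <- c(200, 400)
  expect_equal(psd_band_statistic(ps, band, "band_mean", "linear"), 2)
  expect_equal(psd_band_statistic(ps, band, "geometric_mean"), 2)
  expect_equal(psd_band_statistic(ps, band, "slope_mean"), 0)
  expect_equal(psd_band_statistic(ps, band, "centroid"), 300)

  # linearly increasing PSD: centroid and spread against a direct
  # summation oracle
  ps2 <- flat_psd()
  ps2$power <- 1 + ps2$freq / 1000
  idx <- which(ps2$freq >= 200 & ps2$freq <= 400)
  f <- ps2$freq[idx]; p <- ps2$power[idx]
  c_oracle <- sum(f * p) / sum(p)
  bw_oracle <- sqrt(sum((f - c_oracle)^2 * p) / sum(p))
  expect_equal(psd_band_statistic(ps2, band, "centroid"), c_oracle,
               tolerance = 1e-12)
  expect_equal(psd_band_statistic(ps2, band, "centroid_bandwidth"), bw_oracle,
               tolerance = 1e-12)

  expect_error(psd_band_statistic(ps, c(5000, 5001), "band_mean"),
               "fewer than 3")
})

test_that("peak-frequency operators find the first and the average peak", {
  ps <- flat_psd(1e-6)
  ps$power <- ps$power + 1e-4 * exp(-0.5 * ((ps$freq - 180) / 20)^2) +
    1e-4 * exp(-0.5 * ((ps$freq - 400) / 20)^2) +
    1e-4 * exp(-0.5 * ((ps$freq - 900) / 20)^2)
  expect_equal(psd_band_statistic(ps, NULL, "first_peak_freq", cutoff = 550),
               180)
  m <- psd_band_statistic(ps, c(100, 1000), "mean_max_peak_freq", "linear")
  expect_equal(m, mean(c(180, 400, 900)), tolerance = 0.05)
  # no qualifying peak: missing value with a reason flag
  flatv <- psd_band_statistic(flat_psd(), c(100, 1000), "mean_max_peak_freq",
                              "linear")
  expect_true(is.na(flatv))
})

test_that("band-mean differences compose from independent band means", {
  ps <- flat_psd()
  set.seed(9)
  ps$power <- 10^rnorm(length(ps$power), 0, 0.5)
  a <- c(130, 235); b <- c(1260, 1410)
  expect_equal(band_mean_difference(ps, a, b),
               psd_band_statistic(ps, a, "band_mean") -
                 psd_band_statistic(ps, b, "band_mean"))
  expect_equal(band_mean_difference(ps, a, a), 0)
})

test_that("bispectral line statistics match brute-force summation", {
  f <- seq(0, 1280, by = 10)
  n <- length(f)
  vals <- matrix(0, n, n)
  set.seed(5)
  vals[] <- abs(rnorm(n * n))
  vals <- (vals + t(vals)) / 2
  b <- structure(list(freq = f, values = vals, params = list()),
                 class = "bispec")
  band <- c(200, 400)
  fi <- f[f >= 200 & f <= 400]
  m <- vals[cbind(match(fi, f), match(fi, f))]
  expect_equal(bispectrum_line_statistic(b, "main_diagonal", band, "bis_mean"),
               mean(m))
  expect_equal(bispectrum_line_statistic(b, "main_diagonal", band,
                                         "bis_weight_center"),
               sum(fi * m) / sum(m), tolerance = 1e-12)
  expect_equal(bispectrum_line_statistic(b, "main_diagonal", band,
                                         "bis_moment1"),
               sum(fi * m) / length(m), tolerance = 1e-12)
  expect_equal(bispectrum_line_statistic(b, "main_diagonal", band,
                                         "bis_moment2"),
               sum(fi^2 * m) / length(m), tolerance = 1e-12)

  # half-f and negative-diagonal lines against hand-indexed samples
  m_half <- vals[cbind(match(fi, f), match(round(fi / 2 / 10) * 10, f))]
  expect_equal(bispectrum_line_statistic(b, "half_f_line", band, "bis_mean"),
               mean(m_half))
  m_neg <- vals[cbind(match(fi, f), match(600 - fi, f))]
  expect_equal(bispectrum_line_statistic(b, "negative_diagonal", band,
                                         "bis_mean"),
               mean(m_neg))

  # constant magnitude: weight centre is the band midpoint
  b2 <- b; b2$values <- matrix(1, n, n)
  expect_equal(bispectrum_line_statistic(b2, "main_diagonal", band,
                                         "bis_weight_center"), 300)

  # mass at a single diagonal point: weight centre sits there
  b3 <- b; b3$values <- matrix(0, n, n); b3$values[31, 31] <- 5  # 300 Hz
  expect_equal(bispectrum_line_statistic(b3, "main_diagonal", band,
                                         "bis_weight_center"), 300)

  expect_error(bispectrum_line_statistic(b, "main_diagonal", c(2000, 2100)),
               "band")
})

test_that("Katz dimension is exactly 1 for a straight line", {
  expect_equal(katz_fd(seq(0, 5, length.out = 300)), 1, tolerance = 1e-12)
  expect_equal(unname(fractal_features(rep(1, 256))["katz"]), 1)
})

test_that("Hurst estimation recovers long-range dependence", {
  h <- vapply(1:12, function(s) hurst_rs(fgn_sim(4096, 0.8, seed = s))$hurst, 0)
  expect_lt(abs(mean(h) - 0.8), 0.1)
  expect_true(is.na(hurst_rs(rep(2, 256))$hurst))
})

test_that("the corrected R/S exponent agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  for (s in c(2, 5)) {
    x <- fgn_sim(4096, 0.7, seed = s)
    ours <- hurst_rs(x)$hurst
    ref <- suppressWarnings(pracma::hurstexp(x, display = FALSE))$Hal
    expect_lt(abs(ours - ref), 0.1)
  }
})

test_that("feature matrix assembly is deterministic and handles missing maneuvers", {
  defs <- feature_catalog()[c(1, 2, 10, 30, 67, 69, 70, 137), ]
  set.seed(8)
  mk_subject <- function(with_mouth = TRUE) {
    mp <- function() {
      ps <- flat_psd()
      ps$power <- 10^rnorm(length(ps$power), -3, 0.3)
      f <- seq(0, 5120, by = 40)
      list(psd = ps,
           bis = structure(list(freq = f,
                                values = matrix(abs(rnorm(length(f)^2)),
                                                length(f)),
                                params = list()), class = "bispec"),
           fractal = list(katz = 1.02, higuchi = 1.9, hurst = 0.5))
    }
    out <- list(nose_inspiration = mp(), nose_expiration = mp())
    if (with_mouth) {
      out$mouth_inspiration <- mp()
      out$mouth_expiration <- mp()
    }
    out
  }
  subs <- setNames(lapply(1:10, function(i) mk_subject()), paste0("S", 1:10))
  ft <- build_feature_matrix(subs, defs)
  expect_equal(dim(ft$values), c(10, 8))
  expect_false(anyNA(ft$values))
  ft2 <- build_feature_matrix(subs, defs)
  expect_identical(ft$values, ft2$values)

  # a subject lacking mouth audio keeps its row, mouth features missing
  subs$S1 <- mk_subject(with_mouth = FALSE)
  expect_warning(ft3 <- build_feature_matrix(subs, defs), "lack")
  mouth_cols <- defs$feature_id[defs$maneuver == "mouth"]
  expect_true(all(is.na(ft3$values["S1", mouth_cols])))
  expect_false(anyNA(ft3$values["S1", setdiff(colnames(ft3$values),
                                              mouth_cols)]))
})

test_that("the default catalog spans the expected feature count and operators", {
  cat <- feature_catalog()
  expect_gte(nrow(cat), 200)
  expect_lte(nrow(cat), 300)
  expect_false(any(duplicated(cat$feature_id)))
  expect_true(all(cat$operator[cat$source == "bispectrum"] %in%
                    c("bis_mean", "bis_weight_center", "bis_moment1",
                      "bis_moment2")))
  # extra (discovered) bands append PSD features
  eb <- data.frame(f_lo = 250, f_hi = 350, maneuver = "nose",
                   phase = "inspiration")
  cat2 <- feature_catalog(extra_bands = eb)
  expect_equal(nrow(cat2), nrow(cat) + 3)
})

test_that("unit-interval scaling learns on training rows and clips test rows", {
  v <- matrix(c(2, 4, 6, 8,
                1, 1, 1, 1,
                0, 5, 10, -5), ncol = 3,
              dimnames = list(paste0("S", 1:4), c("a", "const", "b")))
  ft <- structure(list(values = v,
                       definitions = data.frame(feature_id = colnames(v)),
                       scaling = NULL, provenance = "raw"),
                  class = "feature_table")
  expect_warning(sc <- scale_unit_interval(ft, c("S1", "S2", "S3")),
                 "constant")
  expect_false("const" %in% colnames(sc$values))
  expect_equal(unname(sc$values[1:3, "a"]), c(0, 0.5, 1))
  # test row 8 with training range (2, 6): clipped to 1
  expect_equal(unname(sc$values["S4", "a"]), 1)
  expect_equal(unname(sc$values["S4", "b"]), 0)
  expect_true(all(sc$values[1:3, ] >= 0 & sc$values[1:3, ] <= 1))

  # idempotence: re-scaling a scaled table with its own parameters
  sc2 <- scale_unit_interval(sc, c("S1", "S2", "S3"))
  expect_equal(sc2$values, sc$values)
})
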