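test_that("manifest loading validates fields and reports severity counts", {
  df <- make_manifest_df(199, ahi = c(seq(0, 14.5, length.out = 109),
                                      seq(15, 80, length.out = 90)))
  co <- suppressMessages(load_manifest(write_manifest(df)))
  expect_s3_class(co, "osa_cohort")
  expect_equal(as.vector(table(co$group)), c(109, 90))

  empty <- tempfile(fileext = ".csv")
  writeLines(character(), empty)
  expect_error(load_manifest(empty))

  df2 <- make_manifest_df(4)
  df2$mps[3] <- 5
  expect_error(suppressMessages(load_manifest(write_manifest(df2))), "row.*3")

  df3 <- make_manifest_df(4)
  df3$subject_id[2] <- df3$subject_id[1]
  expect_error(suppressMessages(load_manifest(write_manifest(df3))),
               "duplicate")

  df4 <- make_manifest_df(4)[, -2]
  expect_error(load_manifest(write_manifest(df4)), "missing required column")
})

test_that("WAV round trip preserves length, rate and samples", {
  fs <- 10240
  x <- 0.5 * sin(2 * pi * 220 * (0:(10 * fs - 1)) / fs)
  path <- tempfile(fileext = ".wav")
  write_wav(x, path, fs)
  w <- load_audio(path)
  expect_length(w$samples, 10 * fs)
  expect_equal(w$sample_rate, fs)
  expect_lt(max(abs(w$samples - x)), 1 / 32767)
})

test_that("stereo files require and honour a channel selector", {
  # hand-built 2-channel 16-bit PCM WAV
  fs <- 8000
  left <- round(1000 * sin(2 * pi * 100 * (0:799) / fs))
  right <- round(2000 * sin(2 * pi * 200 * (0:799) / fs))
  inter <- as.integer(rbind(left, right))
  path <- tempfile(fileext = ".wav")
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(inter)), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(c(1, 2)), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 4), con, 4, endian = "little")
  writeBin(as.integer(c(4, 16)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(inter)), con, 4, endian = "little")
  writeBin(inter, con, 2, endian = "little")
  close(con)

  expect_error(read_wav(path), "channel")
  w <- read_wav(path, channel = 1)
  expect_equal(w$samples * 32768, left, tolerance = 1e-9)

  # truncated file: cut the data chunk short
  raw <- readBin(path, "raw", file.size(path))
  short <- tempfile(fileext = ".wav")
  writeBin(raw[1:(length(raw) - 400)], short)
  expect_error(read_wav(short), "truncated")
})

test_that("segmentation recovers constructed phase boundaries within 50 ms", {
  rec <- make_burst_recording(n_bursts = 10)
  seg <- segment_phases(rec$samples, rec$sample_rate)
  expect_length(seg$phases, 10)
  expect_equal(sum(vapply(seg$phases, function(p) p$phase, "") == "inspiration"), 5)
  expect_lt(max(abs(seg$boundaries$start_s - rec$boundaries$start_s)), 0.05)
  expect_lt(max(abs(seg$boundaries$end_s - rec$boundaries$end_s)), 0.05)
  expect_false(is.null(seg$silent))
  # protocol-conformant recording: at most 2 phases per cycle, 5 cycles
  expect_lte(length(seg$phases), 10)
  # first phase is inspiration, labels alternate
  labs <- vapply(seg$phases, function(p) p$phase, "")
  expect_identical(labs[1], "inspiration")
  expect_true(all(labs[-1] != labs[-length(labs)]))
})

test_that("degenerate signals yield zero phases with a warning", {
  expect_warning(out <- segment_phases(numeric(10240 * 3), 10240), "no breath")
  expect_length(out$phases, 0)
})

test_that("manual boundaries override automatic segmentation", {
  rec <- make_burst_recording(n_bursts = 4)
  man <- rec$boundaries
  man$start_s <- man$start_s + 0.01
  seg <- segment_phases(rec$samples, rec$sample_rate, boundaries = man)
  expect_equal(seg$boundaries$start_s, man$start_s)
})

test_that("quality screening rejects low-SNR and clipped phases, and is idempotent", {
  fs <- 10240
  silent <- list(samples = 0.01 * rnorm(2 * fs), sample_rate = fs)
  mk <- function(amp) list(samples = amp * rnorm(fs), sample_rate = fs,
                           phase = "inspiration", cycle = 1L,
                           start_s = 0, end_s = 1,
                           quality = "clean", reason = NA_character_)
  # SNR = 20 log10(amp/0.01): 3 dB at amp ~ 0.0141 -> rejected at 10 dB floor
  phases <- list(mk(0.0141), mk(0.2), mk(0.2), mk(0.2))
  out <- screen_quality(phases, silent)
  expect_identical(out[[1]]$quality, "rejected")
  expect_identical(out[[1]]$reason, "low_snr")
  expect_true(all(vapply(out[-1], function(p) p$quality, "") == "clean"))

  clipped <- mk(0.2)
  clipped$samples[1:500] <- 1
  out2 <- screen_quality(list(clipped), silent)
  expect_identical(out2[[1]]$reason, "clipping")

  # idempotence
  again <- screen_quality(out, silent)
  expect_identical(lapply(again, `[[`, "quality"),
                   lapply(out, `[[`, "quality"))
})

test_that("a subject needs two clean cycles per phase type to be included", {
  fs <- 10240
  silent <- list(samples = 0.01 * rnorm(fs), sample_rate = fs)
  mk <- function(ph, amp) list(samples = amp * rnorm(fs), sample_rate = fs,
                               phase = ph, cycle = 1L, start_s = 0, end_s = 1,
                               quality = "clean", reason = NA_character_)
  good <- list(mk("inspiration", 0.2), mk("expiration", 0.2),
               mk("inspiration", 0.2), mk("expiration", 0.2))
  expect_true(attr(screen_quality(good, silent), "include"))
  one_clean <- list(mk("inspiration", 0.2), mk("expiration", 0.2),
                    mk("inspiration", 0.012), mk("expiration", 0.2))
  expect_false(attr(screen_quality(one_clean, silent), "include"))
})

test_that("cohort splitting follows the threshold and feature-extraction bounds", {
  df <- make_manifest_df(4, ahi = c(3, 12, 17, 25))
  co <- suppressMessages(load_manifest(write_manifest(df)))
  expect_equal(as.character(co$group), c("non_osa", "non_osa", "osa", "osa"))
  co$split <- "train"
  sp <- split_cohort(co, threshold = 15, fe_bounds = c(10, 20))
  expect_equal(co$subject_id[sp$feature_extraction], co$subject_id[c(1, 4)])

  # explicit split column is honoured verbatim
  co2 <- co
  co2$split <- c("train", "test", "train", "test")
  sp2 <- split_cohort(co2)
  expect_equal(sp2$split, co2$split)

  # every subject lands in exactly one of train/test
  df3 <- make_manifest_df(30, ahi = c(seq(1, 9, length.out = 15),
                                      seq(21, 60, length.out = 15)))
  co3 <- suppressMessages(load_manifest(write_manifest(df3)))
  sp3 <- split_cohort(co3, seed = 4)
  expect_true(all(sp3$split %in% c("train", "test")))
})
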