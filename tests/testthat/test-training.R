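test_that("subset predicates assign members as the anthropometric rules say", {
  df <- make_manifest_df(1)
  df$age <- 45; df$sex <- "male"; df$bmi <- 30; df$nc <- 42; df$mps <- 2
  co <- suppressMessages(load_manifest(write_manifest(df)))
  co$feature_extraction <- TRUE
  mem <- suppressWarnings(build_subsets(co))
  in_subset <- vapply(mem, function(m) df$subject_id %in% m$members,
                      logical(1))
  expect_true(all(in_subset[c("bmi_lt_35", "age_le_50", "male", "nc_gt_40",
                              "mps_le_2")]))
  expect_false(in_subset["age_gt_50"])

  # small feature-extraction groups trigger a warning
  df2 <- make_manifest_df(20, ahi = c(rep(2, 12), rep(30, 8)))
  co2 <- suppressMessages(load_manifest(write_manifest(df2)))
  co2$feature_extraction <- TRUE
  w <- testthat::capture_warnings(build_subsets(co2))
  expect_true(any(grepl("small feature-extraction", w)))

  # unknown field in a predicate errors
  bad <- data.frame(name = "x", field = "shoe_size", op = "<",
                    threshold = "10", include_nc = FALSE)
  expect_error(build_subsets(co2, bad), "unknown anthropometric field")
})

test_that("adjacent values equal boxplot whisker ends", {
  lab <- factor(rep(c("non_osa", "osa"), each = 5),
                levels = c("non_osa", "osa"))
  v <- cbind(f = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 100))
  fen <- outlier_fences(v, lab)
  # group 1 has no outliers: fences at the data extremes
  expect_equal(unname(fen$per_group$non_osa[, "f"]), c(1, 5))
  # 100 exceeds Q3 + 1.5 IQR of group 2 (type-7 quartiles): upper adjacent 4
  q <- quantile(c(1, 2, 3, 4, 100), c(0.25, 0.75), type = 7)
  expect_gt(100, q[2] + 1.5 * diff(q))
  expect_equal(unname(fen$per_group$osa[2, "f"]), 4)
  # merged fence: min of lowers, max of uppers
  expect_equal(unname(fen$lower["f"]), 1)
  expect_equal(unname(fen$upper["f"]), 5)

  # fencing marks out-of-bound test values missing, and is idempotent
  test_v <- cbind(f = c(0.5, 3, 60))
  fenced <- apply_fences(test_v, fen)
  expect_true(is.na(fenced[1, "f"]) && is.na(fenced[3, "f"]))
  expect_equal(unname(fenced[2, "f"]), 3)
  expect_identical(apply_fences(fenced, fen), fenced)

  # constant feature: fence collapses to the constant
  vc <- cbind(g = rep(2, 10))
  fc <- outlier_fences(vc, lab)
  expect_equal(unname(c(fc$lower["g"], fc$upper["g"])), c(2, 2))
})

test_that("adjacent values match a brute-force quartile oracle on random data", {
  set.seed(77)
  lab <- factor(rep(c("non_osa", "osa"), each = 500),
                levels = c("non_osa", "osa"))
  x <- c(rt(500, df = 3), rt(500, df = 3) + 1)   # heavy tails: real outliers
  fen <- outlier_fences(cbind(f = x), lab)
  oracle <- function(v) {
    s <- sort(v)
    # type-7 quartiles by hand: linear interpolation at h = (n-1)p + 1
    qt <- function(p) {
      h <- (length(s) - 1) * p + 1
      s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
    }
    q1 <- qt(0.25); q3 <- qt(0.75); iqr <- q3 - q1
    range(s[s >= q1 - 1.5 * iqr & s <= q3 + 1.5 * iqr])
  }
  o1 <- oracle(x[1:500]); o2 <- oracle(x[501:1000])
  expect_equal(unname(fen$per_group$non_osa[, "f"]), o1, tolerance = 1e-12)
  expect_equal(unname(fen$per_group$osa[, "f"]), o2, tolerance = 1e-12)
  expect_equal(unname(fen$lower["f"]), min(o1[1], o2[1]))
  expect_equal(unname(fen$upper["f"]), max(o1[2], o2[2]))
})

test_that("combination enumeration counts and constraints are exact", {
  expect_length(enumerate_combinations(paste0("f", 1:5)), 15)   # C(5,3)+C(5,4)
  expect_length(enumerate_combinations(paste0("f", 1:3)), 1)
  expect_length(enumerate_combinations(paste0("f", 1:5), include_nc = TRUE), 35)
  expect_error(enumerate_combinations(c("a", "b")), "at least 3")

  # alternative features never co-occur
  cb <- enumerate_combinations(paste0("f", 1:5),
                               exclusive_pairs = list(c("f1", "f2")))
  expect_false(any(vapply(cb, function(x) all(c("f1", "f2") %in% x),
                          logical(1))))
})

test_that("out-of-bag random forests separate designed classes and are
           deterministic", {
  set.seed(5)
  lab <- factor(rep(c("non_osa", "osa"), each = 25),
                levels = c("non_osa", "osa"))
  x <- data.frame(a = rnorm(50) + 6 * (lab == "osa"),
                  b = rnorm(50) + 6 * (lab == "osa"),
                  c = rnorm(50))
  rownames(x) <- paste0("S", 1:50)
  tr <- train_random_forest_oob(x, lab, num_trees = 300, seed = 3)
  expect_gte(tr$oob_accuracy, 0.95)
  expect_true(all(c(tr$oob_sensitivity, tr$oob_specificity) >= 0,
                  c(tr$oob_sensitivity, tr$oob_specificity) <= 1))
  tr2 <- train_random_forest_oob(x, lab, num_trees = 300, seed = 3)
  expect_identical(tr[c("oob_accuracy", "oob_sensitivity", "oob_specificity")],
                   tr2[c("oob_accuracy", "oob_sensitivity", "oob_specificity")])
  expect_error(train_random_forest_oob(x, factor(rep("osa", 50))), "class")
})

test_that("with cost compensation, permuted labels stay near chance", {
  set.seed(6)
  x <- data.frame(a = rnorm(60), b = rnorm(60))
  lab <- factor(rep(c("non_osa", "osa"), c(36, 24)),
                levels = c("non_osa", "osa"))
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    train_random_forest_oob(x, sample(lab), num_trees = 150,
                            seed = s)$oob_accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("combination scoring keeps strong combinations and orders do not
           matter", {
  set.seed(8)
  n <- 60
  lab <- factor(rep(c("non_osa", "osa"), each = n / 2),
                levels = c("non_osa", "osa"))
  v <- cbind(g1 = rnorm(n) + 5 * (lab == "osa"),
             g2 = rnorm(n) + 5 * (lab == "osa"),
             g3 = rnorm(n) + 5 * (lab == "osa"),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  rownames(v) <- paste0("S", 1:n)
  combos <- list(c("g1", "g2", "g3"), c("n1", "n2", "n3"))
  sc <- score_combinations(v, lab, combos, reps = 3, num_trees = 200, seed = 4)
  ids <- vapply(sc$shortlist, paste, "", collapse = "+")
  expect_true("g1+g2+g3" %in% ids)
  expect_false("n1+n2+n3" %in% ids)

  # scoring is invariant to the order combinations are listed in
  sc_rev <- score_combinations(v, lab, rev(combos), reps = 3,
                               num_trees = 200, seed = 4)
  expect_setequal(ids, vapply(sc_rev$shortlist, paste, "", collapse = "+"))

  # all-noise candidates: nothing reaches the 0.7 floor
  expect_warning(
    out <- score_combinations(v, lab, list(c("n1", "n2", "n3")), reps = 3,
                              num_trees = 200, seed = 4),
    "repetition metrics|scored")
  expect_length(out$shortlist, 0)
})

test_that("final selection prefers the higher-accuracy combination", {
  set.seed(9)
  n <- 60
  lab <- factor(rep(c("non_osa", "osa"), each = n / 2),
                levels = c("non_osa", "osa"))
  v <- cbind(strong1 = rnorm(n) + 5 * (lab == "osa"),
             strong2 = rnorm(n) + 5 * (lab == "osa"),
             strong3 = rnorm(n) + 5 * (lab == "osa"),
             weak1 = rnorm(n) + 0.8 * (lab == "osa"),
             weak2 = rnorm(n) + 0.8 * (lab == "osa"),
             weak3 = rnorm(n) + 0.8 * (lab == "osa"))
  rownames(v) <- paste0("S", 1:n)
  model <- select_final_combination(
    v, lab, list(c("weak1", "weak2", "weak3"),
                 c("strong1", "strong2", "strong3")),
    reps = 5, num_trees = 200, seed = 2)
  expect_s3_class(model, "subset_model")
  expect_equal(model$combination, c("strong1", "strong2", "strong3"))
  expect_true(model$oob_accuracy >= 0 && model$oob_accuracy <= 1)
  expect_named(model$oob_predictions)
  expect_error(select_final_combination(v, lab, list()), "empty")
})
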