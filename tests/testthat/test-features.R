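test_that("feature registry partitions 55 names into 32 linear + 23 nonlinear", {
  nm <- feature_names()
  expect_length(nm, 55)
  expect_false(anyDuplicated(nm) > 0)
  for (ch in c("X", "Y", "Z", "RV"))
    expect_length(grep(paste0("^", ch, "_"), nm), 13)
  expect_length(grep("^XCORR_", nm), 3)

  cls <- feature_classes()
  expect_equal(sum(cls == "linear"), 32)
  expect_equal(sum(cls == "nonlinear"), 23)
  expect_setequal(names(cls), nm)
  # the published equations respect the partition
  expect_true(all(cls[c("RV_75-25", "Y_VAR", "Y_SD")] == "linear"))
  expect_true(all(cls[c("RV_DYN", "RV_ND1", "Y_DYN")] == "nonlinear"))
})

test_that("dispersion_stats matches the n-1 loop formula", {
  expect_equal(dispersion_stats(c(1, 1, 1, 1)), list(SD = 0, VAR = 0))
  expect_equal(dispersion_stats(c(0, 2)), list(SD = sqrt(2), VAR = 2))
  expect_error(dispersion_stats(1), "at least 2")

  set.seed(10)
  for (i in 1:20) {
    s <- rnorm(sample(10:200, 1))
    n <- length(s)
    v_loop <- 0
    for (x in s) v_loop <- v_loop + (x - mean(s))^2 / n
    v_loop <- v_loop * n / (n - 1)
    expect_equal(dispersion_stats(s)$VAR, v_loop)
    expect_equal(dispersion_stats(s)$SD, sqrt(v_loop))
  }
})

test_that("percentile_stats uses linear interpolation between order stats", {
  p <- percentile_stats(1:5)
  expect_equal(p$P50, 3)
  expect_equal(p$P25, 2)
  expect_equal(p$P75, 4)
  expect_equal(p$`75-25`, 2)
  expect_equal(p$P10, 1.4)  # type-7: 1 + 0.4 * (2 - 1)

  const <- percentile_stats(rep(7, 50))
  expect_true(all(unlist(const[c("P10", "P25", "P50", "P75", "P90")]) == 7))
  expect_equal(const$`75-25`, 0)

  set.seed(11)
  s <- runif(101)
  expect_true(with(percentile_stats(s), P10 <= P25 && P25 <= P50 &&
                     P50 <= P75 && P75 <= P90))
})

test_that("lag_one_correlation captures temporal dynamics", {
  expect_equal(lag_one_correlation(1:60), 1.0)
  expect_equal(lag_one_correlation(rep(c(1, -1), 30)), -1.0)
  expect_warning(r0 <- lag_one_correlation(rep(2, 10)), "constant")
  expect_equal(r0, 0)

  # AR(1) consistency: phi = 0.8 recovered within 0.05 across seeds
  est <- vapply(1:100, function(seed) {
    set.seed(seed)
    s <- as.numeric(stats::filter(rnorm(3000), 0.8, method = "recursive"))
    lag_one_correlation(s)
  }, 0)
  expect_true(all(abs(est - 0.8) < 0.05))
})

test_that("wavelet norms conserve energy under periodization", {
  z <- wavelet_norms(numeric(64))
  expect_equal(unlist(z), c(ND1 = 0, ND2 = 0, NA2 = 0))

  set.seed(12)
  for (i in 1:50) {
    n <- sample(c(16, 24, 64, 120, 600), 1)
    s <- rnorm(n)
    w <- wavelet_norms(s)
    expect_equal(w$ND1^2 + w$ND2^2 + w$NA2^2, sum(s^2), tolerance = 1e-8)
  }

  # constant signal: all detail vanishes, NA2 = 2c * sqrt(n/4)
  w <- wavelet_norms(rep(3, 64))
  expect_equal(w$ND1, 0, tolerance = 1e-12)
  expect_equal(w$ND2, 0, tolerance = 1e-12)
  expect_equal(w$NA2, 2 * 3 * sqrt(64 / 4))
  expect_error(wavelet_norms(1:3), "at least 4")
})

test_that("sample_entropy equals the brute-force template counter", {
  expect_warning(e0 <- sample_entropy(rep(1, 30)), "constant")
  expect_equal(e0, 0)

  for (seed in 1:50) {
    set.seed(seed)
    s <- runif(120)
    r <- 0.3 * sd(s)
    cnt <- sampen_bruteforce(s, m = 2, r = r)
    expect_equal(sample_entropy(s), -log(cnt["A"] / cnt["B"]),
                 ignore_attr = TRUE)
  }
})

test_that("sample_entropy of a strict period-2 alternation is 0", {
  s <- rep(c(0, 1), 6)  # n = 12, tolerance 0.3 * SD well below amplitude
  # every m-template match is between samples of equal phase, so its
  # m+1 extension matches too: A = B, SampEn = -ln(1) = 0
  cnt <- sampen_bruteforce(s, m = 2, r = 0.3 * sd(s))
  expect_equal(cnt[["A"]], cnt[["B"]])
  expect_equal(sample_entropy(s), 0)
})

test_that("sample_entropy applies the A = 0 cap", {
  # repeated (1,1) templates whose third samples always differ by more
  # than the tolerance: B > 0 but A = 0
  s <- c(1, 1, 2, 1, 1, 3, 1, 1, 4, 1, 1, 5)
  cnt <- sampen_bruteforce(s, m = 2, r = 0.3 * sd(s))
  expect_gt(cnt[["B"]], 0)
  expect_equal(cnt[["A"]], 0)
  expect_warning(e <- sample_entropy(s), "cap")
  n <- length(s); m <- 2
  expect_equal(e, -log(2 / ((n - m - 1) * (n - m))))
})

test_that("cross_correlation is symmetric zero-lag Pearson", {
  set.seed(13)
  s <- rnorm(100); t <- rnorm(100)
  expect_equal(cross_correlation(s, s), 1)
  expect_equal(cross_correlation(s, -s), -1)
  expect_equal(cross_correlation(s, t), cross_correlation(t, s))
  expect_warning(c0 <- cross_correlation(rep(1, 10), rnorm(10)), "constant")
  expect_equal(c0, 0)
})

test_that("extract_features returns 55 canonically named values", {
  w <- make_window(n = 120, seed = 21)
  fv <- extract_features(w)
  expect_length(fv, 55)
  expect_equal(names(fv), feature_names())
  expect_equal(fv, extract_features(w))  # deterministic

  expect_equal(fv[["X_VAR"]], fv[["X_SD"]]^2)
  q <- fv[c("Y_P10", "Y_P25", "Y_P50", "Y_P75", "Y_P90")]
  expect_true(all(diff(q) >= 0))
  expect_true(all(fv[c("X_SD", "RV_ND1", "Z_NA2", "Y_SAMPEN")] >= 0))
  expect_true(all(abs(fv[c("X_DYN", "XCORR_XY", "XCORR_YZ")]) <= 1))
})

test_that("identical axes give unit cross-correlations", {
  set.seed(22)
  x <- rnorm(60)
  fv <- extract_features(list(X = x, Y = x, Z = x, RV = sqrt(3) * abs(x)))
  expect_equal(unname(fv[c("XCORR_XY", "XCORR_YZ", "XCORR_XZ")]), c(1, 1, 1))
})

test_that("features scale as expected under channel rescaling", {
  w <- make_window(n = 240, seed = 23)
  fv1 <- extract_features(w)
  c_ <- 4  # power of two: rescaling is exact in floating point
  fv2 <- extract_features(lapply(w, `*`, c_))
  scale_c <- unlist(lapply(c("X", "Y", "Z", "RV"), function(ch)
    paste(ch, c("SD", "75-25", "ND1", "ND2", "NA2"), sep = "_")))
  scale_c2 <- paste(c("X", "Y", "Z", "RV"), "VAR", sep = "_")
  invar <- c(paste(c("X", "Y", "Z", "RV"), "DYN", sep = "_"),
             paste(c("X", "Y", "Z", "RV"), "SAMPEN", sep = "_"),
             "XCORR_XY", "XCORR_YZ", "XCORR_XZ")
  expect_equal(fv2[scale_c], c_ * fv1[scale_c])
  expect_equal(fv2[scale_c2], c_^2 * fv1[scale_c2])
  expect_equal(fv2[invar], fv1[invar])
})

test_that("per-feature values agree with the independent per-stat oracles", {
  w <- make_window(n = 120, seed = 24)
  fv <- extract_features(w)
  expect_equal(fv[["Z_SD"]], sd(w$Z))
  expect_equal(fv[["RV_P90"]], unname(quantile(w$RV, 0.9, type = 7)))
  expect_equal(fv[["Y_DYN"]],
               cor(w$Y[-length(w$Y)], w$Y[-1]))
  expect_equal(fv[["X_SAMPEN"]],
               {cnt <- sampen_bruteforce(w$X, 2, 0.3 * sd(w$X))
                -log(cnt[["A"]] / cnt[["B"]])})
  expect_equal(fv[["XCORR_XZ"]], cor(w$X, w$Z))
})

test_that("extract_feature_table binds windows with their metadata", {
  s <- make_tiny_session(n_act = 2, dur_s = 120, rate = 20,
                         vo2_levels = c(4, 8))
  tab <- extract_feature_table(segment_minutes(s))
  expect_equal(nrow(tab), 4)
  expect_equal(colnames(tab),
               c(feature_names(), "label", "type", "vo2", "participant_id"))
  expect_equal(tab$vo2, c(4, 4, 8, 8))

  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_equal(colnames(back), colnames(tab))
  expect_equal(back$`RV_75-25`, tab$`RV_75-25`)
})
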