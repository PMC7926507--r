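# helper: a feature table with independent standard-normal columns for
# every canonical feature, so designed truths are easy to plant
make_feature_table <- function(n = 200, seed = 1) {
  set.seed(seed)
  tab <- as.data.frame(matrix(rnorm(n * 55), ncol = 55,
                              dimnames = list(NULL, feature_names())),
                       check.names = FALSE)
  tab$label <- sample(c("a", "b", "c"), n, replace = TRUE)
  tab$type <- "Housework"
  tab$participant_id <- sprintf("P%02d", sample(1:10, n, replace = TRUE))
  tab
}

test_that("kfold_split makes near-equal deterministic folds", {
  f <- kfold_split(100, k = 10, seed = 3)
  expect_equal(as.integer(table(f)), rep(10L, 10))

  f2 <- kfold_split(103, k = 10, seed = 3)
  expect_true(all(table(f2) %in% c(10L, 11L)))
  expect_lte(diff(range(table(f2))), 1)

  expect_equal(kfold_split(103, seed = 7), kfold_split(103, seed = 7))
  expect_false(identical(kfold_split(103, seed = 7), kfold_split(103, seed = 8)))
  expect_error(kfold_split(5, k = 10), "at least")
})

test_that("grouped folding keeps participants intact", {
  g <- rep(sprintf("P%02d", 1:20), each = 50)
  f <- kfold_split(length(g), k = 10, seed = 1, groups = g)
  expect_equal(length(unique(paste(g, f))), 20)  # one fold per participant
})

test_that("fit_ols recovers a noiseless planted equation", {
  tab <- make_feature_table(n = 300, seed = 5)
  tab$vo2 <- 3.4921 + 10.784 * tab$`RV_75-25` - 25.4524 * tab$Y_VAR +
    21.0447 * tab$Y_SD
  m <- fit_ols(tab, c("RV_75-25", "Y_VAR", "Y_SD"))
  expect_equal(m$intercept, 3.4921, tolerance = 1e-6)
  expect_equal(unname(m$terms), c(10.784, -25.4524, 21.0447),
               tolerance = 1e-6)
})

test_that("fit_ols handles degenerate designs and constants", {
  tab <- make_feature_table(n = 50, seed = 6)
  tab$vo2 <- rep(7, 50)
  m <- fit_ols(tab, c("X_SD", "Z_P50"))
  expect_equal(m$intercept, 7)
  expect_equal(unname(m$terms), c(0, 0), tolerance = 1e-10)

  # single predictor equals the closed-form simple-regression slope
  tab$vo2 <- rnorm(50)
  m1 <- fit_ols(tab, "X_SD")
  expect_equal(unname(m1$terms),
               cov(tab$X_SD, tab$vo2) / var(tab$X_SD))

  tab$Y_VAR <- 2 * tab$Y_SD  # perfectly collinear pair
  expect_error(fit_ols(tab, c("Y_SD", "Y_VAR")), "Y_VAR")
})

test_that("predict.ee_model evaluates the affine equation", {
  m <- published_models()$all
  z <- setNames(numeric(55), feature_names())
  expect_equal(predict(m, z), 3.4921)
  z["RV_75-25"] <- 1
  expect_equal(predict(m, z), 3.4921 + 10.784)
  expect_error(predict(m, c(Y_VAR = 0)), "RV_75-25")

  # affine linearity over term-wise sums
  set.seed(9)
  a <- setNames(rnorm(55), feature_names())
  b <- setNames(rnorm(55), feature_names())
  expect_equal(predict(m, a) + predict(m, b) - m$intercept,
               predict(m, a + b))
})

test_that("published models carry the printed coefficients", {
  pm <- published_models()
  expect_named(pm, c("all", "linear", "nonlinear"))
  for (m in pm) expect_length(m$terms, 3)
  z <- as.data.frame(matrix(0, 1, 55, dimnames = list(NULL, feature_names())),
                     check.names = FALSE)
  expect_equal(predict(pm$all, z), 3.4921)
  expect_equal(predict(pm$linear, z), 3.4921)
  expect_equal(predict(pm$nonlinear, z), -343.0891)
  # the class partition is respected
  cls <- feature_classes()
  expect_true(all(cls[names(pm$linear$terms)] == "linear"))
  expect_true(all(cls[names(pm$nonlinear$terms)] == "nonlinear"))
  # pure function: bit-identical repeat evaluation
  set.seed(10)
  fv <- setNames(runif(55), feature_names())
  expect_identical(predict(pm$all, fv), predict(pm$all, fv))
})

test_that("metrics matches explicit loop formulas", {
  obs <- c(4, 6, 8, 10)
  expect_equal(metrics(obs, obs), list(r = 1, mse = 0, mae = 0))
  off <- metrics(obs + 1, obs)
  expect_equal(off[c("r", "mse", "mae")], list(r = 1, mse = 1, mae = 1))

  set.seed(11)
  p <- rnorm(100); o <- rnorm(100)
  got <- metrics(p, o)
  mse_loop <- 0; mae_loop <- 0
  for (i in 1:100) {
    mse_loop <- mse_loop + (p[i] - o[i])^2 / 100
    mae_loop <- mae_loop + abs(p[i] - o[i]) / 100
  }
  expect_equal(got$mse, mse_loop)
  expect_equal(got$mae, mae_loop)
  expect_equal(got$r, cor(p, o))
  expect_warning(m0 <- metrics(rep(1, 5), rnorm(5)), "constant")
  expect_equal(m0$r, 0)
})

test_that("forward_select finds planted predictors on orthogonal designs", {
  # orthogonalized predictors: greedy is provably exact
  n <- 64
  tab <- make_feature_table(n = n, seed = 12)
  q <- qr.Q(qr(matrix(rnorm(n * 55), n, 55)))
  tab[feature_names()] <- as.data.frame(q)
  tab$vo2 <- 5 + 4 * tab$X_P50 - 3 * tab$Z_SAMPEN + 2 * tab$`RV_75-25`
  sel <- forward_select(tab, "all", max_k = 3)
  expect_setequal(sel, c("X_P50", "Z_SAMPEN", "RV_75-25"))
  # greedy adds in order of explained variance
  expect_equal(sel[1], "X_P50")

  # max_k = 1 equals the highest squared correlation with the response
  tab2 <- make_feature_table(n = 150, seed = 13)
  tab2$vo2 <- 2 * tab2$Y_DYN + rnorm(150, 0, 0.5)
  best <- names(which.max(vapply(feature_names(), function(f)
    cor(tab2[[f]], tab2$vo2)^2, 0)))
  expect_equal(forward_select(tab2, "all", max_k = 1), best)
})

test_that("forward_select respects the variable-set filter", {
  tab <- make_feature_table(n = 100, seed = 14)
  tab$vo2 <- rnorm(100)
  cls <- feature_classes()
  sel_nl <- forward_select(tab, "nonlinear", max_k = 5)
  expect_true(all(cls[sel_nl] == "nonlinear"))
  sel_l <- forward_select(tab, "linear", max_k = 5)
  expect_true(all(cls[sel_l] == "linear"))
})

test_that("cross-validation recovers a noiseless truth and nests properly", {
  tab <- make_feature_table(n = 200, seed = 15)
  tab$vo2 <- 1 + 2 * tab$X_SD + 3 * tab$Y_P90 - 4 * tab$RV_SAMPEN
  cv <- run_cv_experiment(tab, "all", k = 10, max_k = 5, seed = 2)
  val <- cv$curve[cv$curve$split == "validation", ]
  expect_true(all(val$r[val$k >= 3] >= 0.999))
  expect_setequal(cv$final_predictors, c("X_SD", "Y_P90", "RV_SAMPEN"))
  expect_equal(cv$final_model$intercept, 1, tolerance = 1e-6)

  # training MSE non-increasing in k within each fold (nested models)
  tab$vo2 <- tab$vo2 + rnorm(200)
  cv2 <- run_cv_experiment(tab, "all", k = 5, max_k = 6, seed = 3)
  for (f in seq_len(5)) {
    tr <- which(cv2$folds != f)
    sel <- cv2$fold_selections[[f]]
    rss <- vapply(seq_along(sel), function(kk) {
      m <- fit_ols(tab[tr, ], sel[seq_len(kk)])
      mean((predict(m, tab[tr, ]) - tab$vo2[tr])^2)
    }, 0)
    expect_true(all(diff(rss) <= 1e-8))
  }
})

test_that("cv experiment is deterministic and respects fold structure", {
  tab <- make_feature_table(n = 120, seed = 16)
  tab$vo2 <- 2 * tab$Y_SD + rnorm(120, 0, 0.3)
  cv_a <- run_cv_experiment(tab, "linear", k = 6, max_k = 4, seed = 5)
  cv_b <- run_cv_experiment(tab, "linear", k = 6, max_k = 4, seed = 5)
  expect_identical(cv_a$curve, cv_b$curve)
  expect_identical(cv_a$final_predictors, cv_b$final_predictors)
  expect_equal(sort(unique(cv_a$folds)), 1:6)
  cls <- feature_classes()
  expect_true(all(cls[cv_a$final_predictors] == "linear"))
})

test_that("task_error_table applies the declared normalization", {
  t1 <- task_error_table(c(4, 4, 4), c(4, 4, 4), rep("Lying down", 3))
  expect_equal(t1$rel_mse_pct, 0)
  expect_equal(t1$rel_mae_pct, 0)

  # obs all 10, pred all 8: rel MAE = 100 * 2/10; rel MSE = 100 * 4/100
  t2 <- task_error_table(rep(8, 4), rep(10, 4), rep("Ironing", 4))
  expect_equal(t2$rel_mae_pct, 20)
  expect_equal(t2$rel_mse_pct, 4)

  labs <- c("a", "a", "b", "b", "c")
  t3 <- task_error_table(rnorm(5, 5), rnorm(5, 5), labs)
  expect_setequal(t3$label, c("a", "b", "c"))
  expect_true(t3$flagged[t3$label == "c"])  # single window: not computed
  expect_true(all(t3$rel_mse_pct[!t3$flagged] >= 0))
})
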