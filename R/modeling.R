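## Linear VO2 modelling: OLS fitting, greedy forward selection, 10-fold
## cross-validation over the three variable sets, the published
## equations, and per-task error summaries.

#' Construct a linear VO2 model
#'
#' @param intercept Intercept in mL·kg⁻¹·min⁻¹.
#' @param terms Named numeric vector of coefficients; names must be
#'   canonical feature names (see [feature_names()]) and unique.
#' @param variable_set `"all"`, `"linear"` or `"nonlinear"`; the term
#'   names must belong to the set.
#' @param se Optional named numeric vector of coefficient standard
#'   errors (intercept first, named `"(Intercept)"`).
#' @return An object of class `ee_model`.
#' @export
ee_model <- function(intercept, terms, variable_set = "all", se = NULL) {
  nm <- names(terms)
  if (is.null(nm) || anyDuplicated(nm))
    stop("terms must have unique names")
  bad <- setdiff(nm, feature_names())
  if (length(bad))
    stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  allowed <- variable_set_names(variable_set)
  off <- setdiff(nm, allowed)
  if (length(off))
    stop("term(s) outside variable set '", variable_set, "': ",
         paste(off, collapse = ", "))
  structure(list(intercept = as.numeric(intercept), terms = terms,
                 variable_set = variable_set, se = se),
            class = "ee_model")
}

#' @export
print.ee_model <- function(x, ...) {
  rhs <- paste(sprintf("%+.4f*%s", x$terms, names(x$terms)), collapse = " ")
  cat(sprintf("<ee_model [%s]> VO2 = %.4f %s\n", x$variable_set,
              x$intercept, rhs))
  invisible(x)
}

#' Ordinary least-squares fit of VO2 on named features
#'
#' @param features Feature table (from [extract_feature_table()]) with
#'   a `vo2` column (or the column named by `target`).
#' @param names Character vector of predictor feature names.
#' @param target Name of the response column (default `"vo2"`).
#' @param variable_set Variable-set tag stored on the model.
#' @return An `ee_model` with coefficient standard errors.
#' @export
fit_ols <- function(features, names, target = "vo2", variable_set = "all") {
  missing_cols <- setdiff(c(names, target), colnames(features))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  y <- features[[target]]
  n <- length(y)
  if (n < length(names) + 2L)
    stop("need at least length(names) + 2 rows")
  X <- cbind(`(Intercept)` = 1, as.matrix(features[, names, drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("rank-deficient design; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  res <- y - drop(X %*% coefs)
  sigma2 <- sum(res^2) / (n - ncol(X))
  XtX_inv <- solve(crossprod(X))
  se <- stats::setNames(sqrt(sigma2 * diag(XtX_inv)), colnames(X))
  ee_model(intercept = coefs[1L], terms = coefs[-1L],
           variable_set = variable_set, se = se)
}

#' Predict VO2 from a fitted or published model
#'
#' Direct evaluation of the affine equation: intercept plus the sum of
#' coefficient times feature value, vectorized over the rows of a
#' feature table.
#'
#' @param object An `ee_model`.
#' @param newdata Feature table (data frame) or a single named numeric
#'   vector containing every term's feature.
#' @param ... Unused.
#' @return Numeric vector of VO2 estimates in mL·kg⁻¹·min⁻¹.
#' @export
predict.ee_model <- function(object, newdata, ...) {
  nm <- names(object$terms)
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(nm, colnames(newdata))
    if (length(missing_cols))
      stop("feature(s) missing from newdata: ",
           paste(missing_cols, collapse = ", "))
    X <- as.matrix(newdata[, nm, drop = FALSE])
  } else {
    missing_cols <- setdiff(nm, names(newdata))
    if (length(missing_cols))
      stop("feature(s) missing from newdata: ",
           paste(missing_cols, collapse = ", "))
    X <- matrix(newdata[nm], nrow = 1L, dimnames = list(NULL, nm))
  }
  drop(object$intercept + X %*% object$terms)
}

#' The three published VO2 prediction equations
#'
#' The models selected by the original 10-fold cross-validated
#' forward-selection experiment on the study cohort, with coefficients
#' exactly as printed: an all-variables model and a linear-variables
#' model (both built on `RV_75-25`, `Y_VAR`, `Y_SD`) and a
#' non-linear-variables model (built on `RV_DYN`, `RV_ND1`, `Y_DYN`).
#' The all-variables and linear-variables equations differ only in the
#' printed precision of two shared coefficients; both printings are
#' kept verbatim.
#'
#' @return Named list of three `ee_model` objects: `all`, `linear`,
#'   `nonlinear`.
#' @export
#' @examples
#' m <- published_models()
#' predict(m$all, c(`RV_75-25` = 0, Y_VAR = 0, Y_SD = 0))  # the intercept
published_models <- function() {
  list(
    all = ee_model(3.4921,
                   c(`RV_75-25` = 10.784, Y_VAR = -25.4524, Y_SD = 21.0447),
                   variable_set = "all"),
    linear = ee_model(3.4921,
                      c(`RV_75-25` = 10.7083, Y_VAR = -25.4524,
                        Y_SD = 21.04487),
                      variable_set = "linear"),
    nonlinear = ee_model(-343.0891,
                         c(RV_DYN = 503.1303, RV_ND1 = 1.6797,
                           Y_DYN = -156.1103),
                         variable_set = "nonlinear"))
}

#' Agreement metrics between predicted and observed VO2
#'
#' @param pred,obs Numeric vectors of equal length >= 3.
#' @return Named list: `r` (Pearson correlation), `mse` (mean squared
#'   error, (mL·kg⁻¹·min⁻¹)²), `mae` (mean absolute error,
#'   mL·kg⁻¹·min⁻¹). A constant `pred` or `obs` yields a correlation of
#'   0 with a warning.
#' @export
metrics <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs must have equal length")
  if (length(pred) < 3L) stop("metrics needs at least 3 pairs")
  err <- pred - obs
  r <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    warning("metrics: constant series, correlation reported as 0")
    0
  } else stats::cor(pred, obs)
  list(r = r, mse = mean(err^2), mae = mean(abs(err)))
}

#' Random k-fold assignment of windows
#'
#' @param n_windows Number of windows (>= k).
#' @param k Number of folds (default 10).
#' @param seed Integer seed; the assignment is deterministic given the
#'   seed.
#' @param groups Optional vector of length `n_windows` (e.g. participant
#'   ids); when supplied, whole groups are assigned to folds so no group
#'   straddles a fold boundary (fold sizes then differ by more than 1 in
#'   general).
#' @return Integer vector of fold labels in `1..k`.
#' @export
kfold_split <- function(n_windows, k = 10L, seed = 1L, groups = NULL) {
  if (is.null(groups)) {
    if (n_windows < k) stop("need at least k windows")
    f <- local({set.seed(seed); sample(rep_len(seq_len(k), n_windows))})
    return(f)
  }
  stopifnot(length(groups) == n_windows)
  u <- unique(groups)
  if (length(u) < k) stop("need at least k groups for grouped folding")
  gf <- local({set.seed(seed); sample(rep_len(seq_len(k), length(u)))})
  gf[match(groups, u)]
}

#' Greedy forward selection of VO2 predictors
#'
#' At each step the candidate feature that minimizes the training mean
#' squared error of the refit OLS model is added; ties are broken by
#' canonical feature-name order. Candidates that would make the design
#' rank-deficient are skipped.
#'
#' @param features Feature table with a `vo2` column.
#' @param variable_set `"all"`, `"linear"` or `"nonlinear"`; restricts
#'   the candidate pool via [feature_classes()].
#' @param max_k Maximum number of predictors (default 10).
#' @param target Response column name.
#' @return Character vector of up to `max_k` feature names in selection
#'   order.
#' @export
forward_select <- function(features, variable_set = "all", max_k = 10L,
                           target = "vo2") {
  candidates <- intersect(variable_set_names(variable_set),
                          colnames(features))
  if (!length(candidates)) stop("no candidate features in table")
  y <- features[[target]]
  X_all <- as.matrix(features[, candidates, drop = FALSE])
  chosen <- character(0)
  X_cur <- matrix(1, nrow = length(y), ncol = 1L)
  for (step in seq_len(min(max_k, length(candidates)))) {
    remaining <- setdiff(candidates, chosen)
    best <- NA_character_
    best_rss <- Inf
    for (cand in remaining) {  # canonical order => deterministic ties
      Xc <- cbind(X_cur, X_all[, cand])
      fit <- tryCatch(stats::.lm.fit(Xc, y), error = function(e) NULL)
      if (is.null(fit) || fit$rank < ncol(Xc)) next
      rss <- sum(fit$residuals^2)
      if (rss < best_rss - 1e-12 * max(1, rss)) {
        best_rss <- rss
        best <- cand
      }
    }
    if (is.na(best)) break
    chosen <- c(chosen, best)
    X_cur <- cbind(X_cur, X_all[, best])
  }
  chosen
}

## canonical signature used to compare predictor sets across folds
.set_signature <- function(nm) paste(sort(match(nm, feature_names())),
                                     collapse = ",")

#' Forward-selection experiment under k-fold cross-validation
#'
#' In each fold, forward selection and OLS fitting run on the training
#' 90% and the resulting 1..`max_k`-predictor models are evaluated on
#' the held-out 10%. Metrics are aggregated by pooling predictions
#' across folds (all held-out predictions are concatenated and the
#' metrics computed once; training predictions analogously), giving the
#' performance curve over the number of predictors. The final predictor
#' set is the `final_k`-predictor set selected most frequently across
#' folds (ties broken by canonical order) and the final model is refit
#' on all data with that set.
#'
#' @param features Feature table with `vo2` (and `label`,
#'   `participant_id` for reporting).
#' @param variable_set `"all"`, `"linear"` or `"nonlinear"`.
#' @param k Number of folds (default 10).
#' @param max_k Maximum predictors on the performance curve (default
#'   10).
#' @param final_k Number of predictors in the final model (default 3).
#' @param seed Integer seed for the fold assignment.
#' @param group_by_participant If `TRUE`, folds are formed over
#'   participants rather than windows, so no participant contributes to
#'   both training and validation of the same fold. Default `FALSE`
#'   (window-level folding).
#' @return An object of class `ee_cv_experiment`: list with `folds`,
#'   `curve` (data frame: `k`, `split`, `r`, `mse`, `mae`),
#'   `fold_selections`, `final_predictors`, `final_model`,
#'   `validation` (pooled held-out predictions at `final_k`, with
#'   labels), `variable_set`, `final_k`, `seed`.
#' @export
run_cv_experiment <- function(features, variable_set = "all", k = 10L,
                              max_k = 10L, final_k = 3L, seed = 1L,
                              group_by_participant = FALSE) {
  y <- features$vo2
  n <- nrow(features)
  groups <- if (group_by_participant) features$participant_id else NULL
  folds <- kfold_split(n, k = k, seed = seed, groups = groups)
  sel_list <- vector("list", k)
  pred_val <- vector("list", k)
  pred_tr <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    va <- which(folds == f)
    sel <- forward_select(features[tr, , drop = FALSE],
                          variable_set = variable_set, max_k = max_k)
    sel_list[[f]] <- sel
    kk_max <- length(sel)
    pv <- matrix(NA_real_, nrow = length(va), ncol = kk_max)
    pt <- matrix(NA_real_, nrow = length(tr), ncol = kk_max)
    for (kk in seq_len(kk_max)) {
      m <- fit_ols(features[tr, , drop = FALSE], sel[seq_len(kk)],
                   variable_set = variable_set)
      pv[, kk] <- predict(m, features[va, , drop = FALSE])
      pt[, kk] <- predict(m, features[tr, , drop = FALSE])
    }
    pred_val[[f]] <- list(idx = va, pred = pv)
    pred_tr[[f]] <- list(idx = tr, pred = pt)
  }
  kk_all <- min(vapply(sel_list, length, 0L))
  curve <- do.call(rbind, lapply(seq_len(kk_all), function(kk) {
    pv <- unlist(lapply(pred_val, function(p) p$pred[, kk]))
    ov <- y[unlist(lapply(pred_val, `[[`, "idx"))]
    pt <- unlist(lapply(pred_tr, function(p) p$pred[, kk]))
    ot <- y[unlist(lapply(pred_tr, `[[`, "idx"))]
    mv <- metrics(pv, ov)
    mt <- metrics(pt, ot)
    data.frame(k = kk, split = c("training", "validation"),
               r = c(mt$r, mv$r), mse = c(mt$mse, mv$mse),
               mae = c(mt$mae, mv$mae))
  }))
  ## modal final_k-predictor set across folds, ties by canonical order
  sigs <- vapply(sel_list, function(s) .set_signature(s[seq_len(min(final_k, length(s)))]), "")
  tab <- table(sigs)
  top <- names(tab)[tab == max(tab)]
  win_sig <- top[order(top)][1L]
  final_idx <- as.integer(strsplit(win_sig, ",")[[1L]])
  final_predictors <- feature_names()[final_idx]
  final_model <- fit_ols(features, final_predictors,
                         variable_set = variable_set)
  vi <- unlist(lapply(pred_val, `[[`, "idx"))
  kk_f <- min(final_k, kk_all)
  validation <- data.frame(
    obs = y[vi],
    pred = unlist(lapply(pred_val, function(p) p$pred[, kk_f])),
    label = features$label[vi],
    stringsAsFactors = FALSE)
  structure(list(folds = folds, curve = curve, fold_selections = sel_list,
                 final_predictors = final_predictors,
                 final_model = final_model, validation = validation,
                 variable_set = variable_set, final_k = final_k, seed = seed),
            class = "ee_cv_experiment")
}

#' @export
print.ee_cv_experiment <- function(x, ...) {
  cat(sprintf("<ee_cv_experiment [%s]> %d folds, seed %d\n", x$variable_set,
              max(x$folds), x$seed))
  cat("  final predictors:", paste(x$final_predictors, collapse = ", "), "\n")
  v <- x$curve[x$curve$split == "validation" & x$curve$k == x$final_k, ]
  cat(sprintf("  pooled validation (k = %d): r = %.3f, MSE = %.3f, MAE = %.3f\n",
              x$final_k, v$r, v$mse, v$mae))
  invisible(x)
}

#' Per-task relative error table
#'
#' For each activity label: the relative normalized mean squared error,
#' 100 × MSE / mean(obs²), and the relative mean absolute error,
#' 100 × MAE / mean(obs), both in percent. Tasks with fewer than 2
#' windows are flagged (`NA` values, `flagged = TRUE`) rather than
#' computed.
#'
#' @param pred,obs Numeric vectors of aligned predictions and
#'   observations.
#' @param labels Activity label per element.
#' @return Data frame with columns `label`, `n`, `rel_mse_pct`,
#'   `rel_mae_pct`, `flagged`; one row per distinct label.
#' @export
task_error_table <- function(pred, obs, labels) {
  stopifnot(length(pred) == length(obs), length(obs) == length(labels))
  out <- lapply(unique(labels), function(lb) {
    i <- labels == lb
    if (sum(i) < 2L)
      return(data.frame(label = lb, n = sum(i), rel_mse_pct = NA_real_,
                        rel_mae_pct = NA_real_, flagged = TRUE))
    e <- pred[i] - obs[i]
    data.frame(label = lb, n = sum(i),
               rel_mse_pct = 100 * mean(e^2) / mean(obs[i]^2),
               rel_mae_pct = 100 * mean(abs(e)) / mean(obs[i]),
               flagged = FALSE)
  })
  do.call(rbind, out)
}

#' Plot the performance curve of a cross-validation experiment
#'
#' Pooled correlation, MSE and MAE against the number of predictors,
#' for the training and validation splits.
#'
#' @param x An `ee_cv_experiment`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the curve data frame.
#' @export
plot_performance_curve <- function(x, ...) {
  stopifnot(inherits(x, "ee_cv_experiment"))
  cv <- x$curve
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (mname in c("r", "mse", "mae")) {
    wide <- do.call(cbind, lapply(c("training", "validation"), function(s)
      cv[cv$split == s, mname]))
    graphics::matplot(unique(cv$k), wide, type = "b", pch = c(1, 19),
                      lty = 1:2, col = c("grey40", "black"),
                      xlab = "number of predictors", ylab = mname, ...)
    graphics::legend("bottomright", c("training", "validation"),
                     pch = c(1, 19), lty = 1:2, col = c("grey40", "black"),
                     bty = "n", cex = 0.8)
  }
  invisible(cv)
}
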