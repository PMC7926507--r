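## Per-window feature computations. Each operates on one channel of one
## one-minute window (a plain numeric vector of accelerations in g)
## except cross_correlation, which pairs two axes.

#' Sample standard deviation and variance of a window
#'
#' @param s Numeric vector, length >= 2.
#' @return Named list with `SD` and `VAR` (n−1 denominator).
#' @export
dispersion_stats <- function(s) {
  if (length(s) < 2L) stop("dispersion_stats needs at least 2 samples")
  v <- stats::var(s)
  list(SD = sqrt(v), VAR = v)
}

#' Percentile statistics of a window
#'
#' Percentiles use linear interpolation between order statistics
#' (`quantile()` type 7); the interquartile range `75-25` is
#' P75 − P25.
#'
#' @param s Non-empty numeric vector.
#' @return Named list `P10`, `P25`, `P50`, `P75`, `P90`, `75-25`.
#' @export
percentile_stats <- function(s) {
  if (length(s) < 1L) stop("percentile_stats needs a non-empty series")
  q <- stats::quantile(s, probs = c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  list(P10 = q[1], P25 = q[2], P50 = q[3], P75 = q[4], P90 = q[5],
       `75-25` = q[4] - q[2])
}

#' Lag-one autocorrelation of a window
#'
#' Pearson correlation between the window and itself shifted by one
#' sample; a measure of temporal dynamics (smoothness) of the signal.
#' For a degenerate window where either lagged sub-series is constant,
#' 0 is returned with a warning.
#'
#' @param s Numeric vector, length >= 3.
#' @return Scalar in \[−1, 1\].
#' @export
lag_one_correlation <- function(s) {
  n <- length(s)
  if (n < 3L) stop("lag_one_correlation needs at least 3 samples")
  a <- s[-n]; b <- s[-1L]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("lag_one_correlation: constant sub-series, returning 0")
    return(0)
  }
  stats::cor(a, b)
}

## Daubechies-2 scaling filter (orthonormal) and its quadrature mirror.
.db2_h <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
.db2_g <- c(.db2_h[4], -.db2_h[3], .db2_h[2], -.db2_h[1])

## One periodized analysis step: returns approximation and detail
## coefficients of half length. Odd-length inputs are right-padded with
## the final sample before wrapping (so the transform stays defined;
## exact energy conservation holds for even lengths).
.dwt_db2_step <- function(s) {
  n <- length(s)
  if (n %% 2L == 1L) { s <- c(s, s[n]); n <- n + 1L }
  idx <- (outer(seq.int(0L, n - 2L, by = 2L), 0:3, `+`) %% n) + 1L
  m <- matrix(s[idx], ncol = 4L)
  list(a = drop(m %*% .db2_h), d = drop(m %*% .db2_g))
}

#' Euclidean norms of 2-level Daubechies-2 wavelet coefficients
#'
#' Runs a two-level discrete wavelet transform with the Daubechies-2
#' mother wavelet and periodized boundary handling, and returns the
#' Euclidean norms of the level-1 detail (`ND1`), level-2 detail
#' (`ND2`) and level-2 approximation (`NA2`) coefficient vectors. The
#' periodized filter bank is orthonormal, so for even-dyadic lengths
#' ND1² + ND2² + NA2² equals the signal energy exactly.
#'
#' @param s Numeric vector, length >= 4.
#' @return Named list `ND1`, `ND2`, `NA2` (all >= 0).
#' @export
wavelet_norms <- function(s) {
  if (length(s) < 4L) stop("wavelet_norms needs at least 4 samples")
  l1 <- .dwt_db2_step(s)
  l2 <- .dwt_db2_step(l1$a)
  list(ND1 = sqrt(sum(l1$d^2)), ND2 = sqrt(sum(l2$d^2)),
       NA2 = sqrt(sum(l2$a^2)))
}

#' Sample entropy of a window
#'
#' SampEn(m, r) = −ln(A/B), where B is the number of pairs of distinct
#' m-length templates whose Chebyshev distance is at most r, and A the
#' number of those pairs still matching when extended to length m + 1;
#' self-matches are excluded. The tolerance is `r_coeff` times the
#' sample standard deviation of the window, so the statistic is
#' amplitude-scale invariant. Degenerate conventions: a constant window
#' returns 0; if no extended match exists (A = 0 with B > 0) the
#' standard cap −ln(2/((n−m−1)(n−m))) is returned. Both emit a warning.
#'
#' @param s Numeric vector, length >= m + 2.
#' @param m Template (pattern) length, default 2.
#' @param r_coeff Tolerance as a multiple of SD(s), default 0.3.
#' @return Non-negative scalar.
#' @export
sample_entropy <- function(s, m = 2L, r_coeff = 0.3) {
  n <- length(s)
  if (n < m + 2L) stop("sample_entropy needs at least m + 2 samples")
  sdev <- stats::sd(s)
  if (sdev == 0) {
    warning("sample_entropy: constant window, returning 0")
    return(0)
  }
  cnt <- sampen_counts(as.numeric(s), as.integer(m), r_coeff * sdev)
  A <- cnt[1]; B <- cnt[2]
  if (B == 0 || A == 0) {
    warning("sample_entropy: no extended template matches, returning cap")
    return(-log(2 / ((n - m - 1) * (n - m))))
  }
  -log(A / B)
}

#' Zero-lag cross-correlation between two axes of one window
#'
#' Pearson correlation between the two channels, sample by sample (no
#' lag search). Returns 0 with a warning if either channel is constant.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return Scalar in \[−1, 1\].
#' @export
cross_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("cross_correlation needs equal lengths")
  if (length(a) < 2L) stop("cross_correlation needs at least 2 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("cross_correlation: constant channel, returning 0")
    return(0)
  }
  stats::cor(a, b)
}

.channel_features <- function(s, m = 2L, r_coeff = 0.3) {
  c(unlist(dispersion_stats(s)),
    unlist(percentile_stats(s)),
    DYN = lag_one_correlation(s),
    unlist(wavelet_norms(s)),
    SAMPEN = sample_entropy(s, m = m, r_coeff = r_coeff))
}

#' Compute the 55 variables of one minute window
#'
#' Thirteen statistics per channel (X, Y, Z and the resultant vector
#' RV) plus the three zero-lag inter-axis correlations; see
#' [feature_names()] for the canonical naming and order.
#'
#' @param w A `minute_window` (from [segment_minutes()]), or a named
#'   list of four equal-length channels `X`, `Y`, `Z`, `RV`.
#' @param m,r_coeff Sample-entropy parameters; defaults 2 and 0.3.
#' @return Named numeric vector of length 55 in canonical order, with
#'   attributes `label`, `type`, `vo2`, `participant_id` carried over
#'   when `w` is a `minute_window`.
#' @export
extract_features <- function(w, m = 2L, r_coeff = 0.3) {
  ch <- if (inherits(w, "minute_window")) w$channels else w
  if (!all(c("X", "Y", "Z", "RV") %in% names(ch)))
    stop("window must provide channels X, Y, Z, RV")
  len <- lengths(ch[c("X", "Y", "Z", "RV")])
  if (length(unique(len)) != 1L || len[1] < 4L)
    stop("channels must have equal length >= 4")
  vals <- unlist(lapply(c("X", "Y", "Z", "RV"), function(nm)
    .channel_features(ch[[nm]], m = m, r_coeff = r_coeff)))
  xc <- c(cross_correlation(ch$X, ch$Y),
          cross_correlation(ch$Y, ch$Z),
          cross_correlation(ch$X, ch$Z))
  fv <- stats::setNames(c(vals, xc), feature_names())
  if (inherits(w, "minute_window")) {
    attr(fv, "label") <- w$label
    attr(fv, "type") <- w$type
    attr(fv, "vo2") <- w$vo2
    attr(fv, "participant_id") <- w$participant_id
  }
  fv
}

#' Build a feature table from a list of minute windows
#'
#' One row per window: the 55 canonical feature columns followed by
#' `label`, `type`, `vo2` and `participant_id`.
#'
#' @param windows List of `minute_window` objects.
#' @param m,r_coeff Sample-entropy parameters.
#' @return A `data.frame` (55 numeric columns plus metadata; column
#'   names are canonical, so `check.names = FALSE` is used throughout).
#' @export
extract_feature_table <- function(windows, m = 2L, r_coeff = 0.3) {
  stopifnot(length(windows) >= 1L)
  rows <- lapply(windows, extract_features, m = m, r_coeff = r_coeff)
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  tab$label <- vapply(windows, `[[`, "", "label")
  tab$type <- vapply(windows, `[[`, "", "type")
  tab$vo2 <- vapply(windows, `[[`, 0, "vo2")
  tab$participant_id <- vapply(windows, `[[`, "", "participant_id")
  rownames(tab) <- NULL
  tab
}

#' Write / read a feature table as delimited text
#'
#' @param tab Feature table from [extract_feature_table()].
#' @param path Output path (CSV).
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the table.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
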