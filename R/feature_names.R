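## Canonical registry of the 55 per-minute variables.
##
## 13 statistics per channel (three axes X, Y, Z plus the resultant
## vector RV), in a fixed order, followed by the three zero-lag
## inter-axis correlations. The order defined here is the canonical
## order used for output columns and for deterministic tie-breaking in
## forward selection.

.ee_channels <- c("X", "Y", "Z", "RV")

.ee_stats <- c("SD", "VAR", "P10", "P25", "P50", "P75", "P90", "75-25",
               "DYN", "ND1", "ND2", "NA2", "SAMPEN")

.ee_xcorr <- c("XCORR_XY", "XCORR_YZ", "XCORR_XZ")

## statistics computed from a single channel's sample distribution
.ee_linear_stats <- c("SD", "VAR", "P10", "P25", "P50", "P75", "P90", "75-25")

#' Canonical names of the 55 per-minute accelerometer variables
#'
#' Thirteen statistics per channel — standard deviation (`SD`), variance
#' (`VAR`), the 10th/25th/50th/75th/90th percentiles (`P10`..`P90`), the
#' interquartile range (`75-25`), the lag-one autocorrelation (`DYN`),
#' the Euclidean norms of the level-1 and level-2 detail and level-2
#' approximation coefficients of a Daubechies-2 wavelet transform
#' (`ND1`, `ND2`, `NA2`) and the sample entropy (`SAMPEN`) — for each of
#' the channels `X`, `Y`, `Z` and the resultant vector `RV`, plus the
#' three zero-lag inter-axis correlations `XCORR_XY`, `XCORR_YZ`,
#' `XCORR_XZ`.
#'
#' @return Character vector of length 55 in canonical order
#'   (`X_SD`, ..., `X_SAMPEN`, `Y_SD`, ..., `RV_SAMPEN`, `XCORR_XY`,
#'   `XCORR_YZ`, `XCORR_XZ`).
#' @seealso [feature_classes()], [extract_features()]
#' @export
#' @examples
#' length(feature_names())  # 55
#' head(feature_names())
feature_names <- function() {
  c(as.vector(t(outer(.ee_channels, .ee_stats, paste, sep = "_"))), .ee_xcorr)
}

#' Linear/non-linear classification of the 55 variables
#'
#' The modelling stage fits three variable sets: all 55 variables, the
#' 32 "linear" variables (per-channel dispersion and percentile
#' statistics) and the 23 "non-linear" variables (lag-one correlation,
#' wavelet coefficient norms, sample entropy and the inter-axis
#' correlations).
#'
#' @return Named character vector mapping each canonical feature name to
#'   `"linear"` or `"nonlinear"`.
#' @export
#' @examples
#' table(feature_classes())  # 32 linear, 23 nonlinear
feature_classes <- function() {
  nm <- feature_names()
  stat <- sub("^(X|Y|Z|RV)_", "", nm)
  cls <- ifelse(stat %in% .ee_linear_stats & nm %in% setdiff(nm, .ee_xcorr),
                "linear", "nonlinear")
  cls[nm %in% .ee_xcorr] <- "nonlinear"
  stats::setNames(cls, nm)
}

#' Feature names belonging to a variable set
#'
#' @param variable_set One of `"all"`, `"linear"`, `"nonlinear"`.
#' @return Character vector of canonical feature names in canonical
#'   order.
#' @export
variable_set_names <- function(variable_set = c("all", "linear", "nonlinear")) {
  variable_set <- match.arg(variable_set)
  cls <- feature_classes()
  if (variable_set == "all") names(cls) else names(cls)[cls == variable_set]
}
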