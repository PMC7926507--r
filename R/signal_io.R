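## Readers and containers for the three per-session data streams:
## triaxial acceleration, oxygen uptake, and activity annotations.
## Timestamps are seconds relative to session start; readers with
## absolute clock stamps subtract the first stamp.

#' Triaxial accelerometer recording
#'
#' Container for one session's acceleration stream. Time is in seconds
#' since session start and must be strictly increasing; `x`, `y`, `z`
#' are accelerations in g (gravity included — no high-pass filtering is
#' applied anywhere in the pipeline). The median inter-sample gap must
#' lie within ±20% of `1/nominal_rate`, otherwise the declared sampling
#' rate is inconsistent with the data and an error is raised.
#'
#' @param time Numeric vector, seconds since session start.
#' @param x,y,z Numeric vectors of per-sample acceleration in g.
#' @param nominal_rate Nominal sampling rate in samples per second
#'   (default 50).
#' @return An object of class `accel_recording`: a list with elements
#'   `time`, `x`, `y`, `z`, `nominal_rate`.
#' @export
accel_recording <- function(time, x, y, z, nominal_rate = 50) {
  n <- length(time)
  if (n < 2L) stop("accel_recording needs at least 2 samples")
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("time, x, y, z must have equal length")
  if (!all(is.finite(time)) || any(time < 0))
    stop("time must be finite and non-negative")
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing")
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1L || nominal_rate <= 0)
    stop("nominal_rate must be a positive scalar")
  gap <- stats::median(diff(time))
  expected <- 1 / nominal_rate
  if (abs(gap - expected) > 0.2 * expected)
    stop(sprintf(
      "median inter-sample gap %.4gs inconsistent with nominal rate %g Hz",
      gap, nominal_rate))
  structure(
    list(time = as.numeric(time), x = as.numeric(x), y = as.numeric(y),
         z = as.numeric(z), nominal_rate = nominal_rate),
    class = "accel_recording")
}

#' Weight-normalized oxygen-uptake series
#'
#' @param time Numeric vector, seconds since session start, strictly
#'   increasing.
#' @param vo2 Oxygen uptake per measurement, mL·kg⁻¹·min⁻¹ (weight
#'   normalized), all non-negative.
#' @param mass_kg Participant body mass (kg) used for normalization.
#' @return An object of class `vo2_series`.
#' @export
vo2_series <- function(time, vo2, mass_kg) {
  if (length(time) != length(vo2)) stop("time and vo2 must have equal length")
  if (any(diff(time) <= 0)) stop("vo2 time must be strictly increasing")
  if (any(!is.finite(vo2)) || any(vo2 < 0)) stop("vo2 must be finite and >= 0")
  if (!is.numeric(mass_kg) || length(mass_kg) != 1L || mass_kg <= 0)
    stop("mass_kg must be a positive scalar")
  structure(list(time = as.numeric(time), vo2 = as.numeric(vo2),
                 mass_kg = mass_kg),
            class = "vo2_series")
}

.activity_types <- c("Sedentary", "Housework", "Locomotion")

#' Activity annotations for one session
#'
#' @param label Character vector of activity names.
#' @param type Activity class, one of `"Sedentary"`, `"Housework"`,
#'   `"Locomotion"`.
#' @param start_s,end_s Interval bounds in seconds since session start;
#'   intervals must not overlap.
#' @return A `data.frame` of class `activity_annotations` with columns
#'   `label`, `type`, `start_s`, `end_s`, ordered by `start_s`.
#' @export
activity_annotations <- function(label, type, start_s, end_s) {
  if (!all(type %in% .activity_types))
    stop("type must be one of: ", paste(.activity_types, collapse = ", "))
  if (any(start_s >= end_s)) stop("annotation start must precede end")
  o <- order(start_s)
  ann <- data.frame(label = as.character(label)[o], type = as.character(type)[o],
                    start_s = as.numeric(start_s)[o], end_s = as.numeric(end_s)[o],
                    stringsAsFactors = FALSE)
  if (nrow(ann) > 1L && any(ann$start_s[-1L] < ann$end_s[-nrow(ann)]))
    stop("annotation intervals overlap")
  class(ann) <- c("activity_annotations", "data.frame")
  ann
}

#' Bundle the three streams of one recording session
#'
#' Validates that every annotated activity interval is covered by both
#' the acceleration and the VO2 time ranges (acceleration and
#' calorimetry are assumed synchronously started, so a shared relative
#' time base is used).
#'
#' @param participant_id Identifier string.
#' @param accel An [accel_recording()].
#' @param vo2 A [vo2_series()].
#' @param annotations An [activity_annotations()] table.
#' @return An object of class `ee_session`.
#' @export
session <- function(participant_id, accel, vo2, annotations) {
  stopifnot(inherits(accel, "accel_recording"), inherits(vo2, "vo2_series"),
            inherits(annotations, "activity_annotations"))
  a_rng <- range(accel$time)
  v_rng <- range(vo2$time)
  tol <- 1 / accel$nominal_rate
  if (any(annotations$start_s < a_rng[1] - tol) ||
      any(annotations$end_s > a_rng[2] + tol))
    stop("annotation intervals not covered by acceleration time range")
  if (any(annotations$start_s < v_rng[1] - tol) ||
      any(annotations$end_s > v_rng[2] + tol))
    stop("annotation intervals not covered by VO2 time range")
  structure(list(participant_id = as.character(participant_id), accel = accel,
                 vo2 = vo2, annotations = annotations),
            class = "ee_session")
}

#' @export
print.ee_session <- function(x, ...) {
  cat("<ee_session>", x$participant_id, "\n")
  cat(sprintf("  accel: %d samples @ %g Hz nominal, %.1f s\n",
              length(x$accel$time), x$accel$nominal_rate,
              diff(range(x$accel$time))))
  cat(sprintf("  vo2:   %d measurements, mass %.1f kg\n",
              length(x$vo2$time), x$vo2$mass_kg))
  cat(sprintf("  annotations: %d activities (%s)\n", nrow(x$annotations),
              paste(unique(x$annotations$type), collapse = ", ")))
  invisible(x)
}

.read_delim_checked <- function(path, required, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  df
}

#' Read an accelerometer log
#'
#' Two delimited-text dialects are supported: `"physics_toolbox"`, the
#' export format of the Physics Toolbox Suite phone app with header
#' `time,gFx,gFy,gFz`, and `"generic"` with header `t,ax,ay,az` (axes
#' already in g). Rows with unparseable numeric fields are dropped with
#' a logged count; duplicate timestamps are de-duplicated (first kept);
#' absolute clock stamps are converted to seconds since session start by
#' subtracting the first stamp.
#'
#' @param path Path to the delimited text file.
#' @param dialect `"physics_toolbox"` (default) or `"generic"`.
#' @param nominal_rate Declared sampling rate in Hz (default 50).
#' @param sep Field delimiter (default `","`).
#' @return An [accel_recording()].
#' @export
read_accel <- function(path, dialect = c("physics_toolbox", "generic"),
                       nominal_rate = 50, sep = ",") {
  dialect <- match.arg(dialect)
  cols <- switch(dialect,
                 physics_toolbox = c("time", "gFx", "gFy", "gFz"),
                 generic = c("t", "ax", "ay", "az"))
  df <- .read_delim_checked(path, cols, sep = sep)
  df <- df[cols]
  names(df) <- c("time", "x", "y", "z")
  num <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  ok <- Reduce(`&`, lapply(num, is.finite))
  n_bad <- sum(!ok)
  if (n_bad > 0L)
    message("read_accel: dropped ", n_bad, " row(s) with unparseable numerics")
  df <- data.frame(num)[ok, , drop = FALSE]
  if (nrow(df) < 2L) stop("fewer than 2 parseable samples in ", path)
  df <- df[!duplicated(df$time), , drop = FALSE]
  if (any(diff(df$time) <= 0))
    stop("non-monotonic time in ", path, " after de-duplication")
  accel_recording(df$time - df$time[1L], df$x, df$y, df$z,
                  nominal_rate = nominal_rate)
}

#' Read a gas-analyzer VO2 export
#'
#' Expects columns `time` (seconds) and `vo2`. If `already_normalized`
#' is `FALSE` the `vo2` column is taken in mL·min⁻¹ and divided by the
#' body mass to yield mL·kg⁻¹·min⁻¹.
#'
#' @param path Path to the delimited text file.
#' @param mass_kg Participant body mass in kg (must be positive).
#' @param already_normalized Logical; is `vo2` already weight
#'   normalized? Default `TRUE`.
#' @param sep Field delimiter.
#' @return A [vo2_series()] in mL·kg⁻¹·min⁻¹.
#' @export
read_vo2 <- function(path, mass_kg, already_normalized = TRUE, sep = ",") {
  if (!is.numeric(mass_kg) || length(mass_kg) != 1L || mass_kg <= 0)
    stop("mass_kg must be a positive scalar")
  df <- .read_delim_checked(path, c("time", "vo2"), sep = sep)
  tt <- suppressWarnings(as.numeric(df$time))
  vv <- suppressWarnings(as.numeric(df$vo2))
  ok <- is.finite(tt) & is.finite(vv)
  if (any(!ok))
    message("read_vo2: dropped ", sum(!ok), " row(s) with unparseable numerics")
  tt <- tt[ok]; vv <- vv[ok]
  if (!already_normalized) vv <- vv / mass_kg
  vo2_series(tt - tt[1L], vv, mass_kg = mass_kg)
}

#' Read an activity annotation file
#'
#' Expects columns `label`, `type`, `start_s`, `end_s`.
#'
#' @param path Path to the delimited text file.
#' @param sep Field delimiter.
#' @return An [activity_annotations()] table.
#' @export
read_annotations <- function(path, sep = ",") {
  df <- .read_delim_checked(path, c("label", "type", "start_s", "end_s"),
                            sep = sep)
  activity_annotations(df$label, df$type, as.numeric(df$start_s),
                       as.numeric(df$end_s))
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Directory containing `accel.csv`, `vo2.csv`,
#'   `annotations.csv` and `meta.json`.
#' @return An `ee_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  accel <- read_accel(file.path(dir, "accel.csv"), dialect = "physics_toolbox",
                      nominal_rate = meta$nominal_rate)
  vo2 <- read_vo2(file.path(dir, "vo2.csv"), mass_kg = meta$mass_kg,
                  already_normalized = TRUE)
  ann <- read_annotations(file.path(dir, "annotations.csv"))
  session(meta$participant_id, accel, vo2, ann)
}

#' Per-sample resultant acceleration vector
#'
#' Euclidean norm \eqn{\sqrt{x^2+y^2+z^2}} of the three axes, per
#' sample. Invariant under axis permutation and sign flips.
#'
#' @param rec An [accel_recording()].
#' @return Numeric vector (g) of the same length as the recording.
#' @export
resultant_vector <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  sqrt(rec$x^2 + rec$y^2 + rec$z^2)
}

#' Segment a session into one-minute windows
#'
#' Windows are annotation-anchored: for each annotated activity,
#' consecutive non-overlapping windows of `window_s` seconds start at
#' the activity's start; a trailing partial window is discarded. Rest
#' periods between activities are never windowed. Each window carries
#' the four channels (`X`, `Y`, `Z` and the resultant `RV`), the
#' activity label and class, and the minute VO2 — the arithmetic mean of
#' all VO2 measurements whose time falls in the half-open interval
#' `[window start, window end)`. A window containing no VO2 measurement
#' is dropped with a warning.
#'
#' @param session An `ee_session`.
#' @param window_s Window length in seconds (default 60).
#' @return List of `minute_window` objects, each a list with elements
#'   `channels` (named list `X`, `Y`, `Z`, `RV`), `label`, `type`,
#'   `vo2`, `participant_id`, `start_s`.
#' @export
segment_minutes <- function(session, window_s = 60) {
  stopifnot(inherits(session, "ee_session"))
  acc <- session$accel
  rv <- resultant_vector(acc)
  out <- list()
  dropped <- 0L
  for (i in seq_len(nrow(session$annotations))) {
    ann <- session$annotations[i, ]
    n_win <- floor((ann$end_s - ann$start_s) / window_s)
    if (n_win < 1L) next
    for (w in seq_len(n_win)) {
      ws <- ann$start_s + (w - 1L) * window_s
      we <- ws + window_s
      idx <- which(acc$time >= ws & acc$time < we)
      vidx <- which(session$vo2$time >= ws & session$vo2$time < we)
      if (length(vidx) == 0L) { dropped <- dropped + 1L; next }
      out[[length(out) + 1L]] <- structure(
        list(channels = list(X = acc$x[idx], Y = acc$y[idx], Z = acc$z[idx],
                             RV = rv[idx]),
             label = ann$label, type = ann$type,
             vo2 = mean(session$vo2$vo2[vidx]),
             participant_id = session$participant_id, start_s = ws),
        class = "minute_window")
    }
  }
  if (dropped > 0L)
    warning("segment_minutes: dropped ", dropped,
            " window(s) with no VO2 measurements")
  out
}
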