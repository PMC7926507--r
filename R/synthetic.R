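## Synthetic study-protocol generator. Emulates the measurement design
## the modelling stage assumes: 20 participants each completing 10
## five-minute activities of graded intensity with 60-s rests, recorded
## by an arm-worn triaxial accelerometer (nominal 50 Hz) and a portable
## gas analyzer, with minute VO2 coupled to the signal's variability
## through a known ground-truth linear equation.

#' Default activity profiles of the simulated routine
#'
#' Ten activities in three intensity classes (3 sedentary, 4 housework,
#' 3 locomotion), each 300 s. Per activity: the oscillation amplitude
#' (g) of the arm-movement component, its dominant frequency (Hz), the
#' per-minute amplitude jitter (log-scale SD, so movement vigor varies
#' minute to minute), and a nominal resting-reference VO2 used for the
#' rest gaps. Intensities are ordered Sedentary < Housework <
#' Locomotion.
#'
#' @return Data frame with columns `label`, `type`, `duration_s`,
#'   `amplitude_g`, `freq_hz`, `jitter`, `baseline_vo2`.
#' @export
activity_profiles <- function() {
  data.frame(
    label = c("Lying down", "Watching TV", "Working on a computer",
              "Moving items", "Mopping the floor", "Cleaning the windows",
              "Ironing", "Arm-ergometry exercise", "Slow propulsion",
              "Fast propulsion"),
    type = c("Sedentary", "Sedentary", "Sedentary", "Housework", "Housework",
             "Housework", "Housework", "Locomotion", "Locomotion",
             "Locomotion"),
    duration_s = 300,
    amplitude_g = c(0.050, 0.063, 0.101, 0.204, 0.240, 0.215, 0.165,
                    0.455, 0.367, 0.658),
    freq_hz = c(0.25, 0.30, 0.55, 0.45, 0.60, 0.70, 0.50, 1.00, 0.80, 0.95),
    jitter = 0.30,
    baseline_vo2 = c(3.0, 3.2, 3.6, 6.5, 7.0, 6.8, 5.5, 9.5, 8.0, 11.0),
    stringsAsFactors = FALSE)
}

#' Ground truth generating a synthetic session's VO2
#'
#' The minute VO2 is produced by applying `model` to the features of
#' that minute's generated acceleration signal and adding Gaussian
#' noise, so the linear-model assumption of the analysis holds exactly
#' (up to noise) and parameter recovery is meaningful. Setting
#' `quadratic_coeff` non-zero adds `quadratic_coeff * x^2` of the first
#' model term, deliberately misspecifying the linear model to probe
#' robustness.
#'
#' @param model An `ee_model` used as the generating equation; defaults
#'   to the published all-variables equation, so [published_models()]
#'   and the generator are mutually consistent.
#' @param noise_sd SD of the per-minute Gaussian noise,
#'   mL·kg⁻¹·min⁻¹ (default 1).
#' @param quadratic_coeff Coefficient of the optional quadratic
#'   misspecification term (default 0 = well-specified).
#' @return An object of class `ee_ground_truth`.
#' @export
ground_truth <- function(model = published_models()$all, noise_sd = 1,
                         quadratic_coeff = 0) {
  stopifnot(inherits(model, "ee_model"), noise_sd >= 0)
  structure(list(model = model, noise_sd = noise_sd,
                 quadratic_coeff = quadratic_coeff),
            class = "ee_ground_truth")
}

## Compute a single named feature from the four window channels,
## without paying for the full 55-variable extraction (the generator
## only needs the truth model's terms).
.compute_named_feature <- function(name, ch, m = 2L, r_coeff = 0.3) {
  if (name %in% .ee_xcorr) {
    ax <- strsplit(sub("XCORR_", "", name), "")[[1L]]
    return(cross_correlation(ch[[ax[1L]]], ch[[ax[2L]]]))
  }
  channel <- sub("_.*$", "", name)
  stat <- sub("^(X|Y|Z|RV)_", "", name)
  s <- ch[[channel]]
  switch(stat,
         SD = dispersion_stats(s)$SD,
         VAR = dispersion_stats(s)$VAR,
         P10 = , P25 = , P50 = , P75 = , P90 = , `75-25` =
           percentile_stats(s)[[stat]],
         DYN = lag_one_correlation(s),
         ND1 = , ND2 = , NA2 = wavelet_norms(s)[[stat]],
         SAMPEN = sample_entropy(s, m = m, r_coeff = r_coeff),
         stop("unknown feature: ", name))
}

## slowly drifting unit-norm gravity orientation, one row per sample
.gravity_track <- function(tt, base, drift_amp = 0.05, drift_hz = 0.02,
                           phases = c(0, 2, 4)) {
  g <- vapply(1:3, function(i)
    base[i] + drift_amp * sin(2 * pi * drift_hz * tt + phases[i]),
    numeric(length(tt)))
  g / sqrt(rowSums(g^2))
}

#' Generate one synthetic recording session
#'
#' Builds the triaxial signal activity by activity: a unit-norm, slowly
#' drifting gravity orientation, plus an amplitude-modulated sinusoid
#' at the activity's dominant frequency (per-axis amplitude multipliers
#' and phase offsets, amplitude re-drawn every minute via the profile's
#' jitter), plus white sensor noise. Activities are separated by rest
#' gaps. The VO2 stream holds, for each activity minute, the
#' ground-truth model applied to that minute's signal features plus
#' Gaussian noise (floored at 0), emitted as measurements every
#' `vo2_dt` seconds; rest gaps emit a resting value. Sample times are
#' integer sample indices divided by `rate`, so minute windows contain
#' exactly `60 * rate` samples. Fully deterministic given `seed`.
#'
#' @param participant_id Identifier string.
#' @param profiles Activity profile table ([activity_profiles()]).
#' @param truth An [ground_truth()] object.
#' @param rate Sampling rate in Hz (default 50).
#' @param seed Integer seed.
#' @param mass_kg Participant body mass (kg).
#' @param rest_s Rest gap between activities, seconds (default 60).
#' @param vo2_dt VO2 measurement cadence, seconds (default 5, a
#'   breath-averaged cadence, so minute-averaging is exercised).
#' @param rest_vo2 VO2 emitted during rest gaps (default 3.5).
#' @param sensor_noise_g SD of the white accelerometer noise floor, g.
#' @param tremor_coeff SD of the signal-dependent motor-noise component
#'   as a fraction of the minute's oscillation amplitude (default
#'   0.15).
#' @param bias_drift_g SD of the per-minute sensor DC-offset drift, g
#'   (default 0.02).
#' @param spike_rate Expected number of impact spikes per minute
#'   (default 2).
#' @return An `ee_session`.
#' @export
generate_session <- function(participant_id, profiles = activity_profiles(),
                             truth = ground_truth(), rate = 50, seed = 1L,
                             mass_kg = 74.8, rest_s = 60, vo2_dt = 5,
                             rest_vo2 = 3.5, sensor_noise_g = 0.005,
                             tremor_coeff = 0.15, bias_drift_g = 0.02,
                             spike_rate = 2) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar")
  if (any(profiles$freq_hz >= rate / 2))
    stop("dominant frequency must be below the Nyquist rate")
  if (any(profiles$amplitude_g < 0) || any(profiles$duration_s <= 0))
    stop("invalid activity profile")
  set.seed(seed)
  need <- names(truth$model$terms)
  n_act <- nrow(profiles)
  spm <- as.integer(round(60 * rate))        # samples per minute
  acc_x <- acc_y <- acc_z <- tt <- list()
  vo2_t <- vo2_v <- list()
  ann_start <- ann_end <- numeric(n_act)
  idx0 <- 0L                                  # global sample index offset
  seg <- function(n) (idx0 + seq_len(n) - 1L) / rate
  for (i in seq_len(n_act)) {
    p <- profiles[i, ]
    n_min <- as.integer(floor(p$duration_s / 60))
    n_s <- as.integer(round(p$duration_s * rate))
    t_act <- seg(n_s)
    ann_start[i] <- idx0 / rate
    ann_end[i] <- (idx0 + n_s) / rate
    base <- stats::rnorm(3); base <- base / sqrt(sum(base^2))
    grav_ph <- stats::runif(3, 0, 2 * pi)
    grav <- .gravity_track(t_act, base, phases = grav_ph)
    phase <- stats::runif(1, 0, 2 * pi)
    ## movement model: an oscillation along a dominant direction (the
    ## stroke/reach direction of the activity) that wobbles minute to
    ## minute, with per-minute vigor (amplitude), waveform shape and
    ## cadence. Shape sign(sin)|sin|^q is impulsive for q > 1
    ## (propulsion-stroke-like), blunt/sustained for q < 1; it moves
    ## the percentile-to-moment ratio of the signal independently of
    ## its amplitude.
    ## stroke direction biased toward the gravity axis (arm strokes
    ## have a strong vertical component), wobbling minute to minute
    u <- base + 0.8 * stats::rnorm(3); u <- u / sqrt(sum(u^2))
    dirs <- u + 0.4 * matrix(stats::rnorm(3 * n_min), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    amp <- p$amplitude_g * exp(stats::rnorm(n_min, 0, p$jitter))
    shape_q <- exp(stats::rnorm(n_min, 0, 0.6))
    freq <- p$freq_hz * exp(stats::rnorm(n_min, 0, 0.2))
    ## per-minute duty cycle: movement comes in bursts (strokes,
    ## reaches) separated by within-cycle pauses; low duty collapses
    ## the quantile spread of a window while its moment spread stays
    ## large, so the two kinds of dispersion vary independently
    duty <- stats::runif(n_min, 0.25, 1)
    minute_of <- pmin(((seq_len(n_s) - 1L) %/% spm) + 1L, n_min)
    cyc <- (freq[minute_of] * t_act + phase / (2 * pi)) %% 1
    osc <- sin(2 * pi * freq[minute_of] * t_act + phase)
    osc <- sign(osc) * abs(osc)^shape_q[minute_of] *
      (cyc < duty[minute_of])
    ## slow per-minute sensor bias drift (DC offset, g): shifts the
    ## location of the per-window distribution without touching its
    ## dispersion
    bias <- matrix(stats::rnorm(3 * n_min, 0, bias_drift_g), ncol = 3)
    ## per-minute tremor fraction (signal-dependent motor noise): the
    ## Gaussian-vs-burst mixture of a minute varies independently of
    ## its amplitude
    trem <- tremor_coeff * exp(stats::rnorm(n_min, 0, 0.6))
    ## impact spikes (pushrim/caster bumps): brief large transients
    ## along the stroke direction; a heavy-tailed component that loads
    ## the moment statistics of a window far more than its quantiles
    spike <- matrix(0, n_s, 3)
    n_spk <- stats::rpois(n_min, spike_rate)
    for (mi in which(n_spk > 0)) {
      pos <- (mi - 1L) * spm +
        sample.int(min(spm, n_s - (mi - 1L) * spm) - 2L, n_spk[mi])
      ## bump magnitude is environmental, not graded by activity vigor
      h <- stats::runif(n_spk[mi], 0.15, 0.5)
      for (k in seq_along(pos)) {
        sd_ <- stats::rnorm(3)  # impact direction, independent per bump
        sd_ <- sd_ / sqrt(sum(sd_^2))
        spike[pos[k]:(pos[k] + 2L), ] <- spike[pos[k]:(pos[k] + 2L), ] +
          outer(h[k] * c(0.5, 1, 0.5), sd_)
      }
    }
    sig <- vapply(1:3, function(ax) {
      amp_ax <- amp[minute_of] * dirs[minute_of, ax]
      noise_sd_ax <- sqrt(sensor_noise_g^2 +
                            (trem[minute_of] * abs(amp_ax))^2)
      grav[, ax] + bias[minute_of, ax] + amp_ax * osc + spike[, ax] +
        stats::rnorm(n_s, 0, noise_sd_ax)
    }, numeric(n_s))
    tt[[i]] <- t_act
    acc_x[[i]] <- sig[, 1]; acc_y[[i]] <- sig[, 2]; acc_z[[i]] <- sig[, 3]
    ## minute VO2 from the generated signal's own features
    rv <- sqrt(rowSums(sig^2))
    for (mi in seq_len(n_min)) {
      s_idx <- ((mi - 1L) * spm + 1L):(mi * spm)
      ch <- list(X = sig[s_idx, 1], Y = sig[s_idx, 2], Z = sig[s_idx, 3],
                 RV = rv[s_idx])
      fv <- vapply(need, .compute_named_feature, 0, ch = ch)
      v <- truth$model$intercept + sum(truth$model$terms * fv)
      if (truth$quadratic_coeff != 0)
        v <- v + truth$quadratic_coeff * fv[[1L]]^2
      v <- max(0, v + stats::rnorm(1, 0, truth$noise_sd))
      mt <- ann_start[i] + (mi - 1L) * 60
      vo2_t[[length(vo2_t) + 1L]] <- mt + seq(0, 59.999, by = vo2_dt)
      vo2_v[[length(vo2_v) + 1L]] <- rep(v, length(vo2_t[[length(vo2_t)]]))
    }
    idx0 <- idx0 + n_s
    ## rest gap after every activity (quiet arm, resting VO2)
    n_r <- as.integer(round(rest_s * rate))
    t_rest <- seg(n_r)
    grav_r <- .gravity_track(t_rest, base, phases = grav_ph)
    rest_sig <- grav_r + matrix(stats::rnorm(3 * n_r, 0, sensor_noise_g),
                                ncol = 3)
    tt[[n_act + i]] <- t_rest
    acc_x[[n_act + i]] <- rest_sig[, 1]
    acc_y[[n_act + i]] <- rest_sig[, 2]
    acc_z[[n_act + i]] <- rest_sig[, 3]
    vo2_t[[length(vo2_t) + 1L]] <- ann_end[i] + seq(0, rest_s - 0.001,
                                                    by = vo2_dt)
    vo2_v[[length(vo2_v) + 1L]] <-
      rep(max(0, rest_vo2), length(vo2_t[[length(vo2_t)]]))
    idx0 <- idx0 + n_r
  }
  o <- order(unlist(tt))
  accel <- accel_recording(unlist(tt)[o], unlist(acc_x)[o],
                           unlist(acc_y)[o], unlist(acc_z)[o],
                           nominal_rate = rate)
  vt <- unlist(vo2_t); vv <- unlist(vo2_v)
  vo2 <- vo2_series(vt, vv, mass_kg = mass_kg)
  ann <- activity_annotations(profiles$label, profiles$type, ann_start,
                              ann_end)
  session(participant_id, accel, vo2, ann)
}

#' Generate a synthetic multi-participant dataset
#'
#' Per participant, the profile amplitudes and the body mass are
#' perturbed by seeded draws (log-normal amplitude multiplier, SD 0.2;
#' mass from the cohort distribution, mean 74.8 kg, SD 18.05 kg,
#' truncated at 40 kg) and a session is generated from a participant
#' sub-seed derived from the master seed, so all randomness flows from
#' `seed`.
#'
#' @param n_participants Number of participants (default 20).
#' @param seed Master integer seed.
#' @param profiles,truth,rate,... Passed to [generate_session()].
#' @return List of `ee_session` objects, named by participant id.
#' @export
generate_dataset <- function(n_participants = 20L, seed = 1L,
                             profiles = activity_profiles(),
                             truth = ground_truth(), rate = 50, ...) {
  stopifnot(n_participants >= 1L)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  amp_mult <- exp(stats::rnorm(n_participants, 0, 0.2))
  mass <- pmax(40, stats::rnorm(n_participants, 74.8, 18.05))
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%02d", i)
    pf <- profiles
    pf$amplitude_g <- pf$amplitude_g * amp_mult[i]
    out[[i]] <- generate_session(pid, profiles = pf, truth = truth,
                                 rate = rate, seed = sub_seeds[i],
                                 mass_kg = mass[i], ...)
  }
  names(out) <- vapply(out, `[[`, "", "participant_id")
  out
}

#' Write a session to a directory of delimited-text files
#'
#' Emits `accel.csv` in the Physics Toolbox dialect (header
#' `time,gFx,gFy,gFz`), `vo2.csv` (`time,vo2`, weight-normalized),
#' `annotations.csv` (`label,type,start_s,end_s`) and `meta.json`
#' (participant id, body mass, nominal rate), readable without loss by
#' [read_session()].
#'
#' @param session An `ee_session`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "ee_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acc <- data.frame(time = session$accel$time, gFx = session$accel$x,
                    gFy = session$accel$y, gFz = session$accel$z)
  utils::write.csv(acc, file.path(dir, "accel.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time = session$vo2$time, vo2 = session$vo2$vo2),
                   file.path(dir, "vo2.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(session$annotations),
                   file.path(dir, "annotations.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(participant_id = session$participant_id,
         mass_kg = session$vo2$mass_kg,
         nominal_rate = session$accel$nominal_rate),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
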