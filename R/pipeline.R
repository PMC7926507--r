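## End-to-end pipeline: simulate -> extract features -> fit the three
## variable sets -> predict -> report. All stage parameters live in a
## single config object that is serialized alongside every output for
## provenance.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its default:
#' 60-s windows, 10 folds, performance curve over 1..10 predictors,
#' 3-predictor final models, sample-entropy pattern length 2 with
#' tolerance 0.3 × SD, 2-level Daubechies-2 wavelet transform.
#'
#' @param window_s Window length, seconds.
#' @param k_folds Number of cross-validation folds.
#' @param max_predictors Upper end of the performance curve.
#' @param final_predictors Predictor count of the final models.
#' @param sampen_m,sampen_r Sample-entropy pattern length and tolerance
#'   coefficient.
#' @param seed Master seed.
#' @param dialect Accelerometer reader dialect.
#' @param group_by_participant Fold over participants instead of
#'   windows.
#' @return An object of class `ee_config` (a named list; the wavelet is
#'   fixed at 2-level Daubechies-2 and recorded for provenance).
#' @export
run_config <- function(window_s = 60, k_folds = 10L, max_predictors = 10L,
                       final_predictors = 3L, sampen_m = 2L, sampen_r = 0.3,
                       seed = 1L, dialect = "physics_toolbox",
                       group_by_participant = FALSE) {
  structure(list(window_s = window_s, k_folds = k_folds,
                 max_predictors = max_predictors,
                 final_predictors = final_predictors,
                 sampen_m = sampen_m, sampen_r = sampen_r,
                 wavelet = "db2", wavelet_levels = 2L, seed = seed,
                 dialect = dialect,
                 group_by_participant = group_by_participant),
            class = "ee_config")
}

.config_hash <- function(config) {
  ser <- paste(names(config), vapply(config, format, ""), sep = "=",
               collapse = ";")
  ## small stable polynomial hash; provenance tag, not cryptographic
  h <- 0
  for (b in utf8ToInt(ser)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline over a set of session directories
#'
#' Reads each session directory (as written by [write_session()]),
#' segments it into minute windows, extracts the 55 features, runs the
#' cross-validated forward-selection experiment for the three variable
#' sets, and writes the feature table, an experiment report
#' (`report.json`: config with hash and package version, per-set
#' performance curves, final models, per-task error tables) and one
#' model file per variable set to `out_dir`. Deterministic given the
#' config seed.
#'
#' @param session_dirs Character vector of session directories.
#' @param out_dir Output directory.
#' @param config An [run_config()] object.
#' @return Invisibly, the report list.
#' @export
run_pipeline <- function(session_dirs, out_dir, config = run_config()) {
  stopifnot(inherits(config, "ee_config"))
  missing_dirs <- session_dirs[!dir.exists(session_dirs)]
  if (length(missing_dirs))
    stop("[read] missing session director", if (length(missing_dirs) > 1)
      "ies: " else "y: ", paste(missing_dirs, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  windows <- list()
  for (d in session_dirs) {
    s <- read_session(d)
    w <- segment_minutes(s, window_s = config$window_s)
    message(sprintf("[segment] %s: %d windows", s$participant_id, length(w)))
    windows <- c(windows, w)
  }
  message(sprintf("[features] extracting 55 variables for %d windows",
                  length(windows)))
  tab <- extract_feature_table(windows, m = config$sampen_m,
                               r_coeff = config$sampen_r)
  write_feature_table(tab, file.path(out_dir, "features.csv"))
  provenance <- list(package_version =
                       as.character(utils::packageVersion("wheelchairEE")),
                     config = unclass(config),
                     config_hash = .config_hash(config))
  report <- list(provenance = provenance, models = list())
  for (vs in c("all", "linear", "nonlinear")) {
    message(sprintf("[fit] variable set '%s'", vs))
    cv <- run_cv_experiment(tab, variable_set = vs, k = config$k_folds,
                            max_k = config$max_predictors,
                            final_k = config$final_predictors,
                            seed = config$seed,
                            group_by_participant = config$group_by_participant)
    tet <- task_error_table(cv$validation$pred, cv$validation$obs,
                            cv$validation$label)
    report$models[[vs]] <- list(
      final_predictors = cv$final_predictors,
      intercept = cv$final_model$intercept,
      coefficients = as.list(cv$final_model$terms),
      curve = cv$curve,
      task_errors = tet)
    jsonlite::write_json(
      c(provenance, list(variable_set = vs,
                         intercept = cv$final_model$intercept,
                         terms = as.list(cv$final_model$terms))),
      file.path(out_dir, paste0("model_", vs, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(report)
}

#' Simulate a dataset and write it as session directories
#'
#' Convenience wrapper around [generate_dataset()] and
#' [write_session()]; also writes a `manifest.json` recording the
#' ground-truth equation and noise level.
#'
#' @param out_dir Output directory (one sub-directory per participant).
#' @param n_participants,seed,truth,rate Passed to [generate_dataset()].
#' @param ... Further arguments to [generate_dataset()].
#' @return Character vector of the written session directories.
#' @export
simulate_dataset <- function(out_dir, n_participants = 20L, seed = 1L,
                             truth = ground_truth(), rate = 50, ...) {
  sessions <- generate_dataset(n_participants = n_participants, seed = seed,
                               truth = truth, rate = rate, ...)
  dirs <- character(length(sessions))
  for (i in seq_along(sessions)) {
    dirs[i] <- file.path(out_dir, sessions[[i]]$participant_id)
    write_session(sessions[[i]], dirs[i])
  }
  jsonlite::write_json(
    list(n_participants = n_participants, seed = seed, rate = rate,
         truth = list(intercept = truth$model$intercept,
                      terms = as.list(truth$model$terms),
                      noise_sd = truth$noise_sd,
                      quadratic_coeff = truth$quadratic_coeff)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  dirs
}
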