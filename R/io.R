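#' Write a trial log to CSV
#'
#' Columns: `subject_id`, `task`, `trial_index`, `phase`, `stimulus_deg`,
#' `response`, `posterior_mean_deg`, `posterior_sd_deg`. Running posterior
#' columns are filled with `NA` when absent (e.g. manually assembled logs).
#' Round-trips losslessly through [read_trial_log()].
#'
#' @param trials Trial tibble (or a `psych_session`, whose `trials` are
#'   used).
#' @param path Output file path.
#' @param subject_id Subject identifier written into every row.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path, subject_id = "S1") {
  if (inherits(trials, "psych_session")) trials <- trials$trials
  out <- tibble::tibble(
    subject_id = subject_id,
    task = trials$task,
    trial_index = trials$trial_index,
    phase = trials$phase,
    stimulus_deg = trials$stimulus_deg,
    response = as_response_token(trials$response),
    posterior_mean_deg = if ("posterior_mean_deg" %in% names(trials)) {
      trials$posterior_mean_deg
    } else NA_real_,
    posterior_sd_deg = if ("posterior_sd_deg" %in% names(trials)) {
      trials$posterior_sd_deg
    } else NA_real_
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a trial log from CSV
#'
#' Validates every row; malformed rows are reported with their line numbers
#' (header = line 1).
#'
#' @param path CSV file written by [write_trial_log()] (or matching its
#'   schema).
#' @return Validated trial tibble.
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      task = readr::col_character(),
      trial_index = readr::col_integer(),
      phase = readr::col_character(),
      stimulus_deg = readr::col_double(),
      response = readr::col_character(),
      posterior_mean_deg = readr::col_double(),
      posterior_sd_deg = readr::col_double()
    )
  )
  line <- seq_len(nrow(raw)) + 1L
  bad <- !raw$response %in% c("PREFER_PF", "PREFER_DF") |
    !raw$task %in% c("LW", "RA", "RD") |
    !raw$phase %in% c("block", "adaptive", "manual") |
    !is.finite(raw$stimulus_deg)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    rlang::abort(paste0("malformed trial rows at line(s): ",
                        toString(line[bad])))
  }
  if (anyDuplicated(raw[c("subject_id", "task", "trial_index")]) > 0) {
    rlang::abort("duplicate trial_index within a session.")
  }
  raw
}

#' Default run configuration
#'
#' One JSON-serializable list gathering every protocol and processing
#' parameter: task angle grids (seven equally spaced angles centered on 0
#' for LW, +4.5 for RA, -4.5 for RD), trial counts (14 block + 21 adaptive),
#' the 0.75-degree adaptive increment, the adaptive prior (PSE uniform over
#' the tested range, slope log-uniform over 0.3–3) with its assumed 5%
#' lapse, the 2% lapse fixed in final fits, and the filter/segmentation
#' settings of the biomechanics pipeline.
#'
#' @param seed Integer seed stored in the config.
#' @return A nested list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    tasks = list(
      LW = list(block_angles = seq(-4.5, 4.5, by = 1.5)),
      RA = list(block_angles = seq(0, 9, by = 1.5)),
      RD = list(block_angles = seq(-9, 0, by = 1.5))
    ),
    protocol = list(n_block_reps = 2, n_adaptive = 21,
                    adaptive_increment = 0.75),
    adaptive = list(assumed_lapse = 0.05, slope_prior = c(0.3, 3),
                    alpha_step = 0.25, n_slope = 41, pad = 3),
    fitting = list(lapse = 0.02, slope_bounds = c(0.05, 10)),
    biomech = list(sample_rate = 500, lowpass_cutoff = 50, lowpass_order = 2,
                   heel_threshold_fraction = 0.1, refractory_s = 0.4,
                   comp_filter_tau = 1, n_gait_points = 101),
    seed = seed
  )
}

#' Write / read a run configuration as JSON
#'
#' `read_run_config()` validates the task angle grids (seven equally spaced
#' values each) and names any missing top-level keys. Load/dump/load is the
#' identity.
#'
#' @param config A configuration list (see [default_run_config()]).
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("tasks", "protocol", "adaptive", "fitting", "biomech", "seed")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0) {
    rlang::abort(paste0("config missing key(s): ", toString(missing)))
  }
  for (tk in names(cfg$tasks)) {
    ang <- cfg$tasks[[tk]]$block_angles
    d <- diff(ang)
    if (length(ang) != 7 || max(abs(d - d[1])) > 1e-9) {
      rlang::abort(paste0("task ", tk,
                          ": block_angles must be 7 equally spaced values."))
    }
  }
  cfg
}

#' Serialize a psychometric fit to JSON
#'
#' @param fit A `psych_fit`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "psych_fit"))
  jsonlite::write_json(
    list(pse = fit$pse, slope = fit$slope,
         reliability_index = fit$reliability_index, pse_se = fit$pse_se,
         lapse = fit$lapse, log_lik = fit$log_lik, n_trials = fit$n_trials,
         converged = fit$converged, boundary = fit$boundary),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
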