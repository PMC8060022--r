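#' Session configuration for a preference test
#'
#' Encodes the forced-choice protocol: seven equally spaced block angles
#' (centered on 0 degrees for level walking, +4.5 for ramp ascent, -4.5 for
#' ramp descent), each presented twice in seeded random order, followed by
#' adaptive trials whose candidate stimuli lie on an arithmetic grid at
#' `adaptive_increment` (default 0.75 degrees, half the block spacing) across
#' the tested range.
#'
#' @param task `"LW"`, `"RA"` or `"RD"`; sets the default block angles.
#' @param block_angles Seven equally spaced angles, degrees. Defaults:
#'   LW -4.5..4.5, RA 0..9, RD -9..0, step 1.5.
#' @param n_block_reps Presentations of each block angle (default 2, so 14
#'   block trials; 0 gives a fully adaptive session).
#' @param n_adaptive Number of adaptive trials (default 21).
#' @param adaptive_increment Candidate grid spacing in the adaptive phase,
#'   degrees (default 0.75).
#' @param assumed_lapse Lapse rate assumed by the adaptive algorithm
#'   (default 0.05).
#' @param slope_prior Slope prior support, 1/degrees (default `c(0.3, 3)`).
#' @param alpha_step,n_slope,pad Posterior grid resolution, see
#'   [posterior_grid()].
#' @param range_shift Optional `list(trial =, by =)`: from trial `trial`
#'   onward the candidate set is shifted by `by` degrees (used when a
#'   preference sits near the edge of the tested range). The posterior grid
#'   is kept fixed so no information is discarded mid-session.
#' @param manual_stimuli Stimuli appended after the protocol as
#'   `phase = "manual"` trials; they update the posterior like any trial.
#' @param seed Integer seed for the session RNG (block shuffle, response
#'   draws of a stochastic responder, tie-breaks). `NULL` uses the current
#'   RNG state.
#' @return A `session_config` list.
#' @export
session_config <- function(task = c("LW", "RA", "RD"), block_angles = NULL,
                           n_block_reps = 2, n_adaptive = 21,
                           adaptive_increment = 0.75, assumed_lapse = 0.05,
                           slope_prior = c(0.3, 3), alpha_step = 0.25,
                           n_slope = 41, pad = 3, range_shift = NULL,
                           manual_stimuli = numeric(0), seed = NULL) {
  task <- match.arg(task)
  if (is.null(block_angles)) {
    center <- c(LW = 0, RA = 4.5, RD = -4.5)[[task]]
    block_angles <- center + seq(-4.5, 4.5, by = 1.5)
  }
  d <- diff(block_angles)
  if (length(block_angles) < 2 || any(d <= 0) ||
      max(abs(d - d[1])) > 1e-9) {
    rlang::abort("`block_angles` must be increasing and equally spaced.")
  }
  if (!is.null(range_shift) &&
      !all(c("trial", "by") %in% names(range_shift))) {
    rlang::abort("`range_shift` must be list(trial =, by =).")
  }
  structure(
    list(task = task, block_angles = block_angles,
         n_block_reps = n_block_reps,
         n_block = n_block_reps * length(block_angles),
         n_adaptive = n_adaptive, adaptive_increment = adaptive_increment,
         assumed_lapse = assumed_lapse, slope_prior = slope_prior,
         alpha_step = alpha_step, n_slope = n_slope, pad = pad,
         range_shift = range_shift, manual_stimuli = manual_stimuli,
         seed = seed),
    class = "session_config"
  )
}

#' Simulated forced-choice responder
#'
#' Returns a closure that answers a stimulus with a Bernoulli draw from the
#' cumulative-normal decision model at the given true parameters, using the
#' calling RNG stream (so a seeded session is fully reproducible).
#'
#' @inheritParams psych_prob
#' @return `function(stimulus) -> "PREFER_PF" | "PREFER_DF"`.
#' @export
make_responder <- function(pse, slope, lapse = 0.02) {
  check_psych_params(pse, slope, lapse)
  function(stimulus) {
    p <- psych_prob(stimulus, pse, slope, lapse)
    if (stats::runif(1) < p) "PREFER_PF" else "PREFER_DF"
  }
}

#' Run one adaptive forced-choice session
#'
#' Executes the hybrid protocol: `n_block` trials presenting each block angle
#' `n_block_reps` times in seeded random order, then `n_adaptive` trials
#' chosen by expected-entropy minimization over the candidate grid. The
#' posterior is updated after every trial, block trials included, so the
#' adaptive phase starts from all available information. Supports a
#' mid-session candidate-range shift and appended manual trials.
#'
#' A responder that errors mid-session yields a partial log with
#' `incomplete = TRUE` rather than an exception.
#'
#' @param responder `function(stimulus) -> response` (token, 0/1 or logical).
#' @param config A [session_config()].
#' @return A `psych_session`: list with `trials` (tibble including per-trial
#'   running posterior mean/SD), `posterior` (final `posterior_grid`),
#'   `config`, and `incomplete`.
#' @export
run_session <- function(responder, config) {
  stopifnot(inherits(config, "session_config"))
  if (!is.null(config$seed)) withr::local_seed(config$seed)

  rng <- range(config$block_angles)
  grid <- posterior_grid(rng, slope_range = config$slope_prior,
                         lapse = config$assumed_lapse,
                         alpha_step = config$alpha_step,
                         n_slope = config$n_slope, pad = config$pad)
  candidates <- seq(rng[1], rng[2], by = config$adaptive_increment)
  lik_cache <- candidate_likelihoods(grid, candidates)

  n_total <- config$n_block + config$n_adaptive
  block_order <- if (config$n_block > 0) {
    sample(rep(config$block_angles, config$n_block_reps))
  } else numeric(0)

  stim <- resp <- pmean <- psd <- numeric(0)
  phase <- character(0)
  incomplete <- FALSE
  shifted <- FALSE

  for (i in seq_len(n_total)) {
    if (!is.null(config$range_shift) && !shifted &&
        i >= config$range_shift$trial) {
      candidates <- candidates + config$range_shift$by
      lik_cache <- candidate_likelihoods(grid, candidates)
      shifted <- TRUE
    }
    if (i <= config$n_block) {
      x <- block_order[i]
      ph <- "block"
    } else {
      x <- select_next_stimulus(grid, candidates, lik_cache)
      ph <- "adaptive"
    }
    r <- tryCatch(responder(x), error = function(e) NULL)
    if (is.null(r) || (length(r) == 1 && is.na(r))) {
      incomplete <- TRUE
      break
    }
    grid <- update_posterior(grid, x, r)
    est <- posterior_estimates(grid)
    stim <- c(stim, x); resp <- c(resp, response_to_binary(r))
    phase <- c(phase, ph)
    pmean <- c(pmean, est$pse_mean); psd <- c(psd, est$pse_sd)
  }

  if (!incomplete) {
    for (x in config$manual_stimuli) {
      r <- tryCatch(responder(x), error = function(e) NULL)
      if (is.null(r)) { incomplete <- TRUE; break }
      grid <- update_posterior(grid, x, r)
      est <- posterior_estimates(grid)
      stim <- c(stim, x); resp <- c(resp, response_to_binary(r))
      phase <- c(phase, "manual")
      pmean <- c(pmean, est$pse_mean); psd <- c(psd, est$pse_sd)
    }
  }

  trials <- tibble::tibble(
    task = config$task,
    trial_index = seq_along(stim),
    phase = phase,
    stimulus_deg = stim,
    response = ifelse(resp == 1, "PREFER_PF", "PREFER_DF"),
    posterior_mean_deg = pmean,
    posterior_sd_deg = psd
  )
  structure(
    list(trials = trials, posterior = grid, config = config,
         incomplete = incomplete),
    class = "psych_session"
  )
}

#' @export
print.psych_session <- function(x, ...) {
  est <- posterior_estimates(x$posterior)
  cat(sprintf("psych_session: task %s, %d trials%s\n", x$config$task,
              nrow(x$trials), if (x$incomplete) " (incomplete)" else ""))
  cat(sprintf("  final posterior PSE %.2f deg (SD %.2f)\n",
              est$pse_mean, est$pse_sd))
  invisible(x)
}

#' Run a full preference study on a synthetic cohort
#'
#' For every subject and task in a cohort (see [generate_cohort()]), runs a
#' seeded adaptive session against that subject's true decision model and
#' fits the psychometric function (lapse fixed at `fit_lapse`). When the
#' first session's posterior mean lands within `edge_margin` of the candidate
#' range edge (or beyond it), the session is re-run with the candidate range
#' shifted toward the estimate from the first adaptive trial onward —
#' mirroring the protocol adaptation used for participants whose preference
#' exceeds the default tested range.
#'
#' @param cohort Tibble from [generate_cohort()] (one row per subject x task,
#'   columns `subject`, `task`, `pse`, `slope`, `lapse`).
#' @param seed Integer master seed; per-session seeds are derived from it.
#' @param fit_lapse Lapse rate fixed in the final fits (default 0.02).
#' @param edge_margin Degrees from the range edge that triggers a shifted
#'   re-run (default 1.5, one block-angle spacing).
#' @param ... Passed to [session_config()] (e.g. `n_adaptive`).
#' @return Tibble with one row per subject x task: fitted `pse`, `slope`,
#'   `reliability_index`, flags, the applied `range_shift_deg`, plus the true
#'   parameters, and a list-column `trials` of session logs.
#' @export
run_preference_study <- function(cohort, seed = 1L, fit_lapse = 0.02,
                                 edge_margin = 1.5, ...) {
  needed <- c("subject", "task", "pse", "slope", "lapse")
  if (!all(needed %in% names(cohort))) {
    rlang::abort(paste0("`cohort` must have columns: ", toString(needed)))
  }
  session_seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max, nrow(cohort)))

  purrr::pmap_dfr(
    list(cohort$subject, cohort$task, cohort$pse, cohort$slope, cohort$lapse,
         session_seeds),
    function(subject, task, true_pse, true_slope, true_lapse, s_seed) {
      responder <- make_responder(true_pse, true_slope, true_lapse)
      cfg <- session_config(task = task, seed = s_seed, ...)
      ses <- run_session(responder, cfg)
      fit <- fit_psychometric(ses$trials, lapse = fit_lapse)
      rng <- range(cfg$block_angles)
      inc <- cfg$adaptive_increment
      shift <- 0
      # re-run with a shifted candidate range while the fitted preference
      # sits at (or beyond) the shifted range edge; preferences far outside
      # the default range may need more than one enlargement
      for (k in 1:3) {
        lo <- rng[1] + shift; hi <- rng[2] + shift
        if (fit$pse <= hi - edge_margin && fit$pse >= lo + edge_margin) break
        shift <- shift +
          max(-12, min(12, round((fit$pse - (lo + hi) / 2) / inc) * inc))
        cfg2 <- session_config(task = task, seed = s_seed,
                               range_shift = list(trial = cfg$n_block + 1,
                                                  by = shift), ...)
        ses <- run_session(responder, cfg2)
        fit <- fit_psychometric(ses$trials, lapse = fit_lapse)
      }
      tibble::tibble(
        subject = subject, task = task,
        pse = fit$pse, slope = fit$slope,
        reliability_index = fit$reliability_index,
        pse_se = fit$pse_se, boundary = fit$boundary,
        range_shift_deg = shift,
        true_pse = true_pse, true_slope = true_slope, true_lapse = true_lapse,
        trials = list(ses$trials)
      )
    }
  )
}
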