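#' Simulate one forced-choice response
#'
#' Bernoulli draw from the cumulative-normal decision model: PREFER_PF with
#' probability \eqn{\psi(x)} under the true parameters. Uses the calling RNG
#' stream.
#'
#' @inheritParams psych_prob
#' @return `"PREFER_PF"` or `"PREFER_DF"`.
#' @export
simulate_response <- function(stimulus, pse, slope, lapse = 0.02) {
  p <- psych_prob(stimulus, pse, slope, lapse)
  ifelse(stats::runif(length(p)) < p, "PREFER_PF", "PREFER_DF")
}

#' Simulate a fixed-design trial log
#'
#' Draws responses at the given stimuli from a simulated subject; useful for
#' fit-recovery studies that do not involve the adaptive engine.
#'
#' @param stimuli Stimulus angles, degrees.
#' @inheritParams psych_prob
#' @param task Task label for the log.
#' @return A trial tibble (see [trial_log()]).
#' @export
simulate_trials <- function(stimuli, pse, slope, lapse = 0.02, task = "LW") {
  trial_log(task, stimuli, simulate_response(stimuli, pse, slope, lapse))
}

design_config <- function(design, task, assumed_lapse, ...) {
  base <- switch(design,
    hybrid_14_21 = list(n_block_reps = 2, n_adaptive = 21),
    full_adaptive_35 = list(n_block_reps = 0, n_adaptive = 35),
    rlang::abort(paste0("unknown design: ", design))
  )
  args <- utils::modifyList(base, list(...))
  do.call(session_config,
          c(list(task = task, assumed_lapse = assumed_lapse), args))
}

#' Monte-Carlo evaluation of a session design
#'
#' Runs `n_reps` seeded sessions of the named design against each true
#' parameter set, fits every resulting log with [fit_psychometric()], and
#' tabulates bias and RMSE of the PSE and slope estimates. Fully reproducible
#' from `seed`; fit failures are counted, never raised.
#'
#' The two named designs replicate the protocol comparison used when tuning
#' the adaptive algorithm: `hybrid_14_21` presents each of the seven block
#' angles twice (14 trials) before 21 adaptive trials; `full_adaptive_35`
#' lets the adaptive algorithm pick all 35 stimuli.
#'
#' @param design `"hybrid_14_21"` or `"full_adaptive_35"`.
#' @param truth Data frame of true parameters, columns `pse`, `slope`,
#'   `lapse` (one row per simulated-subject condition).
#' @param n_reps Sessions per condition (>= 2).
#' @param seed Integer master seed.
#' @param task Task whose angle range is used (default `"LW"`).
#' @param assumed_lapse Lapse assumed by the adaptive algorithm (default 0.05).
#' @param fit_lapse Lapse fixed in the final fits (default 0.02).
#' @param ... Passed to [session_config()].
#' @return Tibble keyed by (true pse, slope, lapse): `bias_pse`, `rmse_pse`,
#'   `bias_slope`, `rmse_slope`, `n_ok`, `n_fail`, plus a list-column
#'   `estimates` with the per-rep fits.
#' @export
evaluate_design <- function(design, truth, n_reps, seed = 1L, task = "LW",
                            assumed_lapse = 0.05, fit_lapse = 0.02, ...) {
  stopifnot(n_reps >= 2)
  truth <- tibble::as_tibble(truth)
  if (!all(c("pse", "slope", "lapse") %in% names(truth))) {
    rlang::abort("`truth` needs columns pse, slope, lapse.")
  }
  rep_seeds <- withr::with_seed(
    seed, matrix(sample.int(.Machine$integer.max, nrow(truth) * n_reps),
                 nrow = nrow(truth)))

  purrr::pmap_dfr(
    c(truth[c("pse", "slope", "lapse")], list(row = seq_len(nrow(truth)))),
    function(pse, slope, lapse, row) {
      est <- purrr::map_dfr(seq_len(n_reps), function(rep) {
        cfg <- design_config(design, task, assumed_lapse,
                             seed = rep_seeds[row, rep], ...)
        ses <- run_session(make_responder(pse, slope, lapse), cfg)
        fit <- tryCatch(fit_psychometric(ses$trials, lapse = fit_lapse),
                        error = function(e) NULL)
        if (is.null(fit)) {
          tibble::tibble(rep = rep, pse_hat = NA_real_,
                         slope_hat = NA_real_, boundary = NA)
        } else {
          tibble::tibble(rep = rep, pse_hat = fit$pse,
                         slope_hat = fit$slope, boundary = fit$boundary)
        }
      })
      ok <- !is.na(est$pse_hat)
      tibble::tibble(
        design = design, pse = pse, slope = slope, lapse = lapse,
        bias_pse = mean(est$pse_hat[ok]) - pse,
        rmse_pse = sqrt(mean((est$pse_hat[ok] - pse)^2)),
        bias_slope = mean(est$slope_hat[ok]) - slope,
        rmse_slope = sqrt(mean((est$slope_hat[ok] - slope)^2)),
        n_ok = sum(ok), n_fail = sum(!ok),
        n_boundary = sum(est$boundary[ok]),
        estimates = list(est)
      )
    }
  )
}

#' Sensitivity of slope recovery to the assumed lapse rate
#'
#' The adaptive algorithm must assume a lapse rate when selecting stimuli.
#' This study runs matched seeded sessions (common random numbers across
#' assumed-lapse settings) against one true subject and tabulates the RMSE of
#' the fitted slope for each assumed value, exposing the penalty for
#' underestimating the lapse rate: a single lapse far from the preference,
#' interpreted at face value, drags the running slope estimate (and hence
#' stimulus placement) badly off course.
#'
#' @param assumed_lapses Lapse rates for the adaptive algorithm to assume.
#' @param truth One-row data frame (or list): true `pse`, `slope`, `lapse`.
#' @param n_reps Sessions per assumed value.
#' @param seed Integer master seed; the same per-rep seeds are reused across
#'   assumed values.
#' @param design Session design (default `"hybrid_14_21"`).
#' @inheritParams evaluate_design
#' @return Tibble: `assumed_lapse`, `rmse_slope`, `bias_slope`, `rmse_pse`,
#'   `n_ok`.
#' @export
lapse_sensitivity <- function(assumed_lapses, truth, n_reps, seed = 1L,
                              design = "hybrid_14_21", task = "LW",
                              fit_lapse = 0.02, ...) {
  truth <- as.list(tibble::as_tibble(truth)[1, c("pse", "slope", "lapse")])
  rep_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, n_reps))
  purrr::map_dfr(assumed_lapses, function(al) {
    est <- purrr::map_dfr(seq_len(n_reps), function(rep) {
      cfg <- design_config(design, task, al, seed = rep_seeds[rep], ...)
      ses <- run_session(
        make_responder(truth$pse, truth$slope, truth$lapse), cfg)
      fit <- tryCatch(fit_psychometric(ses$trials, lapse = fit_lapse),
                      error = function(e) NULL)
      tibble::tibble(
        pse_hat = if (is.null(fit)) NA_real_ else fit$pse,
        slope_hat = if (is.null(fit)) NA_real_ else fit$slope
      )
    })
    ok <- !is.na(est$slope_hat)
    tibble::tibble(
      assumed_lapse = al,
      rmse_slope = sqrt(mean((est$slope_hat[ok] - truth$slope)^2)),
      bias_slope = mean(est$slope_hat[ok]) - truth$slope,
      rmse_pse = sqrt(mean((est$pse_hat[ok] - truth$pse)^2)),
      n_ok = sum(ok)
    )
  })
}
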