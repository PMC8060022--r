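#' Cumulative-normal psychometric function with lapse
#'
#' Probability of a "prefer plantarflexion" (toes-down) response at a given
#' stimulus ankle angle, under the decision model
#' \deqn{\psi(x) = \lambda/2 + (1 - \lambda)\,\Phi(s (x - \alpha))}
#' where \eqn{\alpha} is the point of subjective equality (PSE, the preferred
#' angle), \eqn{s} the slope (1/degrees) and \eqn{\lambda} the lapse rate.
#' The symmetric lapse placement keeps \eqn{\psi(\alpha) = 0.5} for any lapse,
#' so the PSE always marks the 50/50 split between the two responses.
#'
#' Convention: dorsiflexion is positive, and the probability of preferring
#' plantarflexion increases with stimulus angle (an over-dorsiflexed ankle
#' elicits "toes down").
#'
#' @param stimulus Stimulus ankle angle(s) in degrees (dorsiflexion positive).
#' @param pse Point of subjective equality (degrees).
#' @param slope Slope of the psychometric function (1/degrees), > 0.
#' @param lapse Lapse rate in [0, 0.5).
#' @return Probability (or vector of probabilities) of a PREFER_PF response.
#' @examples
#' psych_prob(0, pse = 0, slope = 1)        # 0.5 at the PSE
#' psych_prob(1.5, pse = 0, slope = 1/1.5)  # one SD away: ~0.84
#' @export
psych_prob <- function(stimulus, pse, slope, lapse = 0) {
  check_psych_params(pse, slope, lapse)
  if (!all(is.finite(stimulus))) {
    rlang::abort("`stimulus` must be finite.")
  }
  lapse / 2 + (1 - lapse) * stats::pnorm(slope * (stimulus - pse))
}

check_psych_params <- function(pse, slope, lapse) {
  if (!is.finite(pse)) rlang::abort("`pse` must be finite.")
  if (!is.finite(slope) || slope <= 0) rlang::abort("`slope` must be > 0.")
  if (!is.finite(lapse) || lapse < 0 || lapse >= 0.5) {
    rlang::abort("`lapse` must lie in [0, 0.5).")
  }
  invisible(TRUE)
}

#' Trial-log constructor
#'
#' Assembles a validated tibble of forced-choice trials. Responses are coded
#' with the tokens `"PREFER_PF"` (prefer plantarflexion / toes down) and
#' `"PREFER_DF"` (prefer dorsiflexion / toes up).
#'
#' @param task Task label: `"LW"` (level walking), `"RA"` (ramp ascent) or
#'   `"RD"` (ramp descent).
#' @param stimulus_deg Stimulus angles, degrees.
#' @param response Response tokens (`PREFER_PF` / `PREFER_DF`) or 0/1
#'   (1 = PREFER_PF) or logical (TRUE = PREFER_PF).
#' @param phase Trial phase: `"block"`, `"adaptive"` or `"manual"`.
#' @return A tibble with columns `task`, `trial_index`, `phase`,
#'   `stimulus_deg`, `response`.
#' @export
trial_log <- function(task, stimulus_deg, response, phase = "adaptive") {
  task <- match.arg(task, c("LW", "RA", "RD"))
  n <- length(stimulus_deg)
  if (!all(is.finite(stimulus_deg))) rlang::abort("stimuli must be finite.")
  response <- as_response_token(response)
  phase <- rep_len(phase, n)
  bad_phase <- setdiff(unique(phase), c("block", "adaptive", "manual"))
  if (length(bad_phase) > 0) {
    rlang::abort(paste0("unknown phase label(s): ", toString(bad_phase)))
  }
  tibble::tibble(
    task = task,
    trial_index = seq_len(n),
    phase = phase,
    stimulus_deg = as.numeric(stimulus_deg),
    response = response
  )
}

as_response_token <- function(response) {
  if (is.logical(response)) response <- as.integer(response)
  if (is.numeric(response)) {
    if (!all(response %in% c(0, 1))) {
      rlang::abort("numeric responses must be 0 (PREFER_DF) or 1 (PREFER_PF).")
    }
    return(ifelse(response == 1, "PREFER_PF", "PREFER_DF"))
  }
  response <- as.character(response)
  bad <- setdiff(unique(response), c("PREFER_PF", "PREFER_DF"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown response token(s): ", toString(bad)))
  }
  response
}

response_to_binary <- function(response) {
  as.integer(as_response_token(response) == "PREFER_PF")
}

#' Negative log-likelihood of a trial log
#'
#' \eqn{-\sum_i [r_i \log\psi(x_i) + (1-r_i)\log(1-\psi(x_i))]} in nats, with
#' \eqn{r_i = 1} for PREFER_PF. Additive over trials. An empty trial log
#' returns 0 with a warning.
#'
#' @param trials Data frame with columns `stimulus_deg` and `response`.
#' @inheritParams psych_prob
#' @return Negative log-likelihood in nats.
#' @export
psych_nll <- function(trials, pse, slope, lapse = 0.02) {
  if (nrow(trials) == 0) {
    rlang::warn("empty trial log: negative log-likelihood is 0.")
    return(0)
  }
  x <- trials$stimulus_deg
  r <- response_to_binary(trials$response)
  p <- psych_prob(x, pse, slope, lapse)
  -sum(r * log(p) + (1 - r) * log1p(-p))
}

# NLL evaluated on vectors of (pse, log slope) pairs; vectorized over the
# parameter grid for the coarse seed search. Returns a vector.
nll_on_grid <- function(x, r, pse_vec, log_slope_vec, lapse) {
  s <- exp(log_slope_vec)
  nll <- numeric(length(pse_vec))
  for (i in seq_along(x)) {
    p <- lapse / 2 + (1 - lapse) * stats::pnorm(s * (x[i] - pse_vec))
    nll <- nll - if (r[i] == 1) log(p) else log1p(-p)
  }
  nll
}

#' Fit the psychometric function by maximum likelihood
#'
#' Fits PSE and slope of the cumulative-normal decision model to a trial log
#' with the lapse rate held fixed (default 0.02). The optimizer is
#' deterministic: a coarse grid over (PSE, log slope) seeds a bounded
#' quasi-Newton refinement, so repeated fits of the same log are identical.
#' The standard error of the PSE comes from the observed information
#' (curvature of the log-likelihood at the optimum).
#'
#' Degenerate data never raise: perfectly separated responses return a fit
#' with the slope clamped at its upper bound and `boundary` set; one-sided
#' response sets return a PSE outside the tested range, also flagged.
#'
#' @param trials Data frame with columns `stimulus_deg` and `response`.
#' @param lapse Fixed lapse rate used in fitting (default 0.02).
#' @param slope_bounds Allowed slope range (1/degrees). Wider than the
#'   adaptive prior on purpose: the prior constrains stimulus selection, not
#'   the final fit.
#' @return A `psych_fit` object: list with elements `pse`, `slope`, `lapse`,
#'   `reliability_index` (= 1/slope, degrees), `pse_se`, `log_lik`,
#'   `converged`, `boundary`, `n_trials`, plus the trial data.
#' @seealso [reliability_index()], [pool_centered_fit()]
#' @export
fit_psychometric <- function(trials, lapse = 0.02, slope_bounds = c(0.05, 10)) {
  stopifnot(length(slope_bounds) == 2, slope_bounds[1] > 0,
            slope_bounds[2] > slope_bounds[1])
  if (nrow(trials) == 0) rlang::abort("cannot fit an empty trial log.")
  x <- as.numeric(trials$stimulus_deg)
  r <- response_to_binary(trials$response)
  log_sb <- log(slope_bounds)

  # coarse deterministic seed over the padded stimulus range
  a_grid <- seq(min(x) - 3, max(x) + 3, length.out = 81)
  ls_grid <- seq(log_sb[1], log_sb[2], length.out = 41)
  grid <- expand.grid(a = a_grid, ls = ls_grid)
  seed_nll <- nll_on_grid(x, r, grid$a, grid$ls, lapse)

  # refine from several well-separated seeds: binomial likelihoods in
  # (pse, log slope) can carry near-tied basins on flat ridges
  ord <- order(seed_nll)
  seeds <- list()
  for (i in ord) {
    cand <- c(grid$a[i], grid$ls[i])
    if (all(vapply(seeds, function(s) {
      abs(s[1] - cand[1]) < 0.75 && abs(s[2] - cand[2]) < 0.5
    }, logical(1)) == FALSE)) {
      seeds[[length(seeds) + 1]] <- cand
    }
    if (length(seeds) >= 6) break
  }

  obj <- function(par) {
    p <- lapse / 2 + (1 - lapse) * stats::pnorm(exp(par[2]) * (x - par[1]))
    -sum(r * log(p) + (1 - r) * log1p(-p))
  }
  span <- diff(range(x)) + 1
  opts <- lapply(seeds, function(s) {
    stats::optim(
      s, obj, method = "L-BFGS-B",
      lower = c(min(x) - 10 * span, log_sb[1]),
      upper = c(max(x) + 10 * span, log_sb[2])
    )
  })
  opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
  pse <- opt$par[1]
  slope <- exp(opt$par[2])
  at_slope_bound <- min(abs(opt$par[2] - log_sb)) < 1e-6
  out_of_range <- pse < min(x) || pse > max(x)

  pse_se <- tryCatch({
    h <- stats::optimHess(opt$par, obj)
    # delta-method back to (pse, slope) not needed for pse: first coordinate
    # is already pse, so invert the observed information directly.
    v <- solve(h)
    if (v[1, 1] > 0) sqrt(v[1, 1]) else NA_real_
  }, error = function(e) NA_real_)

  structure(
    list(
      pse = pse, slope = slope, lapse = lapse,
      reliability_index = 1 / slope,
      pse_se = pse_se,
      log_lik = -opt$value,
      converged = opt$convergence == 0,
      boundary = at_slope_bound || out_of_range,
      at_slope_bound = at_slope_bound,
      pse_in_range = !out_of_range,
      slope_bounds = slope_bounds,
      n_trials = length(x),
      data = tibble::as_tibble(trials)
    ),
    class = "psych_fit"
  )
}

#' Reliability Index of a fitted psychometric function
#'
#' The Reliability Index is the standard deviation of the underlying Gaussian,
#' i.e. the reciprocal of the fitted slope (degrees). It is the deviation from
#' preference at which, absent lapses, 84% of responses favor a change back
#' toward the preference (\eqn{\Phi(1) \approx 0.8413}).
#'
#' @param fit A `psych_fit` object.
#' @return Reliability Index in degrees. Warns when the fit sat on a boundary.
#' @export
reliability_index <- function(fit) {
  stopifnot(inherits(fit, "psych_fit"))
  if (isTRUE(fit$boundary)) {
    rlang::warn("fit hit a parameter boundary; Reliability Index is unreliable.")
  }
  1 / fit$slope
}

#' Pooled, subject-centered psychometric fit
#'
#' Centers each session's stimuli by that session's fitted PSE, concatenates
#' the centered trials across sessions, and fits a single psychometric
#' function. The pooled slope (and its reciprocal) summarize group-level
#' response consistency when individual sessions are too short for stable
#' slope estimates. The pooled PSE is left free; after centering it should be
#' close to zero.
#'
#' @param trials Data frame of trials from one or more sessions, with a
#'   session-identifier column alongside `stimulus_deg` and `response`.
#' @param pse Optional named vector or two-column data frame
#'   (session, pse) of per-session PSEs. If `NULL`, each session is fit with
#'   [fit_psychometric()] first.
#' @param session_col Name of the session-identifier column (default
#'   `"session"`).
#' @inheritParams fit_psychometric
#' @return A `psych_fit` on the pooled, centered trials, with an extra
#'   element `session_pse` recording the centers used.
#' @export
pool_centered_fit <- function(trials, pse = NULL, session_col = "session",
                              lapse = 0.02, slope_bounds = c(0.05, 10)) {
  if (!session_col %in% names(trials)) {
    rlang::abort(paste0("column `", session_col, "` not found in `trials`."))
  }
  ids <- unique(trials[[session_col]])
  if (length(ids) < 2) {
    rlang::warn("fewer than 2 sessions: pooled fit reduces to a single-session fit.")
  }
  if (is.null(pse)) {
    pse_tbl <- trials |>
      dplyr::group_by(.data[[session_col]]) |>
      dplyr::group_modify(function(d, key) {
        tibble::tibble(pse = fit_psychometric(d, lapse = lapse,
                                              slope_bounds = slope_bounds)$pse)
      }) |>
      dplyr::ungroup()
    centers <- stats::setNames(pse_tbl$pse, pse_tbl[[session_col]])
  } else if (is.data.frame(pse)) {
    centers <- stats::setNames(pse[[2]], pse[[1]])
  } else {
    centers <- pse
  }
  missing_ids <- setdiff(as.character(ids), names(centers))
  if (length(missing_ids) > 0) {
    rlang::abort(paste0("no PSE supplied for session(s): ", toString(missing_ids)))
  }
  centered <- trials |>
    dplyr::mutate(stimulus_deg = .data$stimulus_deg -
                    unname(centers[as.character(.data[[session_col]])]))
  fit <- fit_psychometric(centered, lapse = lapse, slope_bounds = slope_bounds)
  fit$session_pse <- centers
  fit
}

#' @export
print.psych_fit <- function(x, ...) {
  cat("Cumulative-normal psychometric fit (lapse fixed at ",
      format(x$lapse), ")\n", sep = "")
  cat(sprintf("  PSE (preference):  %7.3f deg (SE %s)\n", x$pse,
              ifelse(is.na(x$pse_se), "NA", sprintf("%.3f", x$pse_se))))
  cat(sprintf("  slope:             %7.3f /deg\n", x$slope))
  cat(sprintf("  Reliability Index: %7.3f deg\n", x$reliability_index))
  cat(sprintf("  log-likelihood:    %7.3f (n = %d trials)\n",
              x$log_lik, x$n_trials))
  if (x$boundary) cat("  note: fit sits on a parameter boundary or outside the tested range\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a psychometric fit
#'
#' @param x A `psych_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy psych_fit
#' @export
tidy.psych_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pse", "slope", "reliability_index"),
    estimate = c(x$pse, x$slope, x$reliability_index),
    std.error = c(x$pse_se, NA_real_, NA_real_)
  )
}

#' One-row summary of a psychometric fit
#'
#' @param x A `psych_fit`.
#' @param ... Unused.
#' @method glance psych_fit
#' @export
glance.psych_fit <- function(x, ...) {
  tibble::tibble(
    pse = x$pse, slope = x$slope, reliability_index = x$reliability_index,
    pse_se = x$pse_se, lapse = x$lapse, log_lik = x$log_lik,
    n_trials = x$n_trials, converged = x$converged, boundary = x$boundary
  )
}
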