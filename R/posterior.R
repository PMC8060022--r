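#' Initialize the adaptive posterior grid
#'
#' Discretized joint posterior over (PSE, log slope) used by the adaptive
#' stimulus-selection procedure. The PSE prior is uniform over the tested
#' angle range (padded so preferences near the range edge are representable);
#' the slope prior is uniform over log slope between the given bounds.
#'
#' @param angle_range Length-2 numeric, the tested angle range in degrees.
#' @param slope_range Slope prior support (1/degrees), default `c(0.3, 3)`.
#' @param lapse Lapse rate assumed by the adaptive algorithm (default 0.05,
#'   deliberately conservative: stimulus selection is far more damaged by
#'   underestimating the lapse rate than by overestimating it).
#' @param alpha_step PSE grid spacing, degrees (default 0.25).
#' @param n_slope Number of log-slope grid points (default 41).
#' @param pad Padding added beyond the tested range on each side, degrees
#'   (default 3).
#' @return A `posterior_grid` object.
#' @export
posterior_grid <- function(angle_range, slope_range = c(0.3, 3), lapse = 0.05,
                           alpha_step = 0.25, n_slope = 41, pad = 3) {
  if (length(angle_range) != 2 || diff(angle_range) <= 0) {
    rlang::abort("`angle_range` must be increasing with positive width.")
  }
  if (length(slope_range) != 2 || any(slope_range <= 0) ||
      diff(slope_range) <= 0) {
    rlang::abort("`slope_range` must be positive and increasing.")
  }
  if (lapse < 0 || lapse >= 0.5) rlang::abort("`lapse` must lie in [0, 0.5).")
  alpha <- seq(angle_range[1] - pad, angle_range[2] + pad, by = alpha_step)
  log_slope <- seq(log(slope_range[1]), log(slope_range[2]),
                   length.out = n_slope)
  mass <- matrix(1 / (length(alpha) * length(log_slope)),
                 nrow = length(alpha), ncol = length(log_slope))
  structure(
    list(alpha = alpha, log_slope = log_slope, mass = mass, lapse = lapse),
    class = "posterior_grid"
  )
}

#' @export
print.posterior_grid <- function(x, ...) {
  est <- posterior_estimates(x)
  cat(sprintf(
    "posterior_grid: %d alpha x %d log-slope cells (assumed lapse %.2f)\n",
    length(x$alpha), length(x$log_slope), x$lapse))
  cat(sprintf("  PSE mean %.3f deg, SD %.3f deg\n", est$pse_mean, est$pse_sd))
  invisible(x)
}

# Likelihood of a PREFER_PF response at stimulus x, over every grid cell.
# Returns an n_alpha x n_slope matrix.
grid_likelihood <- function(grid, x) {
  s <- exp(grid$log_slope)
  z <- outer(x - grid$alpha, s)
  grid$lapse / 2 + (1 - grid$lapse) * stats::pnorm(z)
}

#' Bayes update of the posterior grid
#'
#' Multiplies each cell by the likelihood of the observed response under that
#' cell's (PSE, slope) at the assumed lapse, then renormalizes.
#'
#' @param grid A `posterior_grid`.
#' @param stimulus Stimulus angle, degrees.
#' @param response `"PREFER_PF"`/`"PREFER_DF"`, or 1/0, or logical.
#' @return The updated `posterior_grid`.
#' @export
update_posterior <- function(grid, stimulus, response) {
  stopifnot(inherits(grid, "posterior_grid"))
  if (!is.finite(stimulus)) rlang::abort("`stimulus` must be finite.")
  r <- response_to_binary(response)
  lik <- grid_likelihood(grid, stimulus)
  if (r == 0) lik <- 1 - lik
  m <- grid$mass * lik
  total <- sum(m)
  if (total <= 0) {
    rlang::abort("posterior update produced zero total mass (inconsistent data with lapse 0).")
  }
  grid$mass <- m / total
  grid
}

#' Posterior marginal moments
#'
#' Exact weighted sums over the grid: mean and SD of the PSE marginal and the
#' mean of the log-slope marginal.
#'
#' @param grid A `posterior_grid`.
#' @return A one-row tibble: `pse_mean`, `pse_sd`, `log_slope_mean`.
#' @export
posterior_estimates <- function(grid) {
  stopifnot(inherits(grid, "posterior_grid"))
  p_alpha <- rowSums(grid$mass)
  p_ls <- colSums(grid$mass)
  m <- sum(grid$alpha * p_alpha)
  v <- sum((grid$alpha - m)^2 * p_alpha)
  tibble::tibble(
    pse_mean = m,
    pse_sd = sqrt(max(v, 0)),
    log_slope_mean = sum(grid$log_slope * p_ls)
  )
}

#' Tidy a posterior grid
#'
#' @param x A `posterior_grid`.
#' @param ... Unused.
#' @return Long tibble: `alpha`, `log_slope`, `mass`.
#' @method tidy posterior_grid
#' @export
tidy.posterior_grid <- function(x, ...) {
  tibble::tibble(
    alpha = rep(x$alpha, times = length(x$log_slope)),
    log_slope = rep(x$log_slope, each = length(x$alpha)),
    mass = as.vector(x$mass)
  )
}

# Shannon entropy (nats) pieces for candidate selection, computed from the
# unnormalized updated mass w with total s: H = log(s) - sum(w log w)/s.
entropy_terms <- function(W) {
  s <- colSums(W)
  wl <- W * log(W)
  wl[!is.finite(wl)] <- 0       # 0 log 0 = 0; cells zeroed by a 0 likelihood
  xlx <- colSums(wl)
  H <- ifelse(s > 0, log(s) - xlx / s, 0)
  list(s = s, H = H)
}

#' Select the next stimulus by expected-entropy minimization
#'
#' For each candidate stimulus, computes the predictive probability of each
#' response, the entropy of the posterior updated on that response, and their
#' expectation; returns the candidate minimizing expected posterior entropy
#' (the classic psi-method criterion). This concentrates trials near the
#' current preference estimate, where responses are most informative about
#' both PSE and slope.
#'
#' Ties (within 1e-9 nats) are broken by proximity to the posterior PSE mean,
#' then by a uniform draw from the session RNG stream.
#'
#' @param grid A `posterior_grid`.
#' @param candidates Candidate stimulus angles, degrees (non-empty).
#' @param likelihoods Optional precomputed matrix of PREFER_PF likelihoods
#'   (cells x candidates), as returned by [candidate_likelihoods()]; computed
#'   on the fly when `NULL`.
#' @return The selected stimulus (scalar, one of `candidates`).
#' @export
select_next_stimulus <- function(grid, candidates, likelihoods = NULL) {
  stopifnot(inherits(grid, "posterior_grid"))
  if (length(candidates) == 0) rlang::abort("`candidates` must be non-empty.")
  if (is.null(likelihoods)) {
    likelihoods <- candidate_likelihoods(grid, candidates)
  }
  m <- as.vector(grid$mass)
  W1 <- likelihoods * m
  W0 <- (1 - likelihoods) * m
  e1 <- entropy_terms(W1)
  e0 <- entropy_terms(W0)
  expected_h <- e1$s * e1$H + e0$s * e0$H
  tol <- 1e-9
  tied <- which(expected_h <= min(expected_h) + tol)
  if (length(tied) > 1) {
    pse_mean <- sum(grid$alpha * rowSums(grid$mass))
    d <- abs(candidates[tied] - pse_mean)
    nearest <- tied[abs(d - min(d)) < 1e-12]
    pick <- if (length(nearest) > 1) sample(nearest, 1) else nearest
  } else {
    pick <- tied
  }
  candidates[[pick]]
}

#' Precompute candidate likelihood matrix
#'
#' PREFER_PF likelihood of every grid cell for every candidate stimulus,
#' flattened to a (cells x candidates) matrix. Computing this once per
#' session makes repeated expected-entropy evaluations cheap.
#'
#' @inheritParams select_next_stimulus
#' @return Numeric matrix, `length(alpha) * length(log_slope)` rows.
#' @export
candidate_likelihoods <- function(grid, candidates) {
  vapply(candidates, function(x) as.vector(grid_likelihood(grid, x)),
         numeric(length(grid$alpha) * length(grid$log_slope)))
}
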