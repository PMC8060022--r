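# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most literal route available (term-by-term loops,
# exhaustive grids, direct posterior updates) and share no code with the
# implementation paths they check.

psi_direct <- function(x, a, s, l) l / 2 + (1 - l) * pnorm(s * (x - a))

# term-by-term negative log-likelihood
oracle_nll <- function(x, r, a, s, l) {
  tot <- 0
  for (i in seq_along(x)) {
    p <- psi_direct(x[i], a, s, l)
    tot <- tot - if (r[i] == 1) log(p) else log(1 - p)
  }
  tot
}

# exhaustive grid search over (pse, log slope) at the stated resolution
oracle_grid_fit <- function(x, r, lapse, pse_lim, step_a = 0.01,
                            log_s_lim = log(c(0.05, 10)), step_ls = 0.01) {
  a_grid <- seq(pse_lim[1], pse_lim[2], by = step_a)
  ls_grid <- seq(log_s_lim[1], log_s_lim[2], by = step_ls)
  best <- c(NA, NA); best_nll <- Inf
  for (ls in ls_grid) {
    s <- exp(ls)
    nll <- numeric(length(a_grid))
    for (i in seq_along(x)) {
      p <- psi_direct(x[i], a_grid, s, lapse)
      nll <- nll - if (r[i] == 1) log(p) else log(1 - p)
    }
    j <- which.min(nll)
    if (nll[j] < best_nll) { best_nll <- nll[j]; best <- c(a_grid[j], ls) }
  }
  list(pse = best[1], log_slope = best[2], nll = best_nll)
}

# posterior mass after a sequence of (stimulus, response) pairs, computed as
# a renormalized product of likelihoods over the whole grid in one go
oracle_posterior_mass <- function(grid, stimuli, responses) {
  m <- matrix(1, nrow = length(grid$alpha), ncol = length(grid$log_slope))
  s <- exp(grid$log_slope)
  for (k in seq_along(stimuli)) {
    lik <- outer(grid$alpha, s, function(a, ss) {
      psi_direct(stimuli[k], a, ss, grid$lapse)
    })
    if (responses[k] == 0) lik <- 1 - lik
    m <- m * lik
  }
  m / sum(m)
}

# brute-force expected posterior entropy for one candidate: update for both
# outcomes via the package's own update (checked independently elsewhere is
# not enough -- so do the update literally here too)
oracle_expected_entropy <- function(grid, x) {
  s <- exp(grid$log_slope)
  lik <- outer(grid$alpha, s, function(a, ss) psi_direct(x, a, ss, grid$lapse))
  ent <- function(m) {
    p <- as.vector(m); p <- p[p > 0]
    -sum(p * log(p))
  }
  out <- 0
  for (resp in c(1, 0)) {
    lk <- if (resp == 1) lik else 1 - lik
    w <- grid$mass * lk
    pr <- sum(w)
    if (pr > 0) out <- out + pr * ent(w / pr)
  }
  out
}

# rising-threshold-crossing scan with refractory rule, index by index
oracle_heel_scan <- function(f, t, thr, refractory) {
  ev <- integer(0); last_t <- -Inf
  for (i in 2:length(f)) {
    if (f[i - 1] < thr && f[i] >= thr && t[i] - last_t >= refractory) {
      ev <- c(ev, i); last_t <- t[i]
    }
  }
  ev
}

# step-function responder (noiseless, infinitely reliable subject)
step_responder <- function(true_pse) {
  function(x) if (x > true_pse) "PREFER_PF" else "PREFER_DF"
}
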