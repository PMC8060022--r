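test_that("psychometric function: PSE symmetry, one-SD point, asymptotes, monotonicity", {
  # exact 50% at the PSE for any lapse
  for (l in c(0, 0.02, 0.05, 0.3)) {
    expect_identical(psych_prob(2.5, pse = 2.5, slope = 0.7, lapse = l), 0.5)
  }
  # lapse-free closed form: psi(pse + k/slope) = Phi(k)
  for (k in c(-2, -1, 0.5, 1, 2)) {
    expect_equal(psych_prob(1 + k / 0.8, pse = 1, slope = 0.8),
                 pnorm(k), tolerance = 1e-12)
  }
  expect_equal(psych_prob(1 + 1 / 0.667, 1, 0.667), 0.8413, tolerance = 1e-4)
  # asymptotes with lapse
  expect_equal(psych_prob(1e6, 0, 1, lapse = 0.02), 0.99, tolerance = 1e-9)
  expect_equal(psych_prob(-1e6, 0, 1, lapse = 0.02), 0.01, tolerance = 1e-9)
  # monotone and bounded for random valid parameters
  withr::with_seed(7, {
    for (i in 1:20) {
      a <- runif(1, -5, 5); s <- exp(runif(1, log(0.1), log(5)))
      l <- runif(1, 0, 0.4)
      x <- seq(-15, 15, length.out = 200)
      p <- psych_prob(x, a, s, l)
      expect_true(all(diff(p) >= 0))
      expect_true(all(p >= l / 2 - 1e-12 & p <= 1 - l / 2 + 1e-12))
    }
  })
  expect_error(psych_prob(NaN, 0, 1), "finite")
  expect_error(psych_prob(0, 0, -1), "slope")
  expect_error(psych_prob(0, 0, 1, lapse = 0.5), "lapse")
})

test_that("negative log-likelihood matches term-by-term summation and handles empty logs", {
  one <- trial_log("LW", 2, "PREFER_PF")
  expect_equal(psych_nll(one, pse = 2, slope = 1, lapse = 0.1), -log(0.5),
               tolerance = 1e-12)
  empty <- trial_log("LW", numeric(0), character(0))
  expect_warning(v <- psych_nll(empty, 0, 1), "empty")
  expect_identical(v, 0)
  withr::with_seed(11, {
    x <- runif(10, -4, 4)
    r <- rbinom(10, 1, 0.5)
    tl <- trial_log("LW", x, r)
    expect_equal(psych_nll(tl, 0.5, 0.9, 0.02),
                 oracle_nll(x, r, 0.5, 0.9, 0.02), tolerance = 1e-12)
  })
})

test_that("ML fit recovers simulated parameters", {
  withr::with_seed(21, {
    x <- runif(2000, -4.5, 4.5)
    tl <- simulate_trials(x, pse = 1.0, slope = 0.667, lapse = 0.02)
  })
  fit <- fit_psychometric(tl, lapse = 0.02)
  expect_true(fit$converged)
  expect_false(fit$boundary)
  expect_lt(abs(fit$pse - 1.0), 0.15)
  expect_lt(abs(fit$slope - 0.667) / 0.667, 0.10)
  # deterministic: refitting gives the identical result
  fit2 <- fit_psychometric(tl, lapse = 0.02)
  expect_identical(fit$pse, fit2$pse)
  expect_identical(fit$slope, fit2$slope)
})

test_that("ML fit agrees with an exhaustive grid-search oracle on small instances", {
  for (seed in c(31, 32, 33)) {
    withr::with_seed(seed, {
      n <- sample(20:50, 1)
      x <- sample(seq(-4.5, 4.5, by = 1.5), n, replace = TRUE)
      tl <- simulate_trials(x, pse = runif(1, -2, 2),
                            slope = exp(runif(1, log(0.4), log(2))),
                            lapse = 0.02)
    })
    fit <- fit_psychometric(tl, lapse = 0.02)
    orc <- oracle_grid_fit(tl$stimulus_deg,
                           as.integer(tl$response == "PREFER_PF"),
                           lapse = 0.02, pse_lim = c(-6, 6))
    nll_fit <- psych_nll(tl, fit$pse, fit$slope, 0.02)
    # the continuous optimum can be no worse than any exhaustive grid point
    expect_lte(nll_fit, orc$nll + 1e-9)
    # and lands in the oracle's grid cell, except when two basins tie within
    # numerical noise (flat binomial ridges), where either is the optimum
    same_cell <- abs(fit$pse - orc$pse) < 0.011 &&
      abs(log(fit$slope) - orc$log_slope) < 0.011
    expect_true(same_cell || abs(nll_fit - orc$nll) < 1e-4)
  }
})

test_that("degenerate response patterns are flagged, never fatal", {
  # perfect separation: DF at and below 0, PF at and above 1.5
  x <- c(-3, -1.5, 0, 1.5, 3, 4.5, -3, 0, 1.5, 3)
  r <- as.integer(x >= 1.5)
  sep <- trial_log("LW", x, r)
  fit <- expect_no_error(fit_psychometric(sep))
  expect_true(fit$boundary)
  expect_true(fit$at_slope_bound)
  expect_gt(fit$pse, 0)
  expect_lt(fit$pse, 1.5)
  # one-sided responses: PSE pushed outside the tested range, flagged
  all_df <- trial_log("LW", seq(-4.5, 4.5, by = 1.5), rep(0, 7))
  fit2 <- expect_no_error(fit_psychometric(all_df))
  expect_true(fit2$boundary)
  expect_false(fit2$pse_in_range)
  expect_gt(fit2$pse, 4.5)
})

test_that("Reliability Index is the reciprocal slope and the 84% point", {
  tl <- withr::with_seed(41, simulate_trials(runif(300, -4, 4), 0, 1, 0.02))
  fit <- fit_psychometric(tl)
  fit$slope <- 1.0; fit$reliability_index <- 1.0  # exact-value checks
  expect_identical(reliability_index(fit), 1.0)
  fit$slope <- 0.667
  expect_equal(reliability_index(fit), 1.4993, tolerance = 1e-4)
  # lapse-free response rate one RI from preference is 84% to the nearest %
  ri <- 1 / 0.667
  rate <- psych_prob(0 + ri, pse = 0, slope = 0.667, lapse = 0)
  expect_identical(round(100 * rate), 84)
})

test_that("parameter recovery improves with trial count (bias -> 0, RMSE decreasing)", {
  ns <- c(35, 140, 560)
  res <- purrr::map_dbl(seq_along(ns), function(j) {
    err <- purrr::map_dbl(1:80, function(rep) {
      tl <- withr::with_seed(1000 + 80 * j + rep, {
        simulate_trials(runif(ns[j], -4.5, 4.5), pse = 0.8, slope = 0.8,
                        lapse = 0.02)
      })
      fit_psychometric(tl)$pse - 0.8
    })
    sqrt(mean(err^2))
  })
  expect_true(all(diff(res) < 0))
  expect_lt(res[3], 0.35)  # bias+noise at 560 trials is small
})

test_that("pooled centered fit recovers a common slope and reduces correctly", {
  mk <- function(seed, pse) {
    withr::with_seed(seed,
      simulate_trials(runif(500, pse - 4.5, pse + 4.5), pse, 0.8, 0.02))
  }
  s1 <- mk(51, -1.2); s2 <- mk(52, 2.7)
  trials <- dplyr::bind_rows(
    dplyr::mutate(s1, session = "a"),
    dplyr::mutate(s2, session = "b")
  )
  pooled <- pool_centered_fit(trials)
  expect_lt(abs(pooled$slope - 0.8) / 0.8, 0.10)
  expect_lt(abs(pooled$pse), 0.5)  # centered data: pooled PSE near 0

  # supplying PSE = 0 makes centering the identity
  ident <- pool_centered_fit(trials, pse = c(a = 0, b = 0))
  direct <- fit_psychometric(trials)
  expect_equal(ident$pse, direct$pse, tolerance = 1e-9)
  expect_equal(ident$slope, direct$slope, tolerance = 1e-9)

  # single session (with warning) equals a plain fit centered by its own PSE
  one <- dplyr::mutate(s1, session = "a")
  expect_warning(p1 <- pool_centered_fit(one), "fewer than 2")
  f1 <- fit_psychometric(s1)
  expect_equal(p1$slope, f1$slope, tolerance = 1e-6)
})

test_that("tidy and glance return well-formed summaries", {
  tl <- withr::with_seed(61, simulate_trials(runif(60, -4, 4), 0.5, 1, 0.02))
  fit <- fit_psychometric(tl)
  td <- generics::tidy(fit)
  expect_identical(td$term, c("pse", "slope", "reliability_index"))
  gl <- generics::glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$reliability_index, 1 / gl$slope, tolerance = 1e-12)
})
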