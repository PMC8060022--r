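test_that("FSR calibration is exact on linear data and matches least squares", {
  g <- 9.80665
  # exact linear conductance data, gain 50, offset 0
  mass <- c(1, 2, 4, 8)
  res <- 50 / (mass * g)
  cal <- calibrate_fsr(tibble::tibble(resistance_ohm = res, mass_kg = mass),
                       area_m2 = 1e-4)
  expect_equal(cal$gain, 50, tolerance = 1e-9)
  expect_equal(cal$offset, 0, tolerance = 1e-9)

  # two points define the line exactly
  cal2 <- calibrate_fsr(tibble::tibble(resistance_ohm = c(10, 2),
                                       mass_kg = c(1, 3)), 1e-4)
  f <- function(r) cal2$gain / r + cal2$offset
  expect_equal(f(10), 1 * g, tolerance = 1e-9)
  expect_equal(f(2), 3 * g, tolerance = 1e-9)

  # noisy data: matches the normal-equations solution
  withr::with_seed(161, {
    cond <- runif(20, 0.01, 0.5)
    force <- 40 * cond + 0.7 + rnorm(20, 0, 0.1)
  })
  rd <- tibble::tibble(resistance_ohm = 1 / cond, mass_kg = force / g)
  cal3 <- calibrate_fsr(rd, 1e-4)
  X <- cbind(1, cond)
  beta <- solve(t(X) %*% X, t(X) %*% force)
  expect_equal(cal3$offset, beta[1], tolerance = 1e-9)
  expect_equal(cal3$gain, beta[2], tolerance = 1e-9)

  expect_error(calibrate_fsr(tibble::tibble(resistance_ohm = c(1, 2),
                                            mass_kg = c(2, 2)), 1e-4),
               "distinct")
})

test_that("raw-to-pressure conversion does the stated arithmetic", {
  cal <- structure(list(gain = 50, offset = 0, area_m2 = 1e-4, sigma = 0),
                   class = "fsr_calibration")
  # resistance chosen so force = 10 N -> 10/1e-4/1000/80 = 1.25 kPa/kg
  st <- tibble::tibble(time = c(0, 0.002), fsr_a = c(5, Inf))
  out <- pressure_from_raw(st, cal, body_mass_kg = 80, channels = "fsr_a")
  expect_equal(out$fsr_a[1], 1.25, tolerance = 1e-12)
  expect_identical(out$fsr_a[2], 0)  # open circuit -> zero pressure

  withr::with_seed(171, r <- runif(50, 1, 100))
  st2 <- tibble::tibble(time = seq(0, by = 0.002, length.out = 50), fsr_a = r)
  out2 <- pressure_from_raw(st2, cal, 70, channels = "fsr_a")
  expect_equal(out2$fsr_a, pmax((50 / r + 0) / 1e-4 / 1000 / 70, 0),
               tolerance = 1e-12)
})

test_that("zero-phase low-pass: DC gain 1, half amplitude at cutoff, no delay", {
  fs <- 1000
  # constant signal passes unchanged
  expect_lt(max(abs(lowpass_zero_phase(rep(3.7, 500), fs) - 3.7)), 1e-9)
  # 50 Hz sinusoid attenuated to |H|^2 = 1/2 at the Butterworth cutoff
  t <- seq(0, 2, by = 1 / fs)
  y <- lowpass_zero_phase(sin(2 * pi * 50 * t), fs)
  mid <- y[(length(y) / 4):(3 * length(y) / 4)]
  expect_equal(max(abs(mid)), 0.5, tolerance = 0.01)
  # symmetric pulse keeps its peak index (zero phase)
  tri <- c(rep(0, 200), seq(0, 1, length.out = 51),
           seq(1, 0, length.out = 51)[-1], rep(0, 200))
  yf <- lowpass_zero_phase(tri, fs, cutoff = 20)
  expect_identical(which.max(yf), which.max(tri))
  # linearity
  withr::with_seed(181, { a <- rnorm(400); b <- rnorm(400) })
  lhs <- lowpass_zero_phase(2 * a - 3 * b, fs)
  rhs <- 2 * lowpass_zero_phase(a, fs) - 3 * lowpass_zero_phase(b, fs)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  expect_error(lowpass_zero_phase(a, sample_rate = 100), "too low")
})

test_that("heel-strike detection finds rising crossings with a refractory rule", {
  fs <- 500
  bw <- 800
  # clean square-wave loading: 8 cycles
  one <- c(rep(0, 250), rep(0.9 * bw, 250))
  f <- rep(one, 8)
  t <- (seq_along(f) - 1) / fs
  ev <- detect_heel_strikes(f, bw, sample_rate = fs)
  expect_identical(nrow(ev), 8L)
  expect_identical(ev$index, as.integer(250 + 500 * (0:7) + 1))

  expect_warning(e0 <- detect_heel_strikes(rep(0, 100), bw, sample_rate = fs),
                 "no threshold")
  expect_identical(nrow(e0), 0L)

  # noisy loading: after the pipeline's 50 Hz low-pass, detection matches
  # the brute-force scan oracle and stays within 10 ms of the true edges
  # (refractory set just below the stride period, the usual practice, so
  # the falling edge of stance cannot re-trigger)
  one <- c(rep(0, 300), 0.9 * bw * sin(pi * seq(0, 1, length.out = 300)))
  f <- rep(one, 50)
  withr::with_seed(191, f <- f + rnorm(length(f), 0, 20))
  f <- lowpass_zero_phase(f, fs)
  t <- (seq_along(f) - 1) / fs
  ev <- detect_heel_strikes(f, bw, refractory_s = 0.9, sample_rate = fs)
  orc <- oracle_heel_scan(f, t, 0.1 * bw, 0.9)
  expect_identical(ev$index, orc)
  # first crossing of the noise-free template within each cycle
  u_true <- asin(0.1 / 0.9) / pi
  true_edge <- (0:49) * 600 / fs + (300 + u_true * 300) / fs
  matched <- vapply(true_edge, function(te) min(abs(ev$time - te)),
                    numeric(1))
  expect_lt(max(matched), 0.010)
  expect_identical(nrow(ev), 50L)
})

test_that("stride time-normalization matches an interpolation oracle", {
  fs <- 200
  t <- seq(0, 4, by = 1 / fs)
  withr::with_seed(201, z <- cumsum(rnorm(length(t))))
  st <- tibble::tibble(time = t, const = 2.5, clock = t, z = z)
  ev <- seq(1, length(t), by = fs)  # strides of exactly 1 s
  cyc <- time_normalize_strides(st, ev, n_points = 101)
  cc <- dplyr::filter(cyc, channel == "const")
  expect_lt(max(abs(cc$value - 2.5)), 1e-12)
  # a clock channel resamples to a straight line spanning the stride, i.e.
  # elapsed time within the stride runs linearly from 0 to its duration
  el <- dplyr::filter(cyc, channel == "clock", stride == 2)
  expect_equal(el$value - el$value[1], seq(0, 1, length.out = 101),
               tolerance = 1e-9)
  expect_equal(el$duration_s[1], 1, tolerance = 1e-12)
  # arbitrary channel equals direct approx()
  z2 <- dplyr::filter(cyc, channel == "z", stride == 3)
  i0 <- ev[3]; i1 <- ev[4]
  orc <- approx(t[i0:i1], z[i0:i1],
                xout = seq(t[i0], t[i1], length.out = 101))$y
  expect_lt(max(abs(z2$value - orc)), 1e-9)
  # linearity of the resampling operator
  st2 <- dplyr::mutate(st, comb = 2 * z + 3 * clock)
  cyc2 <- time_normalize_strides(st2, ev, n_points = 101)
  comb <- dplyr::filter(cyc2, channel == "comb")$value
  parts <- 2 * dplyr::filter(cyc2, channel == "z")$value +
    3 * dplyr::filter(cyc2, channel == "clock")$value
  expect_lt(max(abs(comb - parts)), 1e-9)
})

test_that("pressure-time integral: constants, triangles, fine-grid agreement", {
  expect_equal(pressure_time_integral(rep(4.2, 101)), 4.2, tolerance = 1e-12)
  expect_equal(pressure_time_integral(seq(0, 8, length.out = 101)), 4,
               tolerance = 1e-12)
  f <- function(u) 2 + sin(2 * pi * u) + 0.5 * cos(6 * pi * u + 1)
  coarse <- pressure_time_integral(f(seq(0, 1, length.out = 101)))
  fine <- pracma::trapz(seq(0, 1, length.out = 1e5),
                        f(seq(0, 1, length.out = 1e5)))
  expect_lt(abs(coarse - fine) / abs(fine), 1e-3)
})

test_that("complementary filter: fixed point, tau limits, sandwich property", {
  fs <- 500; dt <- 1 / fs; g <- 9.80665
  # static pose at 10 degrees, zero gyro: converges and stays
  n <- 6 * fs  # 6 s
  th <- complementary_filter_pitch(rep(g * sin(10 * pi / 180), n),
                                   rep(g * cos(10 * pi / 180), n),
                                   rep(0, n), dt)
  expect_lt(max(abs(th[(5 * fs):n] - 10)), 0.01)
  expect_equal(th[1], 10, tolerance = 1e-9)  # initialized at the accel angle

  # tau -> 0: accelerometer-only (to numerical precision), with a warning
  withr::with_seed(211, {
    ax <- g * sin(runif(200, -0.3, 0.3)); az <- sqrt(g^2 - ax^2)
  })
  expect_warning(
    th0 <- complementary_filter_pitch(ax, az, rnorm(200), dt, tau = 1e-9),
    "accelerometer-only")
  expect_lt(max(abs(th0 - atan2(ax, az) * 180 / pi)), 1e-4)

  # gyro that under-reports a monotone rotation: estimate lies between the
  # pure-integration and pure-accelerometer answers
  t <- seq(0, 5, by = dt)
  theta <- 30 * t / 5 * pi / 180
  gy <- c(0, diff(theta)) / dt * 0.8
  th <- complementary_filter_pitch(g * sin(theta), g * cos(theta), gy, dt)
  integ <- (theta[1] + cumsum(gy) * dt - gy[1] * dt) * 180 / pi
  accel <- theta * 180 / pi
  i <- seq(2 * fs, length(t))   # past the initial transient
  expect_true(all(th[i] >= integ[i] - 1e-9 & th[i] <= accel[i] + 1e-9))
})

test_that("condition summaries average strides and report spreads", {
  base <- tibble::tibble(gait_pct = seq(0, 100, length.out = 101))
  mk <- function(stride, angle, vals) {
    dplyr::mutate(base, stride = stride, task = "RA", ankle_angle = angle,
                  channel = "fsr_ant_prox", value = vals)
  }
  v <- sin(pi * base$gait_pct / 100)
  one <- mk(1, 0, 3 * v)
  cs1 <- summarize_conditions(one)
  expect_equal(cs1$curves$mean_value, 3 * v, tolerance = 1e-12)
  two <- dplyr::bind_rows(mk(1, 0, 3 * v), mk(2, 0, 3 * v))
  cs2 <- summarize_conditions(two)
  expect_equal(cs2$summary$peak, 3, tolerance = 1e-12)
  # spread across conditions at the queried instant
  three <- dplyr::bind_rows(mk(1, 0, 3 * v), mk(2, 4.5, 2 * v), mk(3, 9, v))
  cs3 <- summarize_conditions(three, query_pct = 50)
  expect_equal(cs3$spread$spread_at_query, 2, tolerance = 1e-12)
})
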