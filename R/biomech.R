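GRAVITY <- 9.80665  # m/s^2

stream_rate <- function(stream) {
  dt <- diff(stream$time)
  if (length(dt) == 0) rlang::abort("stream has fewer than 2 samples.")
  if (max(dt) - min(dt) > 0.5 * stats::median(dt)) {
    rlang::abort("stream is not uniformly sampled.")
  }
  1 / stats::median(dt)
}

#' Calibrate a force-sensing resistor channel
#'
#' Benchtop calibration against hung weights: FSR force is modeled as linear
#' in conductance, `force = gain * (1/resistance) + offset`, fit by ordinary
#' least squares. Pressure is later derived as force over the sensing area.
#'
#' @param readings Data frame with columns `resistance_ohm` and `mass_kg`
#'   (applied mass; at least 2 distinct loads).
#' @param area_m2 Sensing area of the pad, square meters.
#' @return An `fsr_calibration`: list with `gain` (N·ohm), `offset` (N),
#'   `area_m2`, `sigma` (residual SE, N).
#' @export
calibrate_fsr <- function(readings, area_m2) {
  stopifnot(is.finite(area_m2), area_m2 > 0)
  if (!all(c("resistance_ohm", "mass_kg") %in% names(readings))) {
    rlang::abort("`readings` needs columns resistance_ohm and mass_kg.")
  }
  if (length(unique(readings$mass_kg)) < 2) {
    rlang::abort("calibration needs at least 2 distinct loads.")
  }
  d <- tibble::tibble(force = readings$mass_kg * GRAVITY,
                      conductance = 1 / readings$resistance_ohm)
  fit <- stats::lm(force ~ conductance, data = d)
  df <- nrow(d) - 2
  structure(
    list(gain = unname(stats::coef(fit)[2]),
         offset = unname(stats::coef(fit)[1]),
         area_m2 = area_m2,
         sigma = if (df > 0) sqrt(sum(stats::resid(fit)^2) / df) else NA_real_),
    class = "fsr_calibration"
  )
}

#' Convert raw FSR channels to weight-normalized pressure
#'
#' Applies a calibration to each raw resistance channel and normalizes by
#' body mass: `pressure = (gain/R + offset) / area / 1000 / body_mass`
#' (kPa/kg). Negative values (possible with a nonzero offset at very high
#' resistance) are clamped at zero and the clamp count is attached as the
#' `n_clamped` attribute.
#'
#' @param stream Sensor-stream tibble with a `time` column.
#' @param cal An [calibrate_fsr()] result, or a named list of them keyed by
#'   channel name.
#' @param body_mass_kg Subject body mass, kg.
#' @param channels Channel columns to convert (default: those starting
#'   `"fsr_"`).
#' @return The stream with the named channels replaced by pressure in kPa/kg.
#' @export
pressure_from_raw <- function(stream, cal, body_mass_kg,
                              channels = grep("^fsr_", names(stream),
                                              value = TRUE)) {
  stopifnot(body_mass_kg > 0, length(channels) > 0)
  n_clamped <- 0L
  for (ch in channels) {
    cc <- if (inherits(cal, "fsr_calibration")) cal else cal[[ch]]
    if (is.null(cc)) rlang::abort(paste0("no calibration for channel ", ch))
    r <- stream[[ch]]
    if (any(r <= 0, na.rm = TRUE)) {
      rlang::warn(paste0("non-positive resistance samples in ", ch,
                         " treated as open circuit."))
      r[r <= 0] <- Inf
    }
    force <- cc$gain / r + cc$offset
    p <- force / cc$area_m2 / 1000 / body_mass_kg
    n_clamped <- n_clamped + sum(p < 0)
    stream[[ch]] <- pmax(p, 0)
  }
  attr(stream, "n_clamped") <- n_clamped
  stream
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order (by default) Butterworth low-pass applied forward and
#' backward, giving zero phase shift and a squared magnitude response
#' (amplitude at the cutoff is reduced to 1/2 rather than 1/sqrt(2)).
#' Edges are handled by reflective padding proportional to the filter order,
#' so a constant signal passes through unchanged.
#'
#' @param x Numeric vector, or a sensor-stream tibble (then `channels` are
#'   filtered in place and `sample_rate` is read from `time`).
#' @param sample_rate Sampling rate, Hz; must exceed twice the cutoff.
#' @param cutoff Cutoff frequency, Hz (default 50).
#' @param order Filter order (default 2).
#' @param channels For a stream input, columns to filter (default: all
#'   numeric columns except `time`).
#' @return Filtered vector or stream.
#' @export
lowpass_zero_phase <- function(x, sample_rate = NULL, cutoff = 50, order = 2,
                               channels = NULL) {
  if (is.data.frame(x)) {
    sr <- if (is.null(sample_rate)) stream_rate(x) else sample_rate
    if (is.null(channels)) {
      channels <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], "time")
    }
    for (ch in channels) {
      x[[ch]] <- lowpass_zero_phase(x[[ch]], sr, cutoff, order)
    }
    return(x)
  }
  if (is.null(sample_rate)) rlang::abort("`sample_rate` is required for vectors.")
  if (sample_rate <= 2 * cutoff) {
    rlang::abort(sprintf(
      "sample rate %.3g Hz too low for a %.3g Hz cutoff: need > %.3g Hz.",
      sample_rate, cutoff, 2 * cutoff))
  }
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  n <- length(x)
  pad <- min(3 * (order + 1), n - 1)
  xp <- c(rev(x[seq_len(pad) + 1]), x, rev(x[n - seq_len(pad)]))
  # steady-state initial conditions (past samples pinned at the edge value)
  # so the unit DC gain is exact and edge transients die inside the padding
  run <- function(v) {
    as.numeric(signal::filter(bf$b, bf$a, v,
                              init.x = rep(v[1], order),
                              init.y = rep(v[1], order)))
  }
  bwd <- rev(run(rev(run(xp))))
  bwd[pad + seq_len(n)]
}

#' Detect heel strikes from the pylon axial force
#'
#' Heel strikes are rising crossings of `threshold_fraction` of body weight,
#' separated by at least the refractory interval. Returns sorted, unique
#' sample indices (and times when available).
#'
#' @param stream Sensor-stream tibble with `time` and a force column, or a
#'   numeric force vector (then pass `sample_rate`).
#' @param body_weight_n Body weight in newtons.
#' @param threshold_fraction Fraction of body weight defining contact
#'   (default 0.1).
#' @param refractory_s Minimum separation between events, seconds
#'   (default 0.4).
#' @param force_col Force column name (default `"force_N"`).
#' @param sample_rate Required when `stream` is a bare vector.
#' @return Tibble with `index` (sample) and `time` (s). Zero rows, with a
#'   warning, when no crossing exists.
#' @export
detect_heel_strikes <- function(stream, body_weight_n,
                                threshold_fraction = 0.1, refractory_s = 0.4,
                                force_col = "force_N", sample_rate = NULL) {
  if (is.data.frame(stream)) {
    f <- stream[[force_col]]
    t <- stream$time
  } else {
    f <- stream
    if (is.null(sample_rate)) rlang::abort("`sample_rate` needed for vector input.")
    t <- (seq_along(f) - 1) / sample_rate
  }
  thr <- threshold_fraction * body_weight_n
  n <- length(f)
  rising <- which(f[-1] >= thr & f[-n] < thr) + 1L
  if (length(rising) == 0) {
    rlang::warn("no threshold crossings found.")
    return(tibble::tibble(index = integer(0), time = numeric(0)))
  }
  keep <- rising[1]
  for (i in rising[-1]) {
    if (t[i] - t[keep[length(keep)]] >= refractory_s) keep <- c(keep, i)
  }
  tibble::tibble(index = keep, time = t[keep])
}

#' Resample strides to a common gait-cycle base
#'
#' Cuts the stream at consecutive heel strikes and linearly resamples each
#' stride to `n_points` samples spanning 0–100% of the gait cycle
#' (endpoints inclusive). Zero-length intervals are dropped and counted in
#' the `n_dropped` attribute.
#'
#' @param stream Sensor-stream tibble with `time`.
#' @param events Heel-strike events: tibble from [detect_heel_strikes()], or
#'   a vector of sample indices.
#' @param n_points Samples per normalized stride (default 101).
#' @param channels Columns to resample (default: all numeric except `time`).
#' @return Long tibble: `stride`, `gait_pct` (0–100), `channel`, `value`,
#'   `duration_s`.
#' @export
time_normalize_strides <- function(stream, events, n_points = 101,
                                   channels = NULL) {
  idx <- if (is.data.frame(events)) events$index else as.integer(events)
  if (length(idx) < 2) rlang::abort("need at least 2 heel-strike events.")
  if (is.null(channels)) {
    channels <- setdiff(names(stream)[vapply(stream, is.numeric, logical(1))],
                        "time")
  }
  t <- stream$time
  gait_pct <- seq(0, 100, length.out = n_points)
  n_dropped <- 0L
  out <- vector("list", length(idx) - 1)
  for (k in seq_len(length(idx) - 1)) {
    i0 <- idx[k]; i1 <- idx[k + 1]
    dur <- t[i1] - t[i0]
    if (dur <= 0) { n_dropped <- n_dropped + 1L; next }
    tt <- seq(t[i0], t[i1], length.out = n_points)
    vals <- purrr::map(channels, function(ch) {
      stats::approx(t[i0:i1], stream[[ch]][i0:i1], xout = tt)$y
    })
    out[[k]] <- tibble::tibble(
      stride = k,
      gait_pct = rep(gait_pct, times = length(channels)),
      channel = rep(channels, each = n_points),
      value = unlist(vals),
      duration_s = dur
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Pressure-time integral over one gait cycle
#'
#' Trapezoidal integral of a normalized-gait curve with time expressed as a
#' fraction of the gait cycle, i.e. over the domain [0, 1]. A constant curve
#' integrates to that constant.
#'
#' @param values Curve sampled uniformly over 0–100% gait (>= 2 points).
#' @return Scalar integral, in the units of the curve per gait cycle.
#' @export
pressure_time_integral <- function(values) {
  if (length(values) < 2) rlang::abort("need at least 2 points.")
  pracma::trapz(seq(0, 1, length.out = length(values)), values)
}

#' Complementary-filter shank-pitch estimate
#'
#' Fuses the sagittal-plane gravity direction from the accelerometers with
#' integrated gyroscope rate via a first-order complementary filter:
#' \deqn{\theta_k = a(\theta_{k-1} + \omega_k \Delta t) + (1-a)\,\theta^{acc}_k,
#'   \quad a = \tau / (\tau + \Delta t)}
#' with \eqn{\theta^{acc} = \mathrm{atan2}(a_{fwd}, a_{vert})} and
#' \eqn{\theta_1 = \theta^{acc}_1}. The accelerometer anchors the estimate at
#' low frequency (no gyro drift); the gyro carries it at high frequency
#' (immune to translational-acceleration contamination).
#'
#' @param accel_forward,accel_vertical Sagittal accelerometer components,
#'   m/s^2 (any common scale: only their ratio matters).
#' @param gyro_rate Pitch-axis angular rate, rad/s.
#' @param dt Sample interval, seconds.
#' @param tau Filter time constant, seconds (default 1).
#' @return Pitch angle series in degrees (forward rotation positive).
#' @export
complementary_filter_pitch <- function(accel_forward, accel_vertical,
                                       gyro_rate, dt, tau = 1) {
  stopifnot(tau > 0, dt > 0)
  if (dt >= tau) {
    rlang::warn("dt >= tau: filter degenerates toward accelerometer-only.")
  }
  theta_acc <- atan2(accel_forward, accel_vertical)
  a <- tau / (tau + dt)
  u <- a * gyro_rate * dt + (1 - a) * theta_acc
  n <- length(theta_acc)
  theta <- numeric(n)
  theta[1] <- theta_acc[1]
  if (n > 1) {
    theta[-1] <- as.numeric(
      stats::filter(u[-1], a, method = "recursive", init = theta[1]))
  }
  theta * 180 / pi
}

#' Summarize gait curves by condition
#'
#' Groups normalized strides by task, ankle angle and channel; computes the
#' pointwise mean curve per condition, then per-condition scalars: peak of
#' the mean curve, its pressure-time integral, and its value at a queried
#' percent of the gait cycle. The across-condition spread (max minus min of
#' the condition means at the queried instant) quantifies how strongly a
#' channel responds to alignment changes.
#'
#' @param cycles Long tibble of normalized strides with columns `task`,
#'   `ankle_angle`, `channel`, `gait_pct`, `value` (e.g.
#'   [time_normalize_strides()] output with condition labels added).
#' @param query_pct Percent of the gait cycle at which to read curves
#'   (default 30, midstance).
#' @return A `condition_summary`: list with `summary` (one row per
#'   task x ankle angle x channel), `curves` (mean curves) and `spread`
#'   (one row per task x channel). `tidy()` returns `summary`.
#' @export
summarize_conditions <- function(cycles, query_pct = 30) {
  needed <- c("task", "ankle_angle", "channel", "gait_pct", "value")
  if (!all(needed %in% names(cycles))) {
    rlang::abort(paste0("`cycles` needs columns: ", toString(needed)))
  }
  curves <- cycles |>
    dplyr::group_by(.data$task, .data$ankle_angle, .data$channel,
                    .data$gait_pct) |>
    dplyr::summarise(mean_value = mean(.data$value),
                     n_strides = dplyr::n(), .groups = "drop")
  summary <- curves |>
    dplyr::group_by(.data$task, .data$ankle_angle, .data$channel) |>
    dplyr::summarise(
      peak = max(.data$mean_value),
      pti = pressure_time_integral(
        .data$mean_value[order(.data$gait_pct)]),
      value_at_query = stats::approx(.data$gait_pct, .data$mean_value,
                                     xout = query_pct)$y,
      n_strides = .data$n_strides[1],
      .groups = "drop"
    )
  spread <- summary |>
    dplyr::group_by(.data$task, .data$channel) |>
    dplyr::summarise(
      spread_at_query = max(.data$value_at_query) - min(.data$value_at_query),
      n_conditions = dplyr::n(), .groups = "drop"
    )
  structure(
    list(summary = summary, curves = curves, spread = spread,
         query_pct = query_pct),
    class = "condition_summary"
  )
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("condition_summary over", nrow(x$summary), "conditions",
      sprintf("(queried at %g%% gait)\n", x$query_pct))
  print(x$summary)
  invisible(x)
}

#' @rdname summarize_conditions
#' @param x A `condition_summary`.
#' @param ... Unused.
#' @method tidy condition_summary
#' @export
tidy.condition_summary <- function(x, ...) x$summary
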