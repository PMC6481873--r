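#' Gaussian spike-density function
#'
#' Instantaneous firing-rate estimate: the sum of normalized Gaussian
#' kernels (default sigma = 8 ms) centered at each spike, in spikes/s.
#'
#' @param spike_times spike times (ms); may be empty.
#' @param sigma kernel width (ms), default 8.
#' @param times evaluation grid (ms); default covers the spikes with a
#'   4-sigma margin at 1 ms resolution.
#' @return An object of class `spike_density`: list with `times` (ms),
#'   `rate` (spikes/s) and `n_spikes`.
#' @export
spike_density <- function(spike_times, sigma = 8, times = NULL) {
  stopifnot(sigma > 0)
  if (is.null(times)) {
    if (length(spike_times)) {
      times <- seq(floor(min(spike_times) - 4 * sigma),
                   ceiling(max(spike_times) + 4 * sigma), by = 1)
    } else times <- 0
  }
  rate <- rep(0, length(times))
  for (tk in spike_times)
    rate <- rate + stats::dnorm(times, mean = tk, sd = sigma)
  structure(list(times = times, rate = rate * 1000,
                 n_spikes = length(spike_times), sigma = sigma),
            class = "spike_density")
}

#' Decode a spike raster into an eye-movement trajectory
#'
#' Dynamic linear ensemble coding: every spike of every neuron adds that
#' neuron's fixed mini-vector (efferent map times `zeta`) to the eye
#' displacement. The cumulative displacement is linearly interpolated (a
#' first-order spline) onto a uniform time grid and smoothed with a
#' Savitzky-Golay filter; velocities come from the filter's first
#' derivative.
#'
#' @param raster an `sc_raster` from [run_simulation()].
#' @param zeta efferent scaling factor; default the grid's map constant.
#' @param resample_dt uniform sampling interval (ms), default 1.
#' @param sg_window Savitzky-Golay window length (samples, odd), default 11.
#' @param sg_order Savitzky-Golay polynomial order, default 3.
#' @param smooth apply the Savitzky-Golay filter? (default TRUE; when FALSE
#'   the raw interpolated staircase is returned and velocity is a first
#'   difference)
#' @return An object of class `sc_trace`: data frame with columns `time`
#'   (ms), `x`, `y` (deg), `vx`, `vy`, `v` (deg/s), plus attributes `zeta`
#'   and `raw_end` (the unsmoothed final displacement vector).
#' @export
decode_trace <- function(raster, zeta = NULL, resample_dt = 1,
                         sg_window = 11, sg_order = 3, smooth = TRUE) {
  grid <- raster$grid
  if (is.null(zeta)) zeta <- grid$consts$zeta
  tg <- seq(0, raster$t_end, by = resample_dt)
  if (!length(raster$time)) {
    out <- data.frame(time = tg, x = 0, y = 0, vx = 0, vy = 0, v = 0)
  } else {
    m <- sc_efferent(grid$u[raster$neuron], grid$v[raster$neuron],
                     grid$consts, zeta = zeta)
    ord <- order(raster$time)
    ts <- raster$time[ord]
    cx <- cumsum(m[ord, 1]); cy <- cumsum(m[ord, 2])
    # collapse coincident spike times to their final cumulative value
    last <- !duplicated(ts, fromLast = TRUE)
    ts <- c(0, ts[last]); cx <- c(0, cx[last]); cy <- c(0, cy[last])
    if (ts[length(ts)] < raster$t_end) {
      ts <- c(ts, raster$t_end)
      cx <- c(cx, cx[length(cx)]); cy <- c(cy, cy[length(cy)])
    }
    x <- stats::approx(ts, cx, xout = tg, method = "linear", ties = "ordered")$y
    y <- stats::approx(ts, cy, xout = tg, method = "linear", ties = "ordered")$y
    if (smooth && length(tg) >= sg_window) {
      xs <- signal::sgolayfilt(x, p = sg_order, n = sg_window)
      ys <- signal::sgolayfilt(y, p = sg_order, n = sg_window)
      # first-derivative output of the same filter, per second
      vx <- signal::sgolayfilt(x, p = sg_order, n = sg_window, m = 1) /
        resample_dt * 1000
      vy <- signal::sgolayfilt(y, p = sg_order, n = sg_window, m = 1) /
        resample_dt * 1000
    } else {
      xs <- x; ys <- y
      vx <- c(0, diff(x)) / resample_dt * 1000
      vy <- c(0, diff(y)) / resample_dt * 1000
    }
    out <- data.frame(time = tg, x = xs, y = ys, vx = vx, vy = vy,
                      v = sqrt(vx^2 + vy^2))
  }
  attr(out, "zeta") <- zeta
  attr(out, "raw_end") <- if (length(raster$time))
    c(x = cx[length(cx)], y = cy[length(cy)]) else c(x = 0, y = 0)
  class(out) <- c("sc_trace", "data.frame")
  out
}

#' Calibrate the efferent scaling factor
#'
#' Exploits the linearity of the ensemble decoder in `zeta`: decode the
#' calibration raster with `zeta = 1` and rescale so the raw final
#' displacement amplitude equals the commanded amplitude (by convention a
#' horizontal 21-deg saccade).
#'
#' @param raster an `sc_raster` from stimulation at the calibration site.
#' @param target_R commanded amplitude (deg), default 21.
#' @return The calibrated `zeta`.
#' @export
calibrate_zeta <- function(raster, target_R = 21) {
  tr <- decode_trace(raster, zeta = 1, smooth = FALSE)
  amp <- sqrt(sum(attr(tr, "raw_end")^2))
  if (amp <= 0) stop("zero decoded amplitude: cannot calibrate zeta")
  target_R / amp
}

#' Scalar kinematics of a decoded saccade
#'
#' Onset and offset from a velocity criterion: the contiguous interval
#' around the velocity peak where `v >= v_threshold`. A trace qualifies as
#' "no saccade" when the velocity never reaches the threshold and the total
#' displacement stays below `min_displacement`.
#'
#' @param trace an `sc_trace` from [decode_trace()].
#' @param v_threshold onset/offset velocity criterion (deg/s), default 30.
#' @param min_displacement displacement criterion (deg) for the
#'   no-movement flag, default 0.5.
#' @return A one-row data frame with columns `amplitude` (deg), `direction`
#'   (deg), `duration` (ms), `v_peak` (deg/s), `onset`, `offset` (ms) and
#'   `no_saccade` (logical). For a no-saccade trace the kinematic fields
#'   are `NA`.
#' @export
saccade_metrics <- function(trace, v_threshold = 30, min_displacement = 0.5) {
  above <- trace$v >= v_threshold
  total_disp <- sqrt((trace$x[nrow(trace)] - trace$x[1])^2 +
                       (trace$y[nrow(trace)] - trace$y[1])^2)
  if (!any(above)) {
    return(data.frame(amplitude = NA_real_, direction = NA_real_,
                      duration = NA_real_, v_peak = NA_real_,
                      onset = NA_real_, offset = NA_real_,
                      no_saccade = total_disp < min_displacement))
  }
  ipk <- which.max(trace$v)
  i0 <- ipk; while (i0 > 1 && above[i0 - 1]) i0 <- i0 - 1
  i1 <- ipk; while (i1 < length(above) && above[i1 + 1]) i1 <- i1 + 1
  dx <- trace$x[i1] - trace$x[i0]
  dy <- trace$y[i1] - trace$y[i0]
  data.frame(amplitude = sqrt(dx^2 + dy^2),
             direction = atan2(dy, dx) * 180 / pi,
             duration = trace$time[i1] - trace$time[i0],
             v_peak = trace$v[ipk],
             onset = trace$time[i0], offset = trace$time[i1],
             no_saccade = FALSE)
}

#' Burst metrics from a spike-density function
#'
#' @param density a [spike_density()] object.
#' @return A one-row data frame: `F_peak` (spikes/s), `T_burst` (ms, width
#'   of the interval where the density stays at or above 10% of its peak),
#'   `N` (spike count) and `S_burst` (third standardized moment of the
#'   density treated as a distribution over time).
#' @export
burst_metrics <- function(density) {
  stopifnot(inherits(density, "spike_density"))
  if (density$n_spikes == 0)
    return(data.frame(F_peak = 0, T_burst = 0, N = 0, S_burst = NA_real_))
  r <- density$rate; tt <- density$times
  F_peak <- max(r)
  above <- which(r >= 0.1 * F_peak)
  T_burst <- tt[max(above)] - tt[min(above)]
  w <- r / sum(r)
  mu <- sum(w * tt)
  s2 <- sum(w * (tt - mu)^2)
  S_burst <- sum(w * (tt - mu)^3) / s2^1.5
  data.frame(F_peak = F_peak, T_burst = T_burst, N = density$n_spikes,
             S_burst = S_burst)
}

#' Burst synchronization across the recruited population
#'
#' Pearson correlation, at zero lag, between each recruited neuron's
#' spike-density function and that of the central cell, evaluated on a
#' common time grid spanning the union of all bursts.
#'
#' @param raster an `sc_raster`.
#' @param central central neuron index; default [central_neuron()].
#' @param sigma density kernel width (ms), default 8.
#' @param dt evaluation resolution (ms), default 1.
#' @param min_spikes recruitment criterion (default 1 spike).
#' @return Data frame with columns `neuron`, `n_spikes`, `C_pop` (`NA`
#'   where the correlation is undefined).
#' @export
population_sync <- function(raster, central = NULL, sigma = 8, dt = 1,
                            min_spikes = 1) {
  counts <- spike_counts(raster)
  recruited <- which(counts >= min_spikes)
  if (!length(recruited)) stop("no recruited neurons in raster")
  if (is.null(central)) central <- central_neuron(raster)
  tg <- seq(floor(min(raster$time) - 4 * sigma),
            ceiling(max(raster$time) + 4 * sigma), by = dt)
  sp <- split(raster$time, raster$neuron)
  dens <- function(n) spike_density(sp[[as.character(n)]], sigma, tg)$rate
  ref <- dens(central)
  C_pop <- vapply(recruited, function(n) {
    d <- dens(n)
    if (stats::sd(d) == 0 || stats::sd(ref) == 0) NA_real_
    else stats::cor(d, ref)
  }, numeric(1))
  data.frame(neuron = recruited, n_spikes = counts[recruited], C_pop = C_pop)
}

#' Main-sequence fits over a set of saccades
#'
#' Fits the three characteristic relations: the saturating exponential
#' `v_peak = a (1 - exp(-c R))` (nonlinear least squares), the straight
#' line `D = d0 + d1 R` (ordinary least squares) and the through-origin
#' line `v_peak * D = k * R` with the product converted to degrees.
#'
#' @param metrics data frame with columns `amplitude` (deg), `duration`
#'   (ms) and `v_peak` (deg/s); rows with `NA` are dropped.
#' @return An object of class `main_sequence_fit`: list with `v_asym`
#'   (deg/s), `rate_const` (1/deg), `d_intercept` (ms), `d_slope` (ms/deg),
#'   `k` (dimensionless) and the three fitted model objects.
#' @export
main_sequence_fit <- function(metrics) {
  m <- metrics[stats::complete.cases(metrics[, c("amplitude", "duration",
                                                 "v_peak")]), ]
  if (nrow(m) < 4) stop("need at least 4 saccades spanning the range")
  fit_v <- minpack.lm::nlsLM(
    v_peak ~ a * (1 - exp(-c * amplitude)), data = m,
    start = list(a = max(m$v_peak) * 1.2, c = 0.05),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  fit_d <- stats::lm(duration ~ amplitude, data = m)
  m$vd <- m$v_peak * m$duration / 1000  # deg/s * ms -> deg
  fit_k <- stats::lm(vd ~ 0 + amplitude, data = m)
  structure(list(
    v_asym = unname(stats::coef(fit_v)["a"]),
    rate_const = unname(stats::coef(fit_v)["c"]),
    d_intercept = unname(stats::coef(fit_d)[1]),
    d_slope = unname(stats::coef(fit_d)[2]),
    k = unname(stats::coef(fit_k)[1]),
    fit_v = fit_v, fit_d = fit_d, fit_k = fit_k, data = m),
    class = "main_sequence_fit")
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  cat(sprintf("<main_sequence_fit> over %d saccades\n", nrow(x$data)))
  cat(sprintf("  v_peak = %.1f * (1 - exp(-%.4f R)) deg/s\n",
              x$v_asym, x$rate_const))
  cat(sprintf("  D      = %.1f + %.2f R ms\n", x$d_intercept, x$d_slope))
  cat(sprintf("  v_peak * D = %.3f R deg\n", x$k))
  invisible(x)
}

#' Static vector-averaging decoder
#'
#' The competing center-of-gravity scheme: the activity-weighted mean of
#' the cell vectors, `sum(F_n M_n) / sum(F_n)`, insensitive to the overall
#' firing-rate scale. Specifies only the saccade endpoint, not its time
#' course.
#'
#' @param raster an `sc_raster`.
#' @param rate weighting: `"mean"` (spike count over the burst window,
#'   default) or `"peak"` (peak spike density, 8 ms kernel).
#' @return Named vector `c(x, y)` in deg.
#' @export
decode_vector_average <- function(raster, rate = c("mean", "peak")) {
  rate <- match.arg(rate)
  if (!length(raster$time)) stop("no activity: vector average undefined")
  grid <- raster$grid
  counts <- spike_counts(raster)
  act <- which(counts > 0)
  Fn <- if (rate == "mean") {
    counts[act] / (diff(range(raster$time)) + 1e-9)
  } else {
    sp <- split(raster$time, raster$neuron)
    vapply(act, function(n)
      max(spike_density(sp[[as.character(n)]])$rate), numeric(1))
  }
  M <- sc_efferent(grid$u[act], grid$v[act], grid$consts, zeta = 1)
  c(x = sum(Fn * M[, 1]) / sum(Fn), y = sum(Fn * M[, 2]) / sum(Fn))
}
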