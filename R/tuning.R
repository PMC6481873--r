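#' Location-dependent adaptation time constant
#'
#' The adaptation time constant decreases linearly along the rostral-caudal
#' axis: `tau_q(u) = 100 - 14 u` ms for `u` in `[0, 5]` mm, i.e. from 100 ms
#' at the rostral pole down to 30 ms at the caudal edge.
#'
#' @param u rostral-caudal map coordinate(s), mm, in `[0, 5]`.
#' @param slope,intercept gradient parameters (ms/mm, ms).
#' @return Adaptation time constant(s), ms.
#' @export
tau_q_of_u <- function(u, slope = -14, intercept = 100) {
  if (any(u < 0 - 1e-12 | u > 5 + 1e-12))
    stop("u outside the motor-map range [0, 5] mm")
  intercept + slope * u
}

# Eq-15 polynomial coefficients, ascending powers of tau_q, including the
# global 1e-3 factor.
.s_poly <- c(-8.396, 1.383, -3.607e-2, 4.855e-4, -3.280e-6, 8.808e-9) * 1e-3

#' Synaptic weight-scaling parameter from the adaptation time constant
#'
#' Fifth-order polynomial fit `s(tau_q)` (nS) obtained from the brute-force
#' identification of self-excitation weights that yield a fixed 20-spike
#' burst; valid over `tau_q` in `[30, 100]` ms where it stays within
#' `[0.0112, 0.0147]` nS.
#'
#' @param tau_q adaptation time constant(s), ms.
#' @return Synaptic scaling parameter(s) `s`, nS.
#' @export
s_of_tau <- function(tau_q) {
  if (any(tau_q < 30 | tau_q > 100))
    warning("tau_q outside the fitted range [30, 100] ms; extrapolating")
  drop(outer(tau_q, 0:5, `^`) %*% .s_poly)
}

#' Tuned AdEx population for a motor-map grid
#'
#' Applies the rostral-caudal gradients: per-neuron `tau_q` from
#' [tau_q_of_u()] and synaptic scaling `s` from [s_of_tau()], sharing the
#' remaining biophysical constants.
#'
#' @param grid an [build_grid()] object.
#' @param params shared [adex_params()].
#' @return An object of class `sc_population`: list with `params` and
#'   per-neuron vectors `tau_q` (ms) and `s` (nS).
#' @export
build_population <- function(grid, params = adex_params()) {
  tq <- tau_q_of_u(grid$u)
  structure(list(params = params, tau_q = tq, s = s_of_tau(tq)),
            class = "sc_population")
}

#' Effective population gain of the tuning self-synapse
#'
#' During tuning, a neuron's single excitatory self-synapse stands in for
#' the synchronized drive it would receive from the whole recruited
#' population, so its weight is `s * wbar_exc * gain`. The default gain is
#' identified from the tuning anchor (a 20-spike burst at `tau_q` = 100 ms
#' with the fitted `s` polynomial) and is constant to ~1% over
#' `tau_q` in `[47.5, 100]` ms.
#'
#' @return Dimensionless gain (default 21.7).
#' @export
population_gain <- function() 21.7

#' Spike count of a self-exciting neuron under direct stimulation
#'
#' One AdEx neuron with an excitatory self-synapse of weight
#' `s * wbar_exc * gain` (nS), driven by the electrode current at zero
#' distance (`I0` for `D_S` ms). This is the configuration whose spike
#' count the tuning procedure pins at 20 across the map.
#'
#' @param tau_q adaptation time constant (ms).
#' @param s synaptic scaling parameter (nS); `s = 0` gives pure direct
#'   stimulation (the 4-6 spike regime).
#' @param stim a [stimulus_spec()]; only `I0`, `D_S`, `t_on` are used.
#' @param conn a [connectivity_spec()] supplying `wbar_exc`.
#' @param params shared [adex_params()] (its `tau_q` is overridden).
#' @param gain population gain, see [population_gain()].
#' @param tail post-stimulus horizon (ms).
#' @param dt step size (ms).
#' @return Number of spikes.
#' @export
self_excitation_spike_count <- function(tau_q, s, stim = stimulus_spec(R = 1),
                                        conn = connectivity_spec(),
                                        params = adex_params(),
                                        gain = population_gain(),
                                        tail = 300, dt = 0.01) {
  p <- params; p$tau_q <- tau_q
  t_end <- stim$t_on + stim$D_S + tail
  I_fun <- function(t) ifelse(t >= stim$t_on & t < stim$t_on + stim$D_S,
                              stim$I0, 0)
  tr <- adex_simulate(p, I_fun, t_end = t_end, dt = dt,
                      w_self = s * conn$wbar_exc * gain,
                      tau_exc = conn$tau_exc, E_e = conn$E_e,
                      keep_trace = FALSE)
  length(tr$spikes)
}

#' Brute-force identification of the synaptic scaling parameter
#'
#' Recovers, for a given `tau_q`, the `s` whose self-excitation spike count
#' is closest to `target` (ties toward smaller `s`): coarse grid search over
#' `s_range` followed by bisection refinement on the bracketing interval.
#' Serves as the independent recovery oracle for the printed `s(tau_q)`
#' polynomial.
#'
#' @param tau_q adaptation time constant (ms).
#' @param stim a [stimulus_spec()] (defaults: 150 pA, 100 ms).
#' @param target desired spike count (default 20).
#' @param s_range search range for `s` (nS).
#' @param s_step coarse grid resolution (nS).
#' @param ... passed on to [self_excitation_spike_count()].
#' @return The recovered `s` (nS); attribute `"count"` holds the achieved
#'   spike count.
#' @export
brute_force_tune <- function(tau_q, stim = stimulus_spec(R = 1), target = 20,
                             s_range = c(0.005, 0.03), s_step = 5e-4, ...) {
  stopifnot(target >= 1)
  grid_s <- seq(s_range[1], s_range[2], by = s_step)
  counts <- vapply(grid_s, function(s)
    self_excitation_spike_count(tau_q, s, stim, ...), numeric(1))
  if (all(counts < target) || all(counts > target)) {
    stop(sprintf(
      "target %d unreachable in s range [%g, %g]: counts span [%d, %d]",
      target, s_range[1], s_range[2], min(counts), max(counts)))
  }
  err <- abs(counts - target)
  i <- which.min(err)  # which.min takes the first (smallest s) on ties
  lo <- grid_s[max(i - 1L, 1L)]
  hi <- grid_s[min(i + 1L, length(grid_s))]
  best_s <- grid_s[i]; best_e <- err[i]; best_n <- counts[i]
  for (k in 1:25) {
    mid <- (lo + hi) / 2
    n <- self_excitation_spike_count(tau_q, mid, stim, ...)
    e <- abs(n - target)
    if (e < best_e || (e == best_e && mid < best_s)) {
      best_s <- mid; best_e <- e; best_n <- n
    }
    if (n >= target) hi <- mid else lo <- mid
  }
  structure(best_s, count = best_n)
}

#' Reference peak firing rate along the main sequence
#'
#' Rate-model target for the peak firing rate of the central cell as a
#' function of saccade amplitude: `F_peak(R) = F0 / (1 + beta * R)`.
#'
#' @param R saccade amplitude(s), deg.
#' @param F0 rostral peak rate (spikes/s), default 800.
#' @param beta decay parameter (default 0.07, used as printed).
#' @return Peak firing rate(s), spikes/s.
#' @export
f_peak_reference <- function(R, F0 = 800, beta = 0.07) F0 / (1 + beta * R)

#' Weighted-RMSE fitness of a tuned network
#'
#' Validation score over the eight tuning amplitudes
#' `R = c(2, 3, 5, 8, 13, 21, 33, 55)` deg:
#' `0.1 * RMSE(F_peak vs reference) + 10 * RMSE(N vs target) +
#'  1e3 * RMSE(C_pop vs 1)`. Zero means a perfect match.
#'
#' @param metrics data frame with one row per tuning site and columns `R`,
#'   `F_peak` (spikes/s), `N` (central-cell spike count) and `C_pop` (mean
#'   burst cross-correlation with the central cell).
#' @param F0,beta reference-rate parameters, see [f_peak_reference()].
#' @param target_spikes desired central-cell spike count (default 20).
#' @param weights the three RMSE weights.
#' @param R_required amplitudes that must be present.
#' @return Fitness score (lower is better).
#' @export
tuning_fitness <- function(metrics, F0 = 800, beta = 0.07,
                           target_spikes = 20,
                           weights = c(0.1, 10, 1e3),
                           R_required = c(2, 3, 5, 8, 13, 21, 33, 55)) {
  missing_R <- setdiff(R_required, metrics$R)
  if (length(missing_R))
    stop("missing tuning amplitudes: ", paste(missing_R, collapse = ", "))
  m <- metrics[metrics$R %in% R_required, ]
  rmse <- function(x, ref) sqrt(mean((x - ref)^2))
  weights[1] * rmse(m$F_peak, f_peak_reference(m$R, F0, beta)) +
    weights[2] * rmse(m$N, target_spikes) +
    weights[3] * rmse(m$C_pop, 1)
}
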