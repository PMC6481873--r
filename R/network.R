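#' Lateral connectivity and synapse parameters
#'
#' Mexican-hat (difference-of-Gaussians) coupling over map distance: strong
#' short-range excitation, weak long-range inhibition, implementing a soft
#' winner-take-all. The weight from presynaptic neuron `i` onto
#' postsynaptic neuron `n` at Euclidean map distance `d` (mm) is
#' `w_exc = (s_n / pop_scale) * wbar_exc * exp(-d^2 / (2 sigma_exc^2))` and
#' analogously for inhibition, with `s_n` the postsynaptic scaling
#' parameter. `pop_scale` normalizes the summed lateral drive by the number
#' of neurons standing in for one recruited population: it equals
#' `pop_area / (du * dv)` so that network behaviour is invariant to the
#' grid density.
#'
#' @param wbar_exc,wbar_inh excitatory/inhibitory scaling factors
#'   (dimensionless multipliers of `s_n` in nS; defaults 45 and 14).
#' @param sigma_exc,sigma_inh Gaussian ranges (mm; defaults 0.4 and 1.2).
#' @param E_e,E_i excitatory/inhibitory reversal potentials (mV).
#' @param tau_exc,tau_inh conductance decay time constants (ms).
#' @param pop_area reference population area (mm^2) defining `pop_scale`;
#'   calibrated once so that the central cell of the recruited population
#'   fires the same ~20-spike burst as the tuned self-exciting neuron.
#' @return An object of class `connectivity_spec`.
#' @export
connectivity_spec <- function(wbar_exc = 45, wbar_inh = 14,
                              sigma_exc = 0.4, sigma_inh = 1.2,
                              E_e = 0, E_i = -80,
                              tau_exc = 5, tau_inh = 10,
                              pop_area = 0.0075) {
  stopifnot(wbar_exc > wbar_inh, sigma_inh > sigma_exc,
            tau_exc > 0, tau_inh > 0, pop_area > 0)
  structure(list(wbar_exc = wbar_exc, wbar_inh = wbar_inh,
                 sigma_exc = sigma_exc, sigma_inh = sigma_inh,
                 E_e = E_e, E_i = E_i,
                 tau_exc = tau_exc, tau_inh = tau_inh,
                 pop_area = pop_area),
            class = "connectivity_spec")
}

#' Population normalization divisor for a grid
#'
#' @param conn a [connectivity_spec()].
#' @param grid an [build_grid()] object.
#' @return `pop_area / (du * dv)`, the number of grid neurons in the
#'   reference population area.
#' @export
pop_scale <- function(conn, grid) conn$pop_area / (grid$du * grid$dv)

#' Lateral connection weights between two neurons
#'
#' @param i presynaptic neuron index.
#' @param n postsynaptic neuron index.
#' @param conn a [connectivity_spec()].
#' @param grid an [build_grid()] object.
#' @param s per-neuron synaptic scaling vector (nS), e.g. from
#'   [build_population()].
#' @return Named vector `c(w_exc, w_inh)` in nS.
#' @export
lateral_weight <- function(i, n, conn, grid, s) {
  d2 <- (grid$u[i] - grid$u[n])^2 + (grid$v[i] - grid$v[n])^2
  sc <- s[n] / pop_scale(conn, grid)
  c(w_exc = sc * conn$wbar_exc * exp(-d2 / (2 * conn$sigma_exc^2)),
    w_inh = sc * conn$wbar_inh * exp(-d2 / (2 * conn$sigma_inh^2)))
}

#' One synaptic update step (reference implementation)
#'
#' Exact exponential decay of the conductances followed by the pairwise
#' O(N^2) accumulation of this step's presynaptic spikes. This is the
#' ground-truth loop against which the compiled separable-kernel update is
#' verified; use [run_simulation()] for actual simulations.
#'
#' @param state list with numeric vectors `g_exc`, `g_inh` (nS).
#' @param presyn_spikes logical or 0/1 vector, one flag per neuron.
#' @param conn a [connectivity_spec()].
#' @param grid an [build_grid()] object.
#' @param s per-neuron synaptic scaling (nS).
#' @param dt step size (ms).
#' @return Updated `state`.
#' @export
synapse_step <- function(state, presyn_spikes, conn, grid, s, dt = 0.01) {
  stopifnot(dt > 0)
  g_exc <- state$g_exc * exp(-dt / conn$tau_exc)
  g_inh <- state$g_inh * exp(-dt / conn$tau_inh)
  sc <- s / pop_scale(conn, grid)
  for (i in which(as.logical(presyn_spikes))) {
    d2 <- (grid$u - grid$u[i])^2 + (grid$v - grid$v[i])^2
    g_exc <- g_exc + sc * conn$wbar_exc * exp(-d2 / (2 * conn$sigma_exc^2))
    g_inh <- g_inh + sc * conn$wbar_inh * exp(-d2 / (2 * conn$sigma_inh^2))
  }
  list(g_exc = g_exc, g_inh = g_inh)
}

#' Total input current onto a neuron
#'
#' `I_inp = g_exc (E_e - V) + g_inh (E_i - V) + I_E`.
#'
#' @param n neuron index.
#' @param V_n membrane potential of neuron `n` (mV).
#' @param state synapse state with `g_exc`, `g_inh` vectors (nS).
#' @param field per-neuron stimulation currents (pA), e.g. [stim_field()].
#' @param conn a [connectivity_spec()] for the reversal potentials.
#' @return Input current (pA).
#' @export
input_current <- function(n, V_n, state, field, conn = connectivity_spec()) {
  state$g_exc[n] * (conn$E_e - V_n) + state$g_inh[n] * (conn$E_i - V_n) +
    field[n]
}

#' Simulate the full motor-map network
#'
#' Time-stepped co-evolution (forward Euler, default dt = 0.01 ms) of all
#' AdEx neurons and their conductance-based lateral synapses under a
#' microstimulation pulse. With `lateral = FALSE` the synaptic sums are
#' skipped and neurons see only the electrode field (the direct-activation
#' footprint). Fully deterministic: identical inputs give identical
#' rasters.
#'
#' @param grid an [build_grid()] object.
#' @param pop an [build_population()] object.
#' @param conn a [connectivity_spec()].
#' @param stim a [stimulus_spec()].
#' @param lateral enable lateral interactions? (default TRUE)
#' @param dt step size (ms).
#' @param t_end simulation horizon (ms); default `t_on + D_S + tail`.
#' @param tail post-stimulus horizon (ms), default 300.
#' @param trace_idx optional neuron indices whose state is recorded.
#' @param trace_dt recording resolution for traces (ms), default 1.
#' @return An object of class `sc_raster`: list with integer vector
#'   `neuron`, numeric vector `time` (ms, sorted by time), the grid and
#'   simulation metadata, and optionally a `traces` data frame with columns
#'   `time`, `neuron`, `V`, `q`, `g_exc`, `g_inh`.
#' @export
run_simulation <- function(grid, pop, conn, stim, lateral = TRUE,
                           dt = 0.01, t_end = NULL, tail = 300,
                           trace_idx = integer(0), trace_dt = 1) {
  stopifnot(inherits(grid, "sc_grid"), inherits(pop, "sc_population"),
            inherits(conn, "connectivity_spec"),
            inherits(stim, "stimulus_spec"), dt > 0)
  if (is.null(t_end)) t_end <- stim$t_on + stim$D_S + tail
  p <- pop$params
  res <- sc_sim_cpp(grid$n_u, grid$n_v, pop$tau_q, pop$s,
                    grid$du, grid$dv,
                    p$C, p$g_L, p$E_L, p$eta, p$V_T, p$V_peak, p$V_rst,
                    p$a, p$b,
                    conn$E_e, conn$E_i, conn$tau_exc, conn$tau_inh,
                    conn$wbar_exc, conn$wbar_inh,
                    conn$sigma_exc, conn$sigma_inh,
                    pop_scale(conn, grid),
                    stim_field(stim, grid), stim$t_on, stim$D_S,
                    lateral, dt, t_end,
                    as.integer(trace_idx), trace_dt)
  out <- list(neuron = res$neuron, time = res$time,
              n_neurons = grid$n_u * grid$n_v,
              grid = grid, stim = stim, conn = conn,
              lateral = lateral, dt = dt, t_end = t_end)
  if (length(trace_idx)) {
    nt <- length(res$trace_time)
    k <- length(trace_idx)
    out$traces <- data.frame(
      time = rep(res$trace_time, each = k),
      neuron = rep(as.integer(trace_idx), times = nt),
      V = res$trace_V, q = res$trace_q,
      g_exc = res$trace_gexc, g_inh = res$trace_ginh)
  }
  structure(out, class = "sc_raster")
}

#' @export
print.sc_raster <- function(x, ...) {
  cat(sprintf("<sc_raster> %d spikes from %d of %d neurons (%g ms, lateral %s)\n",
              length(x$time), length(unique(x$neuron)), x$n_neurons,
              x$t_end, if (x$lateral) "on" else "off"))
  invisible(x)
}

#' Per-neuron spike counts of a raster
#'
#' @param raster an `sc_raster`.
#' @return Integer vector of length `n_neurons`.
#' @export
spike_counts <- function(raster) {
  tabulate(raster$neuron, nbins = raster$n_neurons)
}

#' Central (most active) neuron of a raster
#'
#' @param raster an `sc_raster`.
#' @return Neuron index with the maximal spike count (first on ties).
#' @export
central_neuron <- function(raster) {
  if (!length(raster$neuron)) stop("empty raster has no central neuron")
  which.max(spike_counts(raster))
}
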