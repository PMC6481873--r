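#' AdEx neuron parameters
#'
#' Biophysical constants of the adaptive exponential integrate-and-fire
#' neuron. The membrane potential obeys
#' `C dV/dt = -g_L (V - E_L) + g_L eta exp((V - V_T)/eta) - q + I_inp`
#' and the adaptation current `tau_q dq/dt = a (V - E_L) - q`; on reaching
#' `V_peak` a spike is recorded, `V` is reset to `V_rst` and `q` is
#' incremented by `b`. Note `V_rst > V_T`: the reset lands inside the spike
#' initiation zone, which is what makes these neurons burst.
#'
#' @param C membrane capacitance (pF).
#' @param g_L leak conductance (nS).
#' @param E_L leak reversal potential (mV).
#' @param eta spike slope factor (mV).
#' @param V_T exponential threshold (mV).
#' @param V_peak spiking ceiling (mV); numerical stand-in for the divergence.
#' @param V_rst reset potential (mV).
#' @param a sub-threshold adaptation conductance (nS).
#' @param b spike-triggered adaptation increment (pA).
#' @param tau_q adaptation time constant (ms); location-dependent in the
#'   network (see [tau_q_of_u()]), scalar here.
#' @return An object of class `adex_params`.
#' @export
adex_params <- function(C = 600, g_L = 20, E_L = -53, eta = 2, V_T = -50,
                        V_peak = -30, V_rst = -45, a = 0, b = 120,
                        tau_q = 100) {
  stopifnot(C > 0, g_L > 0, eta > 0, tau_q > 0, V_rst < V_peak)
  structure(list(C = C, g_L = g_L, E_L = E_L, eta = eta, V_T = V_T,
                 V_peak = V_peak, V_rst = V_rst, a = a, b = b,
                 tau_q = tau_q),
            class = "adex_params")
}

#' Single forward-Euler step of the AdEx equations
#'
#' Reference implementation of one integration step, used as the ground
#' truth for the compiled simulators.
#'
#' @param state list with elements `V` (mV) and `q` (pA).
#' @param params an [adex_params()] object.
#' @param I_inp input current (pA) during the step.
#' @param dt step size (ms).
#' @return list `V`, `q`, `spiked` (logical).
#' @export
adex_step <- function(state, params, I_inp, dt = 0.01) {
  stopifnot(dt > 0)
  p <- params
  dV <- (-p$g_L * (state$V - p$E_L) +
           p$g_L * p$eta * exp((state$V - p$V_T) / p$eta) -
           state$q + I_inp) * dt / p$C
  dq <- (p$a * (state$V - p$E_L) - state$q) * dt / p$tau_q
  V <- state$V + dV
  q <- state$q + dq
  if (!is.finite(V) || !is.finite(q)) stop("non-finite neuron state")
  spiked <- V >= p$V_peak
  if (spiked) {
    V <- p$V_rst
    q <- q + p$b
  }
  list(V = V, q = q, spiked = spiked)
}

#' Simulate a single AdEx neuron
#'
#' Forward-Euler integration at resolution `dt` of one neuron driven by an
#' arbitrary input-current time series, optionally with an excitatory
#' self-synapse (conductance jump `w_self` one step after each own spike,
#' exponential decay with `tau_exc`) as used by the network-tuning
#' procedure.
#'
#' @param params an [adex_params()] object.
#' @param I_inp input current (pA): either a vector sampled at `dt` or a
#'   function of time (ms).
#' @param t_end simulation horizon (ms); required when `I_inp` is a function.
#' @param dt step size (ms), default 0.01.
#' @param w_self self-synapse conductance increment (nS), default 0 (off).
#' @param tau_exc excitatory conductance decay (ms).
#' @param E_e excitatory reversal potential (mV).
#' @param keep_trace store `V(t)` and `q(t)`? (default TRUE)
#' @return An object of class `neuron_trace`: list with `times`, `V`, `q`
#'   (stored after the reset, so `V` never exceeds `V_peak`) and the spike
#'   times `spikes` (ms, recorded at the end of the crossing step).
#' @export
adex_simulate <- function(params, I_inp, t_end = NULL, dt = 0.01,
                          w_self = 0, tau_exc = 5, E_e = 0,
                          keep_trace = TRUE) {
  stopifnot(dt > 0)
  if (is.function(I_inp)) {
    if (is.null(t_end)) stop("t_end is required when I_inp is a function")
    n <- round(t_end / dt)
    I_vec <- I_inp((seq_len(n) - 1) * dt)
    if (length(I_vec) == 1L) I_vec <- rep(I_vec, n)
  } else {
    I_vec <- as.numeric(I_inp)
  }
  p <- params
  res <- adex_sim_cpp(I_vec, dt, p$C, p$g_L, p$E_L, p$eta, p$V_T,
                      p$V_peak, p$V_rst, p$a, p$b, p$tau_q,
                      w_self, tau_exc, E_e, keep_trace)
  structure(list(times = seq_along(I_vec) * dt,
                 V = res$V, q = res$q,
                 spikes = res$spikes, dt = dt, params = params),
            class = "neuron_trace")
}

#' @export
print.neuron_trace <- function(x, ...) {
  cat(sprintf("<neuron_trace> %g ms at dt = %g ms, %d spikes\n",
              max(x$times), x$dt, length(x$spikes)))
  invisible(x)
}

#' Nullclines and fixed points of the AdEx phase plane
#'
#' The V-nullcline `q = -g_L (V - E_L) + g_L eta exp((V - V_T)/eta) + I` and
#' the q-nullcline `q = a (V - E_L)`, both in pA as functions of V (mV).
#' Fixed points are the intersections, found by root search below the spike
#' initiation zone.
#'
#' @param params an [adex_params()] object.
#' @param I_inp constant input current (pA).
#' @return list with functions `V_null`, `q_null`, and a data frame
#'   `fixed_points` with columns `V`, `q`, `stable`.
#' @export
adex_nullclines <- function(params, I_inp = 0) {
  p <- params
  V_null <- function(V) -p$g_L * (V - p$E_L) +
    p$g_L * p$eta * exp((V - p$V_T) / p$eta) + I_inp
  q_null <- function(V) p$a * (V - p$E_L)
  f <- function(V) V_null(V) - q_null(V)
  # bracket roots on a fine grid from well below rest up to V_peak
  Vs <- seq(p$E_L - 40, p$V_peak, by = 0.01)
  fv <- f(Vs)
  sgn <- sign(fv)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  fps <- lapply(idx, function(i) {
    r <- stats::uniroot(f, c(Vs[i], Vs[i + 1]), tol = 1e-10)
    V0 <- r$root
    # stability from the trace of the Jacobian (a = 0: sign of dF/dV)
    dFdV <- (-p$g_L + p$g_L * exp((V0 - p$V_T) / p$eta)) / p$C
    data.frame(V = V0, q = q_null(V0), stable = dFdV < 0 && p$tau_q > 0)
  })
  fixed_points <- if (length(fps)) do.call(rbind, fps) else
    data.frame(V = numeric(0), q = numeric(0), stable = logical(0))
  list(V_null = V_null, q_null = q_null, fixed_points = fixed_points)
}

#' Rheobase current of the AdEx neuron
#'
#' For `a = 0` the sub-threshold fixed point vanishes when the minimum of
#' the V-nullcline crosses zero, giving the closed form
#' `g_L * ((V_T - E_L) - eta)`.
#'
#' @param params an [adex_params()] object with `a = 0`.
#' @return Rheobase (pA).
#' @export
adex_rheobase <- function(params) {
  if (params$a != 0)
    stop("closed-form rheobase requires a = 0 (no sub-threshold adaptation)")
  params$g_L * ((params$V_T - params$E_L) - params$eta)
}
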