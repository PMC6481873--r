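#' Microstimulation specification
#'
#' A rectangular current pulse delivered at an electrode site in the motor
#' map, with exponential spatial decay of the injected current:
#' `I(u, v, t) = I0 * exp(-lam * dist((u,v), (uE,vE))) * P(t)` where
#' `P(t) = 1` for `t_on <= t < t_on + D_S`. The site may be given in retinal
#' coordinates (`R` deg, `phi` rad, mapped through [sc_afferent()]) or as
#' raw map coordinates (`uE`, `vE` in mm); the continuous tip position is
#' used (no snapping to grid nodes).
#'
#' @param R,phi electrode site in retinal coordinates (deg, rad).
#' @param uE,vE electrode site in map coordinates (mm); overrides `R`/`phi`.
#' @param I0 peak intracellular current (pA), default 150.
#' @param lam spatial decay constant (1/mm), default 10.
#' @param D_S pulse duration (ms), default 100.
#' @param t_on pulse onset (ms), default 0.
#' @param consts a [map_constants()] object for the afferent mapping.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(R = NULL, phi = 0, uE = NULL, vE = NULL,
                          I0 = 150, lam = 10, D_S = 100, t_on = 0,
                          consts = map_constants()) {
  stopifnot(I0 >= 0, lam > 0, D_S > 0)
  if (is.null(uE)) {
    if (is.null(R)) stop("give either (R, phi) or (uE, vE)")
    site <- sc_afferent(R, phi, consts)
    uE <- unname(site[1, "u"]); vE <- unname(site[1, "v"])
  } else {
    if (is.null(vE)) stop("vE required with uE")
    R <- exp(uE / consts$B_u); phi <- vE / consts$B_v
  }
  structure(list(R = R, phi = phi, uE = uE, vE = vE,
                 I0 = I0, lam = lam, D_S = D_S, t_on = t_on),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> site (R = %.3g deg, phi = %.3g rad) -> (u = %.3f, v = %.3f) mm\n",
    x$R, x$phi, x$uE, x$vE))
  cat(sprintf("  I0 = %g pA, lambda = %g /mm, D_S = %g ms, onset %g ms\n",
              x$I0, x$lam, x$D_S, x$t_on))
  invisible(x)
}

#' Stimulation current at a map point and time
#'
#' @param spec a [stimulus_spec()].
#' @param u,v map coordinates (mm); vectorized.
#' @param t time (ms), scalar.
#' @return Current (pA).
#' @export
stim_current <- function(spec, u, v, t) {
  sp <- stim_spatial(spec, u, v)
  if (t >= spec$t_on && t < spec$t_on + spec$D_S) sp else 0 * sp
}

#' Spatial current profile (pulse gating removed)
#'
#' @inheritParams stim_current
#' @return Current (pA) while the pulse is on.
#' @export
stim_spatial <- function(spec, u, v) {
  d <- sqrt((u - spec$uE)^2 + (v - spec$vE)^2)
  spec$I0 * exp(-spec$lam * d)
}

#' Per-neuron stimulation field over a grid
#'
#' @param spec a [stimulus_spec()].
#' @param grid an [build_grid()] object.
#' @param t time (ms); if `NULL` (default) the spatial profile during the
#'   pulse is returned.
#' @return Numeric vector, one current value (pA) per neuron.
#' @export
stim_field <- function(spec, grid, t = NULL) {
  if (is.null(t)) stim_spatial(spec, grid$u, grid$v)
  else stim_current(spec, grid$u, grid$v, t)
}
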