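#' Motor-map constants
#'
#' Scaling constants of the isotropic log-polar gaze-motor map and the
#' efferent mini-vector scale. The afferent map places a retinal target at
#' amplitude `R` (deg) and direction `phi` (rad) onto collicular coordinates
#' `u = B_u*log(R)` (rostral-caudal, mm) and `v = B_v*phi` (medial-lateral,
#' mm), and each spike of a neuron at `(u, v)` contributes the mini-vector
#' `zeta * exp(u) * (cos v, sin v)` (deg) to the eye displacement.
#'
#' @param B_u map scaling along the amplitude axis (mm).
#' @param B_v map scaling along the direction axis (mm/rad).
#' @param zeta efferent mini-vector scaling factor (dimensionless). The
#'   default is the calibrated value for the reference 201 x 201 network; it
#'   can be re-derived for any configuration with [calibrate_zeta()].
#' @return An object of class `sc_map_constants`.
#' @seealso [sc_afferent()], [sc_efferent()], [build_grid()]
#' @export
map_constants <- function(B_u = 1, B_v = 1, zeta = 5.087e-5) {
  stopifnot(B_u > 0, B_v > 0, zeta > 0)
  structure(list(B_u = B_u, B_v = B_v, zeta = zeta),
            class = "sc_map_constants")
}

#' Afferent mapping: retinal coordinates to map coordinates
#'
#' Complex-logarithm projection of a retinal target onto the motor map:
#' `u = B_u*log(R)`, `v = B_v*phi`.
#'
#' @param R saccade amplitude(s), deg; must be positive.
#' @param phi saccade direction(s), rad.
#' @param consts a [map_constants()] object.
#' @return A two-column matrix with columns `u` and `v` (mm).
#' @export
sc_afferent <- function(R, phi, consts = map_constants()) {
  if (any(R <= 0)) stop("amplitude R must be positive (log-polar map)")
  cbind(u = consts$B_u * log(R), v = consts$B_v * phi)
}

#' Efferent mapping: per-spike movement contribution
#'
#' The mini-vector contributed by one spike of a neuron at map site
#' `(u, v)`: `m = zeta * exp(u) * (cos v, sin v)` deg. It inverts the
#' afferent map up to the scale `zeta`.
#'
#' @param u,v map coordinates (mm).
#' @param consts a [map_constants()] object.
#' @param zeta optional override of `consts$zeta`.
#' @return A two-column matrix with columns `m_x` and `m_y` (deg).
#' @export
sc_efferent <- function(u, v, consts = map_constants(), zeta = NULL) {
  z <- if (is.null(zeta)) consts$zeta else zeta
  e <- z * exp(u / consts$B_u)
  cbind(m_x = e * cos(v / consts$B_v), m_y = e * sin(v / consts$B_v))
}

#' Build the discrete motor-map grid
#'
#' Rectangular lattice of neurons covering `u` in `[0, 5]` mm (amplitudes up
#' to `exp(5)` = 148 deg) and `v` in `[-pi/2, pi/2]` mm (the contralateral
#' hemifield). Both endpoints are included so `n` points divide the range
#' evenly; the spacing is anisotropic (`du != dv`) and all distances between
#' neurons are Euclidean in millimetres. Neurons are enumerated row-major
#' with `u` varying fastest, so neuron `n` sits at
#' `(u[(n-1) %% n_u + 1], v[(n-1) %/% n_u + 1])`.
#'
#' @param n_u,n_v number of grid points along each axis (default 201 each).
#' @param consts a [map_constants()] object, stored with the grid.
#' @param u_range,v_range coordinate ranges in mm.
#' @return An object of class `sc_grid` with per-neuron coordinate vectors
#'   `u`, `v` (length `n_u * n_v`), spacings `du`, `dv` and metadata.
#' @export
build_grid <- function(n_u = 201, n_v = 201, consts = map_constants(),
                       u_range = c(0, 5), v_range = c(-pi / 2, pi / 2)) {
  stopifnot(n_u >= 2, n_v >= 2)
  u_ax <- seq(u_range[1], u_range[2], length.out = n_u)
  v_ax <- seq(v_range[1], v_range[2], length.out = n_v)
  structure(list(
    n_u = n_u, n_v = n_v,
    u_axis = u_ax, v_axis = v_ax,
    u = rep(u_ax, times = n_v),
    v = rep(v_ax, each = n_u),
    du = diff(u_range) / (n_u - 1),
    dv = diff(v_range) / (n_v - 1),
    u_range = u_range, v_range = v_range,
    consts = consts
  ), class = "sc_grid")
}

#' @export
print.sc_grid <- function(x, ...) {
  cat(sprintf("<sc_grid> %d x %d neurons, u in [%g, %g] mm, v in [%.4g, %.4g] mm\n",
              x$n_u, x$n_v, x$u_range[1], x$u_range[2],
              x$v_range[1], x$v_range[2]))
  cat(sprintf("  spacing du = %g mm, dv = %.6g mm; zeta = %g\n",
              x$du, x$dv, x$consts$zeta))
  invisible(x)
}

#' Index of the grid neuron nearest to a map point
#'
#' @param grid an `sc_grid`.
#' @param u,v map coordinates (mm).
#' @return Integer neuron index (row-major, `u` fastest).
#' @export
grid_nearest <- function(grid, u, v) {
  iu <- which.min(abs(grid$u_axis - u))
  iv <- which.min(abs(grid$v_axis - v))
  (iv - 1L) * grid$n_u + iu
}
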