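#' Assemble a ready-to-stimulate motor-map model
#'
#' Bundles the grid, the tuned AdEx population and the lateral-connectivity
#' specification. The efferent scale `zeta` can be supplied (e.g. the
#' Table-calibrated default in [map_constants()]) or recalibrated for the
#' configuration with [calibrate_model_zeta()].
#'
#' @param n_u,n_v grid size (default 201 x 201).
#' @param consts [map_constants()].
#' @param params shared [adex_params()].
#' @param conn [connectivity_spec()].
#' @return An object of class `sc_model`: list `grid`, `pop`, `conn`.
#' @export
sc_model <- function(n_u = 201, n_v = 201, consts = map_constants(),
                     params = adex_params(), conn = connectivity_spec()) {
  grid <- build_grid(n_u, n_v, consts)
  structure(list(grid = grid, pop = build_population(grid, params),
                 conn = conn), class = "sc_model")
}

#' Stimulate the model at a retinal site
#'
#' Convenience wrapper: build the [stimulus_spec()] for `(R, phi)` and run
#' the full network simulation.
#'
#' @param model an [sc_model()].
#' @param R,phi site in retinal coordinates (deg, rad).
#' @param I0,lam,D_S,t_on stimulation parameters, see [stimulus_spec()].
#' @param lateral enable lateral interactions?
#' @param ... further arguments to [run_simulation()].
#' @return An `sc_raster`.
#' @export
simulate_site <- function(model, R, phi = 0, I0 = 150, lam = 10, D_S = 100,
                          t_on = 0, lateral = TRUE, ...) {
  stim <- stimulus_spec(R = R, phi = phi, I0 = I0, lam = lam, D_S = D_S,
                        t_on = t_on, consts = model$grid$consts)
  run_simulation(model$grid, model$pop, model$conn, stim,
                 lateral = lateral, ...)
}

#' Calibrate the model's efferent scale
#'
#' Runs the standard calibration stimulation (horizontal 21-deg site,
#' default stimulus parameters) and returns the model with
#' `grid$consts$zeta` replaced by the [calibrate_zeta()] result.
#'
#' @param model an [sc_model()].
#' @param ... passed to [simulate_site()].
#' @return The model with calibrated `zeta`; the value is also attached as
#'   attribute `"zeta"`.
#' @export
calibrate_model_zeta <- function(model, ...) {
  raster <- simulate_site(model, R = 21, phi = 0, ...)
  z <- calibrate_zeta(raster, target_R = 21)
  model$grid$consts$zeta <- z
  attr(model, "zeta") <- z
  model
}

#' Direct-activation footprint (lateral interactions off)
#'
#' @param model an [sc_model()].
#' @param sites list of `c(R, phi)` pairs (deg, rad).
#' @param ... stimulation overrides for [simulate_site()].
#' @return List of per-site results: each with the raster, the per-neuron
#'   spike-count vector of spiking neurons (`counts`), and the activation
#'   `radius` (mm): the largest map distance from the electrode tip among
#'   spiking neurons.
#' @export
exp_direct_footprint <- function(model,
                                 sites = list(c(5, 0), c(31, 30 * pi / 180)),
                                 ...) {
  lapply(sites, function(s) {
    raster <- simulate_site(model, R = s[1], phi = s[2], lateral = FALSE, ...)
    counts <- spike_counts(raster)
    act <- which(counts > 0)
    g <- model$grid
    r <- if (length(act)) {
      max(sqrt((g$u[act] - raster$stim$uE)^2 + (g$v[act] - raster$stim$vE)^2))
    } else 0
    list(raster = raster, counts = counts[act], neurons = act, radius = r)
  })
}

#' Full population response and decoded saccade at one site
#'
#' @param model an [sc_model()] (calibrate `zeta` first for meaningful
#'   kinematics).
#' @param R,phi stimulation site (deg, rad).
#' @param sigma spike-density kernel width (ms).
#' @param ... stimulation overrides for [simulate_site()].
#' @return List with the raster, the decoded `trace`, the saccade metrics
#'   row `saccade`, the central-cell burst metrics row `burst`, the central
#'   neuron index and the recruited-population `diameter` (mm, twice the
#'   largest map distance of a spiking neuron from the central cell).
#' @export
exp_population <- function(model, R, phi = 0, sigma = 8, ...) {
  raster <- simulate_site(model, R = R, phi = phi, lateral = TRUE, ...)
  ctr <- central_neuron(raster)
  ctr_spikes <- raster$time[raster$neuron == ctr]
  burst <- burst_metrics(spike_density(ctr_spikes, sigma = sigma))
  trace <- decode_trace(raster)
  sacc <- saccade_metrics(trace)
  g <- model$grid
  act <- which(spike_counts(raster) > 0)
  diameter <- 2 * max(sqrt((g$u[act] - g$u[ctr])^2 + (g$v[act] - g$v[ctr])^2))
  list(raster = raster, trace = trace, saccade = sacc, burst = burst,
       central = ctr, diameter = diameter)
}

#' Central-cell burst properties along the rostral-caudal axis
#'
#' @param model an [sc_model()].
#' @param R amplitudes (deg) of the horizontal-meridian stimulation sites.
#' @param sigma spike-density kernel width (ms).
#' @param ... stimulation overrides.
#' @return Data frame with one row per site: `R`, the central-cell burst
#'   metrics (`F_peak`, `T_burst`, `N`, `S_burst`), the decoded saccade
#'   metrics and the mean population cross-correlation `C_pop`.
#' @export
exp_rostral_caudal_sweep <- function(model, R = c(2, 7, 11, 15, 21, 31),
                                     sigma = 8, ...) {
  rows <- lapply(R, function(r) {
    res <- exp_population(model, R = r, phi = 0, sigma = sigma, ...)
    sync <- population_sync(res$raster, central = res$central, sigma = sigma)
    cbind(data.frame(R = r), res$burst, res$saccade,
          data.frame(C_pop = mean(sync$C_pop, na.rm = TRUE),
                     diameter = res$diameter))
  })
  do.call(rbind, rows)
}

#' Saccade-endpoint grid across the motor map
#'
#' Decoded endpoints for stimulation over a grid of sites covering the
#' contralateral range (log-spaced amplitudes crossed with directions),
#' avoiding the vertical meridian and the caudal map edge.
#'
#' @param model an [sc_model()].
#' @param R amplitudes (deg); default 9 log-spaced values in `[2, 40]`.
#' @param phi_deg directions (deg); default `c(-60, -30, 0, 30, 60)`.
#' @param I0 current intensity (pA), default 120 for this experiment.
#' @param ... further stimulation overrides.
#' @return Data frame with one row per site: commanded `R`, `phi_deg`,
#'   target `x`, `y` and decoded endpoint `x_dec`, `y_dec` plus the
#'   saccade metrics.
#' @export
exp_saccade_grid <- function(model,
                             R = exp(seq(log(2), log(40), length.out = 9)),
                             phi_deg = c(-60, -30, 0, 30, 60),
                             I0 = 120, ...) {
  sites <- expand.grid(R = R, phi_deg = phi_deg)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    r <- sites$R[i]; ph <- sites$phi_deg[i] * pi / 180
    raster <- simulate_site(model, R = r, phi = ph, I0 = I0, ...)
    trace <- decode_trace(raster)
    sm <- saccade_metrics(trace)
    cbind(data.frame(R = r, phi_deg = sites$phi_deg[i],
                     x = r * cos(ph), y = r * sin(ph),
                     x_dec = trace$x[nrow(trace)],
                     y_dec = trace$y[nrow(trace)]),
          sm)
  })
  do.call(rbind, rows)
}

#' Stimulation-parameter sweeps
#'
#' Peak velocity and amplitude of the decoded saccade as a function of
#' current intensity (at fixed duration) and, optionally, of pulse
#' duration (at fixed intensity).
#'
#' @param model an [sc_model()].
#' @param R amplitudes (deg) of the horizontal-meridian sites.
#' @param I0 current intensities to sweep (pA).
#' @param D_S pulse duration (ms) for the current sweep.
#' @param DS_sweep optional vector of pulse durations (ms) swept at
#'   `I0_fixed`.
#' @param I0_fixed current (pA) for the duration sweep, default 150.
#' @param v_threshold,min_displacement no-saccade criterion, see
#'   [saccade_metrics()].
#' @return Data frame with one row per condition: `R`, `I0`, `D_S`, the
#'   saccade metrics and the `no_saccade` flag.
#' @export
exp_parameter_sweep <- function(model, R = c(15, 21, 31),
                                I0 = seq(40, 280, by = 10), D_S = 100,
                                DS_sweep = NULL, I0_fixed = 150,
                                v_threshold = 30, min_displacement = 0.5) {
  conds <- expand.grid(R = R, I0 = I0, D_S = D_S)
  if (!is.null(DS_sweep))
    conds <- rbind(conds, expand.grid(R = R, I0 = I0_fixed, D_S = DS_sweep))
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    raster <- simulate_site(model, R = conds$R[i], phi = 0,
                            I0 = conds$I0[i], D_S = conds$D_S[i])
    sm <- saccade_metrics(decode_trace(raster),
                          v_threshold = v_threshold,
                          min_displacement = min_displacement)
    cbind(conds[i, , drop = FALSE], sm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
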