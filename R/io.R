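#' Write a spike raster to a self-describing CSV file
#'
#' Plain-text format: `# key=value` header lines carrying the grid metadata
#' (size, ranges, map constants, neuron-indexing convention), the stimulus
#' and the simulation settings, followed by a CSV body with columns
#' `neuron_index`, `u_mm`, `v_mm`, `t_spike_ms`.
#'
#' @param raster an `sc_raster`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  g <- raster$grid; s <- raster$stim
  hdr <- c(
    sprintf("n_u=%d", g$n_u), sprintf("n_v=%d", g$n_v),
    sprintf("u_min_mm=%.17g", g$u_range[1]), sprintf("u_max_mm=%.17g", g$u_range[2]),
    sprintf("v_min_mm=%.17g", g$v_range[1]), sprintf("v_max_mm=%.17g", g$v_range[2]),
    sprintf("B_u_mm=%.17g", g$consts$B_u), sprintf("B_v_mm_per_rad=%.17g", g$consts$B_v),
    sprintf("zeta=%.17g", g$consts$zeta),
    "indexing=row-major, u fastest",
    sprintf("uE_mm=%.17g", s$uE), sprintf("vE_mm=%.17g", s$vE),
    sprintf("I0_pA=%.17g", s$I0), sprintf("lambda_per_mm=%.17g", s$lam),
    sprintf("DS_ms=%.17g", s$D_S), sprintf("t_on_ms=%.17g", s$t_on),
    sprintf("dt_ms=%.17g", raster$dt), sprintf("t_end_ms=%.17g", raster$t_end),
    sprintf("lateral=%s", if (raster$lateral) "on" else "off"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", hdr), con)
  df <- data.frame(neuron_index = raster$neuron,
                   u_mm = g$u[raster$neuron],
                   v_mm = g$v[raster$neuron],
                   t_spike_ms = raster$time)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a spike raster written by [write_raster()]
#'
#' @param path input file.
#' @return An `sc_raster` (grid rebuilt from the header; stimulus and
#'   simulation metadata restored).
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^# ", lines)
  kv <- sub("^# ", "", lines[hdr_lines])
  keyed <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", keyed)
  vals <- sub("^[^=]*=", "", keyed)
  h <- stats::setNames(as.list(vals), keys)
  num <- function(k) as.numeric(h[[k]])
  grid <- build_grid(as.integer(h$n_u), as.integer(h$n_v),
                     map_constants(num("B_u_mm"), num("B_v_mm_per_rad"),
                                   num("zeta")),
                     u_range = c(num("u_min_mm"), num("u_max_mm")),
                     v_range = c(num("v_min_mm"), num("v_max_mm")))
  stim <- stimulus_spec(uE = num("uE_mm"), vE = num("vE_mm"),
                        I0 = num("I0_pA"), lam = num("lambda_per_mm"),
                        D_S = num("DS_ms"), t_on = num("t_on_ms"),
                        consts = grid$consts)
  df <- utils::read.csv(textConnection(lines[-hdr_lines]))
  structure(list(neuron = as.integer(df$neuron_index),
                 time = df$t_spike_ms,
                 n_neurons = grid$n_u * grid$n_v,
                 grid = grid, stim = stim, conn = NULL,
                 lateral = identical(h$lateral, "on"),
                 dt = num("dt_ms"), t_end = num("t_end_ms")),
            class = "sc_raster")
}

#' Write a decoded eye-movement trace to CSV
#'
#' Columns `time_ms`, `x_deg`, `y_deg`, `vx_degps`, `vy_degps`, `v_degps`.
#'
#' @param trace an `sc_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_ms = trace$time, x_deg = trace$x, y_deg = trace$y,
                   vx_degps = trace$vx, vy_degps = trace$vy,
                   v_degps = trace$v)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' INI-like sections (`[neural]`, `[synaptic]`, `[mexican_hat]`,
#' `[stimulation]`, `[simulation]`) with `key = value` lines; `#` starts a
#' comment. Returns a flat named list (numeric where possible); section
#' names are dropped since keys are unique.
#'
#' @param path configuration file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  suppress <- function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) v else n
  }
  stats::setNames(lapply(vals, suppress), keys)
}

#' Write a single-neuron trace to CSV
#'
#' Columns `time_ms`, `V_mV`, `q_pA`; the spike times go to a separate
#' single-column CSV when `spikes_path` is given.
#'
#' @param trace a `neuron_trace` from [adex_simulate()].
#' @param path output file for the state trace.
#' @param spikes_path optional output file for the spike times.
#' @return `path`, invisibly.
#' @export
write_neuron_trace <- function(trace, path, spikes_path = NULL) {
  utils::write.csv(data.frame(time_ms = trace$times, V_mV = trace$V,
                              q_pA = trace$q),
                   path, row.names = FALSE)
  if (!is.null(spikes_path))
    utils::write.csv(data.frame(t_spike_ms = trace$spikes), spikes_path,
                     row.names = FALSE)
  invisible(path)
}
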