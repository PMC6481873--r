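test_that("spike density is a normalized Gaussian rate estimate", {
  tg <- seq(0, 200, by = 0.5)
  d1 <- spike_density(100, sigma = 8, times = tg)
  # single-spike peak: 1/(0.008 sqrt(2 pi)) ~ 49.87 spikes/s
  expect_equal(max(d1$rate), 1000 / (8 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(tg[which.max(d1$rate)], 100)
  # two coincident spikes double the density exactly
  d2 <- spike_density(c(100, 100), sigma = 8, times = tg)
  expect_equal(d2$rate, 2 * d1$rate)
  # integral recovers the spike count
  d5 <- spike_density(c(40, 90, 95, 100, 160), sigma = 8, times = tg)
  expect_equal(sum(d5$rate) * 0.5 / 1000, 5, tolerance = 1e-3)
  # empty spike list: zero density
  expect_equal(spike_density(numeric(0), times = tg)$rate, rep(0, length(tg)))
})

test_that("the ensemble decoder accumulates per-spike mini-vectors", {
  g <- build_grid(41, 41)
  # empty raster decodes to rest
  r0 <- make_raster(g, integer(0), numeric(0), t_end = 100)
  tr0 <- decode_trace(r0)
  expect_true(all(tr0$x == 0 & tr0$y == 0 & tr0$v == 0))
  # K spikes from one neuron: final displacement K * zeta * exp(u) * (cos v, sin v)
  n <- grid_nearest(g, 3, 0.5)
  K <- 17
  r1 <- make_raster(g, rep(n, K), seq(20, 52, length.out = K), t_end = 150)
  tr1 <- decode_trace(r1)
  expect_equal(tr1$x[nrow(tr1)],
               K * g$consts$zeta * exp(g$u[n]) * cos(g$v[n]), tolerance = 1e-6)
  expect_equal(tr1$y[nrow(tr1)],
               K * g$consts$zeta * exp(g$u[n]) * sin(g$v[n]), tolerance = 1e-6)
  # linearity in zeta is exact
  tr2 <- decode_trace(r1, zeta = 2 * g$consts$zeta)
  expect_equal(tr2$x, 2 * tr1$x, tolerance = 1e-12)
  expect_equal(tr2$v, 2 * tr1$v, tolerance = 1e-12)
})

test_that("zeta calibration inverts the decoded amplitude", {
  g <- build_grid(41, 41)
  n <- grid_nearest(g, log(21), 0)
  r <- make_raster(g, rep(n, 20), seq(20, 60, length.out = 20), t_end = 150)
  z <- calibrate_zeta(r, target_R = 21)
  expect_equal(z * 20 * exp(g$u[n]), 21, tolerance = 1e-9)
  # doubling every neuron's spike count halves the calibrated zeta
  r2 <- make_raster(g, rep(n, 40),
                    sort(c(seq(20, 60, length.out = 20),
                           seq(20, 60, length.out = 20) + 0.2)), t_end = 150)
  expect_equal(calibrate_zeta(r2, 21), z / 2, tolerance = 1e-9)
  r_empty <- make_raster(g, integer(0), numeric(0), t_end = 100)
  expect_error(calibrate_zeta(r_empty), "calibrat")
})

test_that("saccade metrics recover a known minimum-jerk movement", {
  tr <- min_jerk_trace(A = 10, D = 50, dt = 1, t0 = 50)
  sm <- saccade_metrics(tr, v_threshold = 30)
  expect_false(sm$no_saccade)
  # analytic peak velocity of a minimum-jerk profile: 1.875 * A / D
  expect_equal(sm$v_peak, 1.875 * 10 / 0.050, tolerance = 0.01)
  expect_equal(sm$amplitude, 10, tolerance = 0.05)
  # onset/offset where |v| crosses 30 deg/s; duration within one sample
  v_norm <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
  crossing <- uniroot(function(x) 10 / 0.05 * v_norm(x) - 30, c(0, 0.4))$root
  expect_lt(abs(sm$duration - 50 * (1 - 2 * crossing)), 2.1)
  # all-zero trace: no saccade
  z <- min_jerk_trace(A = 0)
  expect_true(saccade_metrics(z)$no_saccade)
})

test_that("burst metrics quantify peak, width and asymmetry", {
  tg <- seq(0, 300, by = 0.5)
  sym <- spike_density(c(148, 149, 150, 151, 152), sigma = 8, times = tg)
  bm <- burst_metrics(sym)
  expect_equal(bm$N, 5)
  expect_equal(bm$S_burst, 0, tolerance = 1e-6)
  expect_equal(bm$F_peak, max(sym$rate))
  # a long right tail skews the density positive
  skewed <- spike_density(c(100, 101, 102, 103, 120, 150, 190), sigma = 8,
                          times = tg)
  expect_gt(burst_metrics(skewed)$S_burst, 0.2)
  # width at the 10%-of-peak level grows with spread
  wide <- spike_density(c(100, 130, 160), sigma = 8, times = tg)
  expect_gt(burst_metrics(wide)$T_burst, bm$T_burst)
})

test_that("population synchrony is the zero-lag burst correlation", {
  g <- build_grid(41, 41)
  base <- c(100, 104, 107, 110, 112, 114, 116, 119, 123, 128)
  n1 <- grid_nearest(g, 2.5, 0)
  n2 <- n1 + 1L
  n3 <- n1 + 2L
  # neuron 2: identical burst; neuron 3: anti-phase (silent in the burst,
  # active before and after)
  anti <- c(60, 65, 70, 75, 80, 150, 155, 160, 165, 170)
  r <- make_raster(g, c(rep(n1, 10), rep(n2, 10), rep(n3, 10)),
                   c(base, base, anti), t_end = 250)
  sy <- population_sync(r, central = n1)
  expect_equal(sy$C_pop[sy$neuron == n1], 1)
  expect_equal(sy$C_pop[sy$neuron == n2], 1)
  expect_lt(sy$C_pop[sy$neuron == n3], 0)
  # a time-scaled copy with aligned peak stays highly correlated
  scaled <- 112 + (base - 112) * 1.5
  r2 <- make_raster(g, c(rep(n1, 10), rep(n2, 10)), c(base, scaled),
                    t_end = 250)
  sy2 <- population_sync(r2, central = n1)
  expect_gt(sy2$C_pop[sy2$neuron == n2], 0.8)
})

test_that("main-sequence fit recovers exact generating parameters", {
  R <- c(2, 4, 7, 12, 20, 30, 45, 65)
  dat <- data.frame(amplitude = R,
                    v_peak = 1172 * (1 - exp(-0.04 * R)),
                    duration = 28.7 + 1.1 * R)
  fit <- main_sequence_fit(dat)
  expect_equal(fit$v_asym, 1172, tolerance = 1e-4)
  expect_equal(fit$rate_const, 0.04, tolerance = 1e-4)
  expect_equal(fit$d_intercept, 28.7, tolerance = 1e-6)
  expect_equal(fit$d_slope, 1.1, tolerance = 1e-6)
  expect_error(main_sequence_fit(dat[1:3, ]), "at least 4")
})

test_that("vector averaging returns the activity-weighted cell vector", {
  g <- build_grid(41, 41)
  n <- grid_nearest(g, 3, 0.4)
  r1 <- make_raster(g, rep(n, 8), seq(50, 80, length.out = 8))
  va <- decode_vector_average(r1)
  expect_equal(unname(va["x"]), exp(g$u[n]) * cos(g$v[n]), tolerance = 1e-9)
  expect_equal(unname(va["y"]), exp(g$u[n]) * sin(g$v[n]), tolerance = 1e-9)
  # two equally active neurons symmetric about a site average to the site,
  # independent of the common rate scale
  nA <- grid_nearest(g, 3, 0.4 + 2 * g$dv)
  nB <- grid_nearest(g, 3, 0.4 - 2 * g$dv)
  mid <- (sc_efferent(g$u[nA], g$v[nA], g$consts, zeta = 1) +
            sc_efferent(g$u[nB], g$v[nB], g$consts, zeta = 1)) / 2
  for (K in c(3, 12)) {
    tA <- seq(50, 80, length.out = K)
    rr <- make_raster(g, c(rep(nA, K), rep(nB, K)), c(tA, tA + 0.3))
    va2 <- decode_vector_average(rr)
    expect_equal(unname(va2["x"]), as.numeric(mid[1, 1]), tolerance = 1e-9)
    expect_equal(unname(va2["y"]), as.numeric(mid[1, 2]), tolerance = 1e-9)
  }
  expect_error(decode_vector_average(make_raster(g, integer(0), numeric(0))),
               "undefined")
})
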