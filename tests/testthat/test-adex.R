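test_that("resting state is the stable fixed point", {
  p <- adex_params()
  st <- adex_step(list(V = p$E_L, q = 0), p, I_inp = 0)
  # exponential term contributes a small depolarizing drift at rest; the
  # state stays in the basin and the full simulation settles at rest
  expect_false(st$spiked)
  tr <- adex_simulate(p, function(t) 0 * t, t_end = 500)
  expect_length(tr$spikes, 0)
  # rest sits ~0.6 mV above E_L where leak and exponential currents balance
  expect_lt(abs(tr$V[length(tr$V)] - p$E_L), 1)
  expect_lt(abs(tr$q[length(tr$q)]), 1e-6)
})

test_that("sub-rheobase current never elicits a spike", {
  p <- adex_params()
  tr <- adex_simulate(p, function(t) rep(15, length(t)), t_end = 1000)
  expect_length(tr$spikes, 0)
  expect_lt(max(tr$V), p$V_T)
  # the membrane settles at the stable root of the shifted nullcline
  nc <- adex_nullclines(p, I_inp = 15)
  v_star <- nc$fixed_points$V[nc$fixed_points$stable]
  expect_lt(abs(tr$V[length(tr$V)] - v_star[1]), 0.05)
})

test_that("long-tau neuron fires repetitive short bursts under long pulses", {
  p <- adex_params(tau_q = 84.6)
  tr <- adex_simulate(p, function(t) ifelse(t < 225, 250, 0), t_end = 425,
                      keep_trace = FALSE)
  sp <- tr$spikes
  # burst cycles separated by silent periods: split at gaps > 25 ms
  groups <- cumsum(c(0, diff(sp) > 25))
  sizes <- as.integer(table(groups))
  expect_gte(length(sizes), 2)
  expect_true(all(sizes >= 4 & sizes <= 6))
})

test_that("short-tau neuron keeps eliciting spikes through long pulses", {
  # fast adaptation recovery: the neuron does not settle into the
  # burst-silence cycling of the long-tau cell but accumulates many more
  # spikes over a long, strong pulse
  p <- adex_params(tau_q = 52.4)
  tr <- adex_simulate(p, function(t) ifelse(t < 225, 250, 0), t_end = 425,
                      keep_trace = FALSE)
  expect_gt(length(tr$spikes), 13)
  slow <- adex_simulate(adex_params(tau_q = 84.6),
                        function(t) ifelse(t < 225, 250, 0), t_end = 425,
                        keep_trace = FALSE)
  expect_gt(length(tr$spikes), length(slow$spikes))
  # and keeps firing in the late phase of the pulse
  expect_gt(sum(tr$spikes > 150 & tr$spikes < 225), 3)
})

test_that("first-spike latency is non-increasing in stimulus strength", {
  p <- adex_params(tau_q = 70.95)
  lat <- vapply(seq(50, 250, by = 50), function(I0) {
    tr <- adex_simulate(p, function(t) ifelse(t < 100, I0, 0), t_end = 300,
                        keep_trace = FALSE)
    if (length(tr$spikes)) tr$spikes[1] else Inf
  }, numeric(1))
  expect_true(all(diff(lat) <= 0))
})

test_that("adaptation decays exponentially between spikes and jumps by b", {
  p <- adex_params(tau_q = 84.6)
  tr <- adex_simulate(p, function(t) ifelse(t < 100, 150, 0), t_end = 400)
  sp <- tr$spikes
  expect_gte(length(sp), 2)
  i_sp <- round(sp / tr$dt)
  # jump at each reset: q just after minus just before, corrected for the
  # one-step Euler decay
  for (k in seq_along(sp)) {
    q_before <- if (i_sp[k] > 1) tr$q[i_sp[k] - 1] else 0
    jump <- tr$q[i_sp[k]] - q_before * (1 - tr$dt / p$tau_q)
    expect_equal(jump, p$b, tolerance = 1e-9)
  }
  # exponential decay with time constant tau_q after the last spike
  i0 <- i_sp[length(i_sp)] + 500
  i1 <- i0 + 5000  # 50 ms later
  ratio <- tr$q[i1] / tr$q[i0]
  expect_equal(ratio, exp(-5000 * tr$dt / p$tau_q), tolerance = 1e-3)
})

test_that("traces never exceed the spiking ceiling and stay finite", {
  p <- adex_params(tau_q = 52.4)
  tr <- adex_simulate(p, function(t) ifelse(t < 225, 250, 0), t_end = 425)
  expect_true(all(tr$V <= p$V_peak))
  expect_true(all(is.finite(tr$V)), all(is.finite(tr$q)))
})

test_that("nullclines have the analytic shape", {
  p <- adex_params()
  nc0 <- adex_nullclines(p, I_inp = 0)
  # with a = 0 the q-nullcline is identically zero
  expect_equal(nc0$q_null(c(-70, -53, -40)), c(0, 0, 0))
  # stable fixed point at the resting state (~E_L, 0 pA): the exponential
  # term shifts the exact root ~0.6 mV above E_L
  stab <- nc0$fixed_points[nc0$fixed_points$stable, ]
  expect_lt(abs(stab$V[1] - p$E_L), 1)
  expect_equal(stab$q[1], 0)
  # V-nullcline minimum at V_T
  Vs <- seq(-60, -40, by = 0.001)
  expect_equal(Vs[which.min(nc0$V_null(Vs))], p$V_T, tolerance = 2e-3)
  # additive shift by the input current
  nc1 <- adex_nullclines(p, I_inp = 37)
  expect_equal(nc1$V_null(-48) - nc0$V_null(-48), 37)
})

test_that("rheobase follows the closed form", {
  p <- adex_params()
  expect_equal(adex_rheobase(p), 20)
  # no fixed point just above rheobase
  nc <- adex_nullclines(p, I_inp = 21)
  expect_equal(nrow(nc$fixed_points), 0)
  # two fixed points just below
  nc2 <- adex_nullclines(p, I_inp = 19)
  expect_gte(nrow(nc2$fixed_points), 2)
  # leaky-IF limit and linearity in g_L
  expect_equal(adex_rheobase(adex_params(eta = 1e-9)), 60, tolerance = 1e-6)
  expect_equal(adex_rheobase(adex_params(g_L = 40)), 40)
  expect_error(adex_rheobase(adex_params(a = 2)), "a = 0")
})

test_that("compiled stepper agrees with the R reference step", {
  p <- adex_params(tau_q = 60)
  I0 <- 180
  n <- 3000  # 30 ms
  tr <- adex_simulate(p, rep(I0, n), dt = 0.01)
  st <- list(V = p$E_L, q = 0)
  V_ref <- numeric(n)
  for (k in seq_len(n)) {
    st <- adex_step(st, p, I0, dt = 0.01)
    V_ref[k] <- st$V
  }
  expect_equal(tr$V, V_ref, tolerance = 1e-10)
})

test_that("spike counts converge with the integration step", {
  # forward Euler at the reference resolution agrees with a 10x finer step
  # in spike count for nearly all stimulus combinations (regime boundaries
  # can flip a burst cycle) and in first-spike latency throughout
  combos <- expand.grid(tau_q = c(84.6, 70.95, 52.4),
                        I0 = c(50, 150, 250), DS = c(25, 125, 225))
  agree <- 0
  for (i in seq_len(nrow(combos))) {
    p <- adex_params(tau_q = combos$tau_q[i])
    I_fun <- function(t) ifelse(t < combos$DS[i], combos$I0[i], 0)
    s1 <- adex_simulate(p, I_fun, t_end = combos$DS[i] + 200, dt = 0.01,
                        keep_trace = FALSE)$spikes
    s2 <- adex_simulate(p, I_fun, t_end = combos$DS[i] + 200, dt = 0.001,
                        keep_trace = FALSE)$spikes
    if (length(s1) == length(s2)) agree <- agree + 1
    if (length(s1) && length(s2))
      expect_lt(abs(s1[1] - s2[1]), 0.1)
  }
  expect_gte(agree / nrow(combos), 0.9)
})

test_that("an adaptive high-accuracy integrator reproduces Euler spike counts", {
  p <- adex_params()
  ode_spike_times <- function(tau_q, I0, DS, t_end) {
    f <- function(t, y, parms) {
      I <- if (t < DS) I0 else 0
      list(c((-p$g_L * (y[1] - p$E_L) +
                p$g_L * p$eta * exp((y[1] - p$V_T) / p$eta) - y[2] + I) / p$C,
             (p$a * (y[1] - p$E_L) - y[2]) / tau_q))
    }
    root <- function(t, y, parms) y[1] - p$V_peak
    t0 <- 0; y <- c(p$E_L, 0); times <- numeric(0)
    repeat {
      out <- deSolve::lsodar(y, seq(t0, t_end, by = 0.05), f, NULL,
                             rootfun = root, rtol = 1e-10, atol = 1e-8)
      tr <- attr(out, "troot")
      if (is.null(tr) || !length(tr)) break
      times <- c(times, tr[1])
      y <- c(p$V_rst, out[nrow(out), 3] + p$b)
      t0 <- tr[1]
      if (t0 >= t_end - 0.1) break
    }
    times
  }
  for (cfg in list(c(84.6, 150, 100), c(84.6, 250, 225), c(52.4, 250, 225))) {
    pe <- adex_params(tau_q = cfg[1])
    eu <- adex_simulate(pe, function(t) ifelse(t < cfg[3], cfg[2], 0),
                        t_end = cfg[3] + 200, keep_trace = FALSE)$spikes
    od <- ode_spike_times(cfg[1], cfg[2], cfg[3], cfg[3] + 200)
    expect_equal(length(eu), length(od))
    expect_lt(abs(eu[1] - od[1]), 0.1)
  }
})
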