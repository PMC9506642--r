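test_that("passive RC compartment matches the closed form to 0.1%", {
  m <- rc_model(g_pas = 1e-4, e_pas = -70, diam = 20)
  area <- m$graph$area_cm2[1]
  g_nS <- 1e-4 * area * 1e9          # leak in nS
  tau <- 1e-3 * 1 / 1e-4             # cm/g_pas in ms (10 ms here)
  i_nA <- 0.02
  res <- run_sim(m, list(square_pulse(1L, 0, 500, i_nA)),
                 sim_config(dt = 0.025, t_stop = 400, settle = 200))
  dv_inf <- i_nA / (g_nS * 1e-3)     # I/g in mV
  v_t <- function(t) -70 + dv_inf * (1 - exp(-t / tau))
  for (t in c(5, 10, 20, 50, 399)) {
    idx <- which.min(abs(res$t - t))
    expect_close(res$v[idx, 1] / v_t(res$t[idx]), 1, 1e-3)
  }
})

test_that("finite sealed-end cable input resistance matches cable theory", {
  d_um <- 2; len <- 800; rm <- 1e4; ra <- 100
  m <- cable_model(diam = d_um, len = len, max_len = 10, g_pas = 1 / rm,
                   ra = ra)
  end <- nrow(m$graph)               # most distal compartment
  i_nA <- 0.01
  res <- run_sim(m, list(square_pulse(end, 0, 4000, i_nA)),
                 sim_config(dt = 0.05, t_stop = 3000, settle = 100,
                            record_stride = 100),
                 probes = list(end))
  dv <- res$v[nrow(res$v), 2] - (-70)
  r_in_MOhm <- dv / i_nA             # mV/nA = MOhm
  d_cm <- d_um * 1e-4
  lambda <- sqrt(rm * d_cm / (4 * ra))                 # cm
  r_inf <- sqrt(rm / (pi * d_cm) * 4 * ra / (pi * d_cm^2))  # Ohm
  r_th <- r_inf / tanh((len * 1e-4) / lambda) / 1e6    # MOhm
  expect_close(r_in_MOhm / r_th, 1, 0.01)
})

test_that("equilibrium and steady-state initialization hold", {
  m <- hz_model()
  ## settled state: max |dV/dt| below 1e-4 mV/ms across compartments
  r1 <- run_sim(m, list(), sim_config(t_stop = 1, settle = 2000))
  r2 <- run_sim(m, list(), sim_config(t_stop = 4, settle = 2000))
  rate <- max(abs(r2$v_end - r1$v_end)) / 3
  expect_lt(rate, 1e-4)
  ## no stimulus, gates settled: V constant to < 0.01 mV over 1 s
  r3 <- run_sim(m, list(), sim_config(t_stop = 1000, settle = 2000,
                                      record_stride = 100),
                probes = list(300, 800, 1300))
  expect_lt(max(abs(apply(r3$v, 2, function(x) diff(range(x))))), 0.01)
})

test_that("with zero conductances and no stimulus V stays constant", {
  tree <- make_ball_and_tuft()
  m <- cmodel(discretize(tree), g_pas = 0, e_pas = -70, v_init = -63.25)
  res <- run_sim(m, list(), sim_config(t_stop = 50, settle = 10))
  expect_lt(max(abs(res$v_end - (-63.25))), 1e-10)
})

test_that("halving dt changes the somatic response by < 0.5%", {
  m <- hz_model()
  stim <- list(alpha_synapse(select_site(scenario_tree(m), "apical", 300),
                             10, tau = 5, g_max = 10, e_rev = 0))
  peak <- function(dt) {
    r <- run_sim(m, stim, sim_config(dt = dt, t_stop = 80, settle = 400))
    max(r$v[, 1]) - r$v[1, 1]        # depolarization peak
  }
  p1 <- peak(0.05); p2 <- peak(0.025)
  expect_close(p2 / p1, 1, 5e-3)
})

test_that("halving the spatial step changes input resistance by < 0.5%", {
  rin <- function(ml) {
    tree <- make_ball_and_tuft()
    m <- cmodel(discretize(tree, max_len = ml), g_pas = 5e-5, e_pas = -70,
                v_init = -70)
    r <- run_sim(m, list(square_pulse(1L, 0, 3000, 0.05)),
                 sim_config(dt = 0.05, t_stop = 2000, settle = 50,
                            record_stride = 400))
    (r$v[nrow(r$v), 1] + 70) / 0.05
  }
  expect_close(rin(10) / rin(20), 1, 5e-3)
})

test_that("detect_spikes finds threshold crossings with refractoriness", {
  tt <- seq(0, 100, by = 0.1)
  trace <- -65 + 80 * (exp(-(tt - 20)^2 / 2) + exp(-(tt - 60)^2 / 2))
  sp <- detect_spikes(trace, tt)
  expect_equal(length(sp), 2)
  expect_close(sp, c(19, 59), 1.5)
  ## subthreshold trace
  expect_equal(length(detect_spikes(trace * 0 - 20, tt)), 0)
  ## refractory suppression of a double crossing
  tr2 <- -65 + 80 * (exp(-(tt - 20)^2 / 0.02) + exp(-(tt - 20.6)^2 / 0.02))
  expect_equal(length(detect_spikes(tr2, tt, refractory = 1)), 1)
  expect_equal(length(detect_spikes(tr2, tt, refractory = 0.2)), 2)
  ## window restriction
  expect_equal(length(detect_spikes(trace, tt, window = c(40, 100))), 1)
})

test_that("engine spike detection agrees with detect_spikes on the trace", {
  m <- hz_model()
  res <- run_sim(m, list(square_pulse(1L, 20, 400, 0.6)),
                 sim_config(t_stop = 450, settle = 500))
  sp_r <- detect_spikes(res$v[, 1], res$t, threshold = 0, refractory = 1)
  expect_equal(length(res$spikes), length(sp_r))
  expect_close(res$spikes, sp_r, 0.05)
  expect_true(all(diff(res$spikes) > 0))
})

test_that("gating replay reproduces and swaps responses", {
  m <- one_comp_model()
  mb <- ih_blocked(m)
  stim <- list(alpha_synapse(1L, 10, tau = 5, g_max = 2, e_rev = 0))
  cfg <- sim_config(t_stop = 150, settle = 1000)
  rc <- run_sim(m, stim, cfg)
  rb <- run_sim(mb, stim, cfg)
  ## self-replay identity within 0.1 mV
  cap_self <- capture_gating(m, stim, cfg, "calva", gate = 2, comp = 1)
  rs <- run_with_replay(m, stim, cfg, cap_self)
  expect_lt(max(abs(rs$v - rc$v)), 0.1)
  ## h from the blocked run into the intact model -> stronger response
  cap_h <- capture_gating(mb, stim, cfg, "calva", gate = 2, comp = 1)
  rh <- run_with_replay(m, stim, cfg, cap_h)
  expect_gt(max(rh$v), max(rc$v) + 5)
  ## m from the blocked run -> no stronger response
  cap_m <- capture_gating(mb, stim, cfg, "calva", gate = 1, comp = 1)
  rm_ <- run_with_replay(m, stim, cfg, cap_m)
  expect_lt(max(rm_$v), max(rc$v) + 1)
  ## trace must cover the simulation epoch
  short <- cap_h; short$t <- short$t[short$t <= 50]
  short$values <- short$values[seq_along(short$t)]
  expect_error(run_with_replay(m, stim, cfg, short), "cover")
})

test_that("integration failure is reported with time information", {
  ## a wildly unstable mechanism: enormous inward conductance at rest
  m <- rc_model()
  m <- add_mechanism(m, "bad",
                     generic_channel_params(
                       gates = list(generic_gate(voff = -200, vslo = 1,
                                                 tau_min = 1e-4)),
                       e_rev = Inf),
                     density = 1e4)
  expect_error(run_sim(m, list(), sim_config(t_stop = 10, settle = 0)),
               "integration failure")
})
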