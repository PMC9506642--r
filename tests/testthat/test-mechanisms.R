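## Channel-kinetics oracles: expected values are computed inline from the
## closed-form expressions, independently of the package implementation.

vgrid <- seq(-120, 60, by = 0.1)

test_that("Hay Ih rates match the closed form and its singular limit", {
  p <- ih_hay_params()
  ## removable singularity at v_off_a: alpha -> v_slo_a / tau_a
  r <- ih_hay_rates(-154.9, p)
  alpha_lim <- 11.9 / 155.521
  beta <- exp(-154.9 / 33.1) / 5.18135
  expect_close(r$h_inf, alpha_lim / (alpha_lim + beta), 1e-9)
  expect_equal(round(r$h_inf, 3), 0.977)
  expect_close(r$tau, 1 / (alpha_lim + beta), 1e-6)
  ## generic point, independent evaluation
  v <- -80
  a <- (v + 154.9) / (155.521 * (exp((v + 154.9) / 11.9) - 1))
  b <- exp(v / 33.1) / 5.18135
  r80 <- ih_hay_rates(v, p)
  expect_close(r80$h_inf, a / (a + b), 1e-12)
  expect_close(r80$tau, 1 / (a + b), 1e-9)
  ## asymptotics
  expect_gt(ih_hay_rates(-300, p)$h_inf, 0.999)
  expect_lt(ih_hay_rates(60, p)$h_inf, 1e-3)
})

test_that("Almog Ih rates match the closed form", {
  p <- ih_almog_params()
  expect_close(ih_almog_rates(-91, p)$h_inf, 0.5, 1e-12)
  expect_close(ih_almog_rates(-85, p)$h_inf, 1 / (1 + exp(1)), 1e-12)
  t_adj <- 2.3^1.2
  tau91 <- 1 / (t_adj * (exp(91 / 40.1606426) / 2542.5883549 +
                         exp(-91 / 16.1290323) / 11.40250855))
  expect_close(ih_almog_rates(-91, p)$tau, tau91, 1e-9)
  expect_equal(round(tau91, 1), 89.7)
})

test_that("LVA calcium gates match the closed form", {
  p <- calva_params()
  r <- calva_rates(c(-40, -90, -34), p)
  expect_close(r$m_inf[1], 0.5, 1e-12)
  expect_close(r$h_inf[2], 0.5, 1e-12)
  expect_close(r$m_inf[3], 1 / (1 + exp(-1)), 1e-12)
  ## inactivation decreases with depolarization (resting availability logic)
  rr <- calva_rates(vgrid, p)
  expect_true(all(diff(rr$h_inf) < 0))
  expect_true(all(diff(rr$m_inf) > 0))
})

test_that("gates are bounded and time constants positive over [-120,60]", {
  for (fn in list(function(v) ih_hay_rates(v),
                  function(v) ih_almog_rates(v))) {
    r <- fn(vgrid)
    expect_true(all(r$h_inf >= 0 & r$h_inf <= 1))
    expect_true(all(r$tau > 0))
    expect_true(all(diff(r$h_inf) < 0))   # monotone decreasing
  }
  r <- calva_rates(vgrid)
  expect_true(all(r$m_inf >= 0 & r$m_inf <= 1))
  expect_true(all(r$h_inf >= 0 & r$h_inf <= 1))
  expect_true(all(r$tau_m > 0) && all(r$tau_h > 0))
  ## generic plug-in gate is evaluable without overflow
  g <- generic_gate(voff = -35, vslo = 9, tau_min = 1)
  gr <- generic_gate_rates(vgrid, g)
  expect_true(all(is.finite(gr$inf)) && all(is.finite(gr$tau)))
})

test_that("neuromodulation shifts the curves and is invertible", {
  p <- ih_almog_params()
  p5 <- apply_neuromod(p, neuromod_spec(dv = 5))
  expect_close(ih_almog_rates(-86, p5)$h_inf, 0.5, 1e-12)
  ## identity
  p0 <- apply_neuromod(p, neuromod_spec(dv = 0, tau_scale = 1))
  expect_identical(ih_almog_rates(vgrid, p0), ih_almog_rates(vgrid, p))
  ## pointwise shift on a grid (Hay, -10 mV)
  h <- ih_hay_params()
  hm <- apply_neuromod(h, neuromod_spec(dv = -10))
  expect_close(ih_hay_rates(vgrid, hm)$h_inf,
               ih_hay_rates(vgrid + 10, h)$h_inf, 1e-12)
  ## +dv then -dv restores the original pointwise
  hpm <- apply_neuromod(apply_neuromod(h, neuromod_spec(dv = 7)),
                        neuromod_spec(dv = -7))
  expect_close(ih_hay_rates(vgrid, hpm)$h_inf,
               ih_hay_rates(vgrid, h)$h_inf, 1e-12)
  expect_close(ih_hay_rates(vgrid, hpm)$tau, ih_hay_rates(vgrid, h)$tau,
               1e-9)
  ## tau scaling, and the steady-state-only variant
  hs <- apply_neuromod(h, neuromod_spec(dv = 0, tau_scale = 0.25))
  expect_close(ih_hay_rates(-80, hs)$tau, ih_hay_rates(-80, h)$tau / 4, 1e-9)
  hn <- apply_neuromod(h, neuromod_spec(dv = 10, shift_tau = FALSE))
  expect_close(ih_hay_rates(-80, hn)$tau, ih_hay_rates(-80, h)$tau, 1e-9)
  expect_close(ih_hay_rates(-80, hn)$h_inf, ih_hay_rates(-90, h)$h_inf, 1e-12)
  ## only Ih may be modulated
  expect_error(apply_neuromod(calva_params(), neuromod_spec(dv = 5)),
               "unsupported modulation")
})

test_that("conductance profiles, block and hot zone reproduce the published
           densities", {
  ## Hay-style LVA: 187 uS/cm^2 baseline, x100 inside 685-885 um
  lva <- conductance_profile("apical", "constant", base = 187e-6,
                             hot_zone = list(interval = c(685, 885),
                                             multiplier = 100))
  expect_close(profile_density(lva, 700), 100 * 187e-6, 1e-12)
  expect_close(profile_density(lva, 600), 187e-6, 1e-12)
  ## closed-interval boundaries
  expect_close(profile_density(lva, c(685, 885)), rep(100 * 187e-6, 2), 1e-12)
  ## removal -> constant along the dendrite
  flat <- hot_zone(lva, remove = TRUE)
  d <- profile_density(flat, seq(0, 1300, by = 10))
  expect_true(all(d == 187e-6))
  ## Almog-style absolute zone: 300 mS/cm^2 inside 585-985, 3 mS/cm^2 outside
  alm <- conductance_profile("apical", "constant", base = 3e-3,
                             hot_zone = list(interval = c(585, 985),
                                             absolute = 0.3))
  expect_close(profile_density(alm, c(585, 985)), rep(0.3, 2), 1e-12)
  expect_close(profile_density(alm, c(584.9, 985.1)), rep(3e-3, 2), 1e-12)
  ## block: factor 0 everywhere, factor 1 identity, factor 2 over-expression
  expect_true(all(profile_density(block(lva, 0), seq(0, 1300, 10)) == 0))
  expect_close(profile_density(block(lva, 1), 700),
               profile_density(lva, 700), 1e-15)
  expect_close(profile_density(block(lva, 2), 600), 2 * 187e-6, 1e-12)
})

test_that("model-level block respects region selectors", {
  m <- hz_model()
  mb <- block(m, 0, mechanism = "ih", region = "dend")
  soma <- m$graph$region == "soma"
  expect_equal(mb$mechs$ih$density[soma], m$mechs$ih$density[soma])
  expect_true(all(mb$mechs$ih$density[!soma] == 0))
  ## whole-cell block zeroes every sampled density
  mall <- block(m, 0, mechanism = "ih")
  expect_true(all(mall$mechs$ih$density == 0))
  ## toggling the hot zone leaves non-calcium densities unchanged
  m2 <- make_scenario(scenario_spec(hot_zone = FALSE))
  expect_equal(m2$mechs$ih$density, m$mechs$ih$density)
  expect_equal(m2$mechs$na$density, m$mechs$na$density)
})

test_that("calcium reversal and pool follow their closed forms", {
  expect_close(nernst_eca(1e-4, 2, 307.15),
               1e3 * 8.31446261815324 * 307.15 / (2 * 96485.33212) *
                 log(2 / 1e-4), 1e-12)
  expect_equal(round(nernst_eca(1e-4, 2, 307.15), 0), 131)
  expect_equal(nernst_eca(2, 2), 0)
  ## monotone decreasing in ca_i
  cas <- c(1e-5, 1e-4, 1e-3, 1e-2)
  expect_true(all(diff(nernst_eca(cas)) < 0))
  expect_error(nernst_eca(-1), "positive")

  p <- ca_pool_params()
  ## fixed point at rest with no current
  expect_close(ca_pool_step(p$ca_rest, 0, p, 5), p$ca_rest, 1e-15)
  ## exponential decay toward rest, closed form to 1e-9 relative
  ca0 <- 5e-3
  got <- ca_pool_step(ca0, 0, p, 7)
  want <- p$ca_rest + (ca0 - p$ca_rest) * exp(-7 / p$tau_decay)
  expect_close(got / want, 1, 1e-9)
  ## constant inward current drives the pool to rest + gamma*|I|*tau
  area <- 2e-6
  gam <- 1e-6 / (2 * 96485.33212 * p$depth_um * 1e-4 * area)
  ca <- p$ca_rest
  for (i in 1:4000) ca <- ca_pool_step(ca, -0.5, p, 1, area_cm2 = area)
  expect_close(ca / (p$ca_rest + gam * 0.5 * p$tau_decay), 1, 1e-6)
})

test_that("gate ODE relaxes to the analytic steady state", {
  ## integrate dh/dt = (h_inf - h)/tau at fixed V well past 10 time
  ## constants (15 here, so the residual e^-15 transient sits below the
  ## 1e-6 tolerance even from h = 0)
  p <- ih_hay_params()
  v <- -95
  r <- ih_hay_rates(v, p)
  h <- 0
  dt <- r$tau / 1000
  for (i in seq_len(15000)) h <- h + dt * (r$h_inf - h) / r$tau
  expect_close(h, r$h_inf, 1e-6)
})
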