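test_that("density rules evaluate the published piecewise expressions", {
  rules <- default_density_rules()
  expect_equal(conductance_at(rules, "CaT", region = "apical", x = 300), 0.012)
  expect_equal(conductance_at(rules, "CaT", region = "basal", x = 100), 0.036)
  expect_equal(conductance_at(rules, "CaT", region = "apical", x = 100),
               0.029 * sin(0.009 * 100 + 0.88))
  expect_equal(conductance_at(rules, "KA", region = "basal", d = 0.5), 108)
  expect_equal(conductance_at(rules, "KA", region = "basal", d = 1.0), 10.8)
  expect_equal(conductance_at(rules, "Na", region = "apical", x = 42), 0.303)
  expect_equal(conductance_at(rules, "Na", region = "basal", x = 999), 0.303)
  expect_equal(conductance_at(rules, "Kdr", region = "soma"), 0.05)
  expect_equal(conductance_at(rules, "CaHVA", region = "basal", x = 100),
               0.05e-3 + 1e-7 * 100)
  expect_error(conductance_at(rules, "Kv7", region = "soma"),
               class = "ab_lookup_error")
})

test_that("densities are finite and non-negative over a whole morphology", {
  rules <- default_density_rules()
  m <- generate_synthetic_morphology(seed = 2)
  segs <- m$segments
  for (ch in ab_channels) {
    vals <- vapply(seq_len(nrow(segs)), function(i)
      conductance_at(rules, ch, segment = segs[i, ]), numeric(1))
    expect_true(all(is.finite(vals)))
    expect_true(all(vals >= 0))
  }
})

test_that("the apical calcium sinusoid is clamped and jumps at its cut-over", {
  rules <- default_density_rules()
  # the printed sinusoid goes negative just below 260 um; the rule clamps it
  expect_equal(conductance_at(rules, "CaT", region = "apical", x = 255), 0)
  # recorded discontinuity at x = 260: 0 on the left, 0.012 on the right
  left <- conductance_at(rules, "CaT", region = "apical", x = 260)
  right <- conductance_at(rules, "CaT", region = "apical", x = 260.0001)
  expect_equal(left, 0)
  expect_equal(right - left, 0.012)
})

test_that("gates converge to steady state and integrate exactly", {
  st <- channel_state_init(-79)
  # drive to a new voltage long enough: every gate reaches inf within 1e-9
  v <- -30
  for (i in 1:500) st <- step_channel_states(st, v, dt = 50)
  kin <- channel_kinetics(v, st$ca)
  expect_equal(unname(st$gates), kin$inf, tolerance = 1e-9)

  # one dt step equals two dt/2 sub-steps at constant voltage (exact update)
  s1 <- step_channel_states(channel_state_init(-79), -50, dt = 0.2)
  s2 <- step_channel_states(
    step_channel_states(channel_state_init(-79), -50, dt = 0.1), -50, dt = 0.1)
  expect_equal(s1$gates, s2$gates, tolerance = 1e-12)

  # unconditional stability: gates stay in [0, 1] for any dt
  s3 <- step_channel_states(channel_state_init(-79), 50, dt = 1e6)
  expect_true(all(s3$gates >= 0 & s3$gates <= 1))
})

test_that("calcium decays monotonically to its resting floor", {
  st <- channel_state_init(-79)
  st$ca <- 5e-3
  ions <- st$ions
  track <- numeric(30)
  for (i in 1:30) {
    st <- step_channel_states(st, -79, dt = 10, i_ca = 0)
    track[i] <- st$ca
  }
  expect_true(all(diff(track) < 0 | track[-1] == ions$ca_inf))
  # closed-form exponential decay toward ca_inf
  expect_equal(track[1],
               ions$ca_inf + (5e-3 - ions$ca_inf) * exp(-10 / ions$ca_tau),
               tolerance = 1e-12)
  expect_gt(min(track), ions$ca_inf - 1e-15)
})

test_that("membrane current assembles leak and channel terms in uA/cm^2", {
  st <- channel_state_init(-79)
  p <- passive_params()
  expect_equal(membrane_current(st, p$e_leak, passive = p), 0)
  p2 <- passive_params(g_leak = 1e-4, e_leak = -70)
  expect_equal(membrane_current(st, -60, passive = p2), 1.0)
  # sodium fully open at V = e_Na contributes nothing beyond leak
  st_open <- channel_state_init(60)
  st_open$gates[c("na.m", "na.h")] <- 1
  i_na_only <- membrane_current(st_open, 60, densities = c(Na = 100),
                                passive = p2) -
    membrane_current(st_open, 60, passive = p2)
  expect_equal(i_na_only, 0)
  # with all active densities zero the membrane is affine in V
  vs <- seq(-100, 40, by = 20)
  iv <- vapply(vs, function(v) membrane_current(st, v, passive = p), numeric(1))
  expect_equal(diff(iv, differences = 2), rep(0, length(vs) - 2),
               tolerance = 1e-12)
})
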