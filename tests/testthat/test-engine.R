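test_that("discretisation follows the lambda fraction rule", {
  soma <- cylinder_morphology(length = 1, diameter = 1)$segments[1, ]
  soma_only <- apicobasal:::new_morphology(soma, soma_area_um2 = pi * 1e-6)
  sys0 <- build_system(soma_only, rules = passive_density_rules())
  expect_equal(nrow(sys0$comp), 1)

  p <- passive_params(g_leak = 1e-4, r_a = 100) # lambda(d = 1) = 500 um
  cyl <- cylinder_morphology(length = 500, diameter = 1)
  sys <- build_system(cyl, passive = p, rules = passive_density_rules(),
                      lambda_fraction = 0.1)
  expect_equal(sum(sys$comp$segment_id == 2L), 10)
  expect_error(build_system(cyl, passive = p, max_compartments = 5),
               class = "ab_resource_error")
})

test_that("a quiescent passive membrane stays at its leak reversal", {
  cyl <- cylinder_morphology(length = 200, diameter = 1, soma_diameter = 10)
  sys <- build_system(cyl, rules = passive_density_rules())
  res <- run_simulation(sys, config = sim_config(duration = 200, onset = 0))
  expect_equal(max(abs(res$traces + 79)), 0, tolerance = 1e-9)
  expect_length(res$spike_times, 0)
  expect_equal(nrow(res$traces), 2001) # duration/dt + 1 samples
})

test_that("steady-state attenuation along a sealed cable matches cosh", {
  p <- passive_params()
  cyl <- cylinder_morphology(length = 500, diameter = 1, soma_diameter = 1e-3)
  sys <- build_system(cyl, passive = p, rules = passive_density_rules(),
                      lambda_fraction = 0.02)
  ic <- iclamp(2L, 0.05, 200, 1500, pos = 0.999)
  c_near <- comp_at(sys, 2L, 0.01)
  c_far <- comp_at(sys, 2L, 0.8)
  res <- run_simulation(sys, config = sim_config(duration = 1500, onset = 0),
                        iclamps = ic, record_comps = c(c_near, c_far))
  lam <- lambda_um(1, p)
  x1 <- sys$comp$path_distance[c_near]
  x2 <- sys$comp$path_distance[c_far]
  v1 <- utils::tail(res$traces[, "comp2"], 1) + 79
  v2 <- utils::tail(res$traces[, paste0("comp", c_far)], 1) + 79
  expect_equal(v2 / v1, cosh(x2 / lam) / cosh(x1 / lam), tolerance = 0.01)
})

test_that("passive sphere charging matches R_m C_m and R_m / area", {
  m <- small_cell()
  soma_only <- apicobasal:::new_morphology(m$segments[1, ], m$soma_area_um2)
  sys <- build_system(soma_only, rules = passive_density_rules())
  p <- passive_params()
  r_theory <- (1 / p$g_leak) / (m$soma_area_um2 * 1e-8) * 1e-6 # MOhm
  expect_equal(input_resistance(sys), r_theory, tolerance = 0.005)
  expect_equal(membrane_time_constant(sys), p$c_m / p$g_leak / 1e3,
               tolerance = 0.005)
})

test_that("somatic spike detection applies threshold and refractory rules", {
  t <- seq(0, 100, by = 0.1)
  expect_length(detect_somatic_spikes(rep(-79, length(t)), t), 0)
  v <- rep(-30, length(t)) +
    50 * exp(-(t - 20)^2) + 50 * exp(-(t - 50)^2) + 50 * exp(-(t - 80)^2)
  expect_length(detect_somatic_spikes(v, t, threshold = 0), 3)
  v2 <- rep(-70, length(t)) + 120 * exp(-(t - 40)^2 / 0.02) +
    120 * exp(-(t - 41)^2 / 0.02)
  expect_length(detect_somatic_spikes(v2, t, threshold = 0, refractory = 3), 1)
})

test_that("runs are reproducible and interventions with scale 1 are inert", {
  m <- small_cell()
  syn <- allocate_synapses(m, distribution_model(), n_total = 3000, seed = 8)
  sys <- build_system(m, synapses = syn)
  tr <- generate_spike_trains(syn, stimulus_config(theta_stim = 0), seed = 8)
  cfg <- sim_config(duration = 1500)
  r1 <- run_simulation(sys, tr, cfg)
  r2 <- run_simulation(sys, tr, cfg)
  expect_identical(r1$spike_times, r2$spike_times)
  expect_identical(r1$traces, r2$traces)
  null_ivn <- intervention_spec("apical", "g_Na", 1, 600, 900)
  r3 <- run_simulation(sys, tr, cfg, interventions = null_ivn)
  expect_identical(r1$traces, r3$traces)
  null_syn <- intervention_spec("basal", "stim_syn_weight", 1, 600, 900)
  r4 <- run_simulation(sys, tr, cfg, interventions = null_syn)
  expect_identical(r1$traces, r4$traces)
})

test_that("solutions converge under time-step and grid refinement", {
  m <- small_cell()
  # spiking configuration: strong paired-pulse drive onto one basal segment
  seg <- 2L
  syn <- tibble::tibble(synapse_id = 1L, site_id = 1L, segment_id = seg,
                        tree_label = "basal", pos = 0.5, kind = "AMPA",
                        role = "background", theta_pref = NA_real_,
                        weight_scale = 40, delay_ms = 0)
  sys <- build_system(m, synapses = syn)
  tr <- tibble::tibble(site_id = 1L, t_ms = c(100, 120))
  s1 <- run_simulation(sys, tr, sim_config(dt = 0.1, duration = 300, onset = 0))
  s2 <- run_simulation(sys, tr, sim_config(dt = 0.05, duration = 300, onset = 0))
  expect_equal(length(s1$spike_times), length(s2$spike_times))
  if (length(s1$spike_times)) {
    expect_lt(max(abs(s1$spike_times - s2$spike_times)), 0.1)
  }

  # grid refinement: steady somatic response to a distal current step
  p <- passive_params()
  cyl <- cylinder_morphology(length = 400, diameter = 1, soma_diameter = 10)
  resp <- vapply(c(0.1, 0.05), function(fr) {
    sysc <- build_system(cyl, passive = p, rules = passive_density_rules(),
                         lambda_fraction = fr)
    ic <- iclamp(2L, 0.02, 100, 900, pos = 0.95)
    rr <- run_simulation(sysc, config = sim_config(duration = 900, onset = 0),
                         iclamps = ic)
    utils::tail(rr$traces[, 1], 1)
  }, numeric(1))
  expect_equal(resp[1], resp[2], tolerance = 0.01)
})

test_that("non-finite states abort with a diagnostic", {
  cyl <- cylinder_morphology(length = 100, diameter = 1, soma_diameter = 10)
  sys <- build_system(cyl, rules = passive_density_rules())
  ic <- iclamp(1L, 1e30, 10, 900)
  expect_error(run_simulation(sys, config = sim_config(duration = 900,
                                                       onset = 0),
                              iclamps = ic),
               "numerical-state error")
})

test_that("tree-restricted density scaling leaves the other tree untouched", {
  m <- small_cell()
  sys <- build_system(m)
  blocked <- sodium_block(sys, "apical", scale = 0)
  ap <- blocked$comp$tree == 1L
  expect_true(all(blocked$gbar_mScm2[ap, "Na"] == 0))
  expect_identical(blocked$gbar_mScm2[!ap, ], sys$gbar_mScm2[!ap, ])
  expect_identical(sodium_block(sys, "basal", scale = 1)$gbar_mScm2,
                   sys$gbar_mScm2)
})
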