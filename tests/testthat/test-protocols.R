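m_cell <- small_cell()

test_that("current-based paired-pulse drive is exactly linear", {
  prof <- i3p(m_cell, 2L, n_values = c(1, 2, 4, 8), drive = "current",
              duration = 300)
  expect_equal(prof$table$actual_peak, prof$table$expected_peak,
               tolerance = 1e-6)
  expect_equal(prof$nrle, 1, tolerance = 1e-6)
})

test_that("sodium thresholds require sodium conductance", {
  passive_prof <- i3p(m_cell, 2L, n_values = c(1, seq(4, 24, 4)),
                      nmda_enabled = FALSE, rules = passive_density_rules(),
                      duration = 300, amp_min = 60)
  expect_true(is.na(passive_prof$sodium_threshold))

  active_prof <- i3p(m_cell, 2L, n_values = c(1, seq(4, 24, 4)),
                     nmda_enabled = TRUE, duration = 300)
  expect_false(is.na(active_prof$sodium_threshold))
  expect_false(is.na(active_prof$nmda_threshold))
  expect_gt(active_prof$nrle, 1) # regenerative jump above linear expectation
  expect_error(i3p(m_cell, 1L), class = "ab_lookup_error")
  expect_error(i3p(m_cell, 2L, n_values = 2:5), class = "ab_domain_error")
})

test_that("attenuation probes calibrate the local EPSP and grow with distance", {
  at_soma <- attenuation_probe(m_cell, 1L)
  expect_equal(at_soma$attenuation, 0, tolerance = 1e-9)
  # chain of three basal segments: attenuation increases along the cable
  chain <- cylinder_morphology(length = 450, diameter = 1, soma_diameter = 12,
                               n_segments = 3)
  probes <- dplyr::bind_rows(lapply(2:4, function(s)
    attenuation_probe(chain, s)))
  expect_true(all(probes$achieved))
  expect_true(all(abs(probes$local_peak - 20) <= 1))
  expect_true(all(diff(probes$attenuation) > 0))
})

test_that("tuning collapses without stimulus-driven drive", {
  tun <- tuning_experiment(m_cell, orientations = c(0, 45, 90), n_trials = 1,
                           seed = 5, rate_stim_peak = 0, duration = 1500)
  expect_true(!tun$fit$defined || tun$fit$osi < 0.2 ||
                max(tun$curve$mean_rate) < 0.5)
})

test_that("preference rotation shifts the preferred orientation", {
  orient <- seq(0, 150, by = 30)
  t0 <- tuning_experiment(m_cell, orientations = orient, n_trials = 2,
                          seed = 42)
  t60 <- tuning_experiment(m_cell, orientations = orient, n_trials = 2,
                           seed = 42, pref_rotation = 60)
  expect_true(t0$fit$defined && t60$fit$defined)
  shift <- (t60$fit$preferred - t0$fit$preferred) %% 180
  expect_lt(circ_orientation_diff(shift, 60), 35)
})

test_that("interventions replay exactly and partition baseline spikes", {
  syn <- allocate_synapses(m_cell, distribution_model(),
                           n_total = default_n_total(m_cell), seed = 31)
  sys <- build_system(m_cell, synapses = syn)
  tr <- generate_spike_trains(syn, stimulus_config(theta_stim = 0), seed = 31)
  cfg <- sim_config()
  base <- run_simulation(sys, tr, cfg)
  expect_gt(length(base$spike_times), 0)
  # replay determinism: an empty intervention list reproduces the baseline
  replay <- run_simulation(sys, tr, cfg, interventions = NULL)
  expect_identical(base$spike_times, replay$spike_times)

  ivn <- intervention_experiment(m_cell, kind = "ionic", n_trials = 1,
                                 seed = 31, max_spikes_per_trial = 6)
  expect_gt(ivn$n_spikes, 0)
  expect_equal(sort(as.character(unique(ivn$outcomes$label))),
               sort(as.character(unique(classify_spike(
                 ivn$outcomes$survived_apical, ivn$outcomes$survived_basal)))))
  expect_equal(sum(ivn$summary$mean_pct), 100, tolerance = 1e-9)

  # a scale-1 "intervention" leaves every spike independent
  null_ivn <- intervention_experiment(m_cell, kind = "ionic", scale = 1,
                                      n_trials = 1, seed = 31,
                                      max_spikes_per_trial = 4)
  expect_true(all(null_ivn$outcomes$label == "independent"))
})

test_that("whole-run sodium block agrees with a degenerate window", {
  syn <- allocate_synapses(m_cell, distribution_model(),
                           n_total = default_n_total(m_cell), seed = 13)
  sys <- build_system(m_cell, synapses = syn)
  tr <- generate_spike_trains(syn, stimulus_config(theta_stim = 0), seed = 13)
  cfg <- sim_config(duration = 1500)
  blocked <- run_simulation(sodium_block(sys, "apical", scale = 0), tr, cfg)
  windowed <- run_simulation(sys, tr, cfg,
                             interventions = intervention_spec(
                               "apical", "g_Na", 0, 0, 1500))
  expect_equal(blocked$spike_times, windowed$spike_times, tolerance = 1e-9)
})

test_that("disparity experiments report Euler expectations and adequacy", {
  disp <- disparity_experiment(m_cell, disparities = c(0, 40),
                               orientations = seq(0, 160, 40), n_trials = 1,
                               seed = 7, duration = 1500)
  expect_equal(nrow(disp), 2)
  expect_lt(circ_orientation_diff(disp$euler_pref[1], 0), 10)
  # with a 40 deg basal offset the linear expectation sits between the trees
  expect_gt(disp$euler_pref[2], 5)
  expect_lt(disp$euler_pref[2], 40)
  expect_true(all(c("adequate", "frac_inadequate") %in% names(disp)))
})
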