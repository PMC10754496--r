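test_that("double-exponential waveforms match their closed forms", {
  ampa <- synapse_kinetics("AMPA")
  tp <- syn_time_to_peak(ampa)
  expect_equal(tp, 0.1 * 2.5 / 2.4 * log(25), tolerance = 1e-12)
  expect_equal(tp, 0.335, tolerance = 1e-3)
  expect_equal(synaptic_conductance(ampa, tp), 0.84)
  expect_equal(synaptic_conductance(ampa, 0), 0)
  for (k in c("NMDA", "GABA_A")) {
    kin <- synapse_kinetics(k)
    expect_equal(synaptic_conductance(kin, syn_time_to_peak(kin)),
                 kin$g_max_nS)
  }
  # non-negative with a single interior maximum, and linear superposition
  t <- seq(0, 20, by = 0.01)
  g <- synaptic_conductance(ampa, t)
  expect_true(all(g >= 0))
  expect_equal(sum(diff(sign(diff(g))) != 0), 1)
  g2 <- synaptic_conductance(ampa, t) + synaptic_conductance(ampa, t - 3)
  expect_equal(g2, synaptic_conductance(ampa, t) +
                 ifelse(t > 3, synaptic_conductance(ampa, t - 3), 0))
})

test_that("the NMDA magnesium block opens with depolarisation", {
  expect_gt(nmda_mg_block(40), 0.95)
  expect_lt(nmda_mg_block(-80), 0.05)
  expect_true(all(diff(nmda_mg_block(seq(-90, 40, 5))) > 0))
  # near-full NMDA conductance when strongly depolarised, a small
  # fraction of it at rest
  nmda <- synapse_kinetics("NMDA")
  peak <- synaptic_conductance(nmda, syn_time_to_peak(nmda))
  expect_equal(peak * nmda_mg_block(40), 1.15, tolerance = 0.06)
  expect_lt(peak * nmda_mg_block(-80), 0.06)
})

test_that("synapse allocation follows the distribution model", {
  m <- small_cell()
  syn <- allocate_synapses(m, distribution_model("biologically_plausible"),
                           n_total = 100, bg_fraction = 0.75, seed = 11)
  sites <- syn[!duplicated(syn$site_id), ]
  stim <- sites[sites$role == "stimulus", ]
  expect_equal(nrow(stim), 25)
  expect_equal(sum(stim$tree_label == "basal"), 15)
  expect_equal(sum(stim$tree_label == "apical"), 10)
  # preferences defined iff stimulus-driven
  expect_true(all(!is.na(stim$theta_pref)))
  expect_true(all(is.na(sites$theta_pref[sites$role == "background"])))
  expect_true(all(stim$theta_pref >= 0 & stim$theta_pref < 180))
  # apical stimulus-driven synapses carry the 10 ms feedback delay
  expect_true(all(stim$delay_ms[stim$tree_label == "apical"] == 10))
  expect_true(all(stim$delay_ms[stim$tree_label == "basal"] == 0))
  expect_true(all(sites$delay_ms[sites$role == "background"] == 0))
  # excitatory sites are co-located AMPA+NMDA pairs
  exc <- syn[syn$kind %in% c("AMPA", "NMDA"), ]
  expect_true(all(table(exc$site_id) == 2))

  # even model: per-role tree counts differ by at most one
  syn_even <- allocate_synapses(m, distribution_model("even"),
                                n_total = 137, seed = 2)
  se <- syn_even[!duplicated(syn_even$site_id), ]
  for (r in c("stimulus", "background")) {
    tab <- table(se$tree_label[se$role == r & se$tree_label != "soma"])
    expect_lte(abs(tab[["basal"]] - tab[["apical"]]), 1)
  }

  # determinism contract
  again <- allocate_synapses(m, distribution_model(), n_total = 100, seed = 11)
  expect_identical(syn, again)
  other <- allocate_synapses(m, distribution_model(), n_total = 100, seed = 12)
  expect_false(identical(syn$segment_id, other$segment_id))

  expect_error(distribution_model("custom", basal_stim = 0.7,
                                  apical_stim = 0.7, basal_bg = 0.5,
                                  apical_bg = 0.5, basal_inhib = 0.5,
                                  apical_inhib = 0.4, soma_inhib = 0.1),
               class = "ab_config_error")
})

test_that("preference sampling wraps to orientation space", {
  expect_equal(sample_preferences(5, mean = 30, sigma = 0, seed = 1),
               rep(30, 5))
  x <- sample_preferences(10000, mean = 0, sigma = 30, seed = 4)
  expect_true(all(x >= 0 & x < 180))
  circ_mean <- (Arg(mean(exp(2i * pi * x / 180))) * 90 / pi) %% 180
  expect_true(circ_mean < 1 || circ_mean > 179)
  # rotation equivariance under the same seed
  y <- sample_preferences(1000, mean = 90, sigma = 20, seed = 9)
  y0 <- sample_preferences(1000, mean = 0, sigma = 20, seed = 9)
  expect_equal((y - 90) %% 180, y0 %% 180, tolerance = 1e-12)
})

test_that("tuned rates follow the circular Gaussian of preference mismatch", {
  cfg <- stimulus_config()
  expect_equal(tuned_rate(0, 0, cfg), 0.3)
  expect_lte(tuned_rate(90, 0, cfg), 0.3 * exp(-4.5) + 1e-12)
  expect_equal(tuned_rate(20, 50, cfg), tuned_rate(50, 20, cfg))
  # wrap-around: 170 vs 10 is 20 degrees apart
  expect_equal(tuned_rate(170, 10, cfg), tuned_rate(30, 10, cfg))
  expect_equal(tuned_rate(45, NA, cfg), 0)
})

test_that("Poisson trains are reproducible and have the nominal rate", {
  m <- small_cell()
  syn <- allocate_synapses(m, distribution_model(), n_total = 400, seed = 3)
  cfg <- stimulus_config(theta_stim = 0)
  tr1 <- generate_spike_trains(syn, cfg, duration = 2500, seed = 21)
  tr2 <- generate_spike_trains(syn, cfg, duration = 2500, seed = 21)
  expect_identical(tr1, tr2)
  expect_true(all(diff(tr1$t_ms) >= 0))
  expect_true(all(tr1$t_ms >= 0 & tr1$t_ms <= 2500))

  # background-only event count across many synapse-seconds: within 3 SD
  syn_bg <- syn[syn$role == "background" & syn$kind != "GABA_A", ]
  n_sites <- length(unique(syn_bg$site_id))
  lam <- n_sites * 0.11 * 2.5
  counts <- sum(generate_spike_trains(syn_bg, stimulus_config(theta_stim = NA),
                                      duration = 2500, seed = 5)$t_ms >= 0)
  expect_lt(abs(counts - lam), 3 * sqrt(lam) + 1)

  # rate estimator unbiased across seeds (2 SEM band)
  one <- syn[syn$site_id == syn$site_id[1] & syn$kind == "AMPA", ]
  one$role <- "background"
  ns <- vapply(1:1000, function(s)
    nrow(generate_spike_trains(one, cfg, duration = 10000, seed = s)),
    numeric(1))
  lam1 <- 0.11 * 10
  expect_lt(abs(mean(ns) - lam1), 2 * sd(ns) / sqrt(length(ns)))
})
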