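#' Synaptic kinetics
#'
#' Double-exponential conductance kinetics for the three synapse types.
#' Peak conductances and rise/decay time constants: NMDA 1.15 nS (2, 30 ms),
#' AMPA 0.84 nS (0.1, 2.5 ms), GABA_A 1.25 nS (0.2, 1.4 ms). Excitatory
#' reversal 0 mV, inhibitory -80 mV. The NMDA conductance is additionally
#' multiplied by the voltage-dependent magnesium block [nmda_mg_block()].
#'
#' @param kind Optionally restrict to one of `"AMPA"`, `"NMDA"`, `"GABA_A"`.
#' @return A tibble with columns `kind`, `g_max_nS`, `tau1`, `tau2`,
#'   `reversal`.
#' @export
synapse_kinetics <- function(kind = NULL) {
  tab <- tibble(
    kind = c("AMPA", "NMDA", "GABA_A"),
    g_max_nS = c(0.84, 1.15, 1.25),
    tau1 = c(0.1, 2, 0.2),
    tau2 = c(2.5, 30, 1.4),
    reversal = c(0, 0, -80))
  if (!is.null(kind)) tab <- tab[tab$kind %in% kind, , drop = FALSE]
  tab
}

#' Double-exponential synaptic conductance waveform
#'
#' g(t) = g_max N (exp(-t/tau2) - exp(-t/tau1)), with N chosen so the peak
#' equals g_max. The waveform peaks at t_p = tau1 tau2 / (tau2 - tau1)
#' log(tau2/tau1) and superposes linearly across events.
#'
#' @param kinetics A one-row tibble as returned by [synapse_kinetics()].
#' @param t_since_event Time since the presynaptic event, ms (vectorised).
#' @return Conductance in nS (0 at t = 0 and for t < 0).
#' @examples
#' ampa <- synapse_kinetics("AMPA")
#' tp <- syn_time_to_peak(ampa) # 0.335 ms
#' synaptic_conductance(ampa, tp) # 0.84 nS
#' @export
synaptic_conductance <- function(kinetics, t_since_event) {
  tau1 <- kinetics$tau1[1]; tau2 <- kinetics$tau2[1]
  stopifnot(tau2 > tau1, tau1 > 0)
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  norm <- 1 / (exp(-tp / tau2) - exp(-tp / tau1))
  g <- kinetics$g_max_nS[1] * norm *
    (exp(-t_since_event / tau2) - exp(-t_since_event / tau1))
  ifelse(t_since_event <= 0, 0, g)
}

#' @rdname synaptic_conductance
#' @export
syn_time_to_peak <- function(kinetics) {
  tau1 <- kinetics$tau1[1]; tau2 <- kinetics$tau2[1]
  tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
}

#' NMDA magnesium block factor
#'
#' Standard sigmoidal voltage dependence of the NMDA receptor conductance
#' under extracellular magnesium: 1 / (1 + ([Mg]/3.57) exp(-0.062 V)).
#'
#' @param v Membrane potential, mV.
#' @param mg Magnesium concentration, mM (default 1).
#' @return Unblocked fraction in (0, 1).
#' @export
nmda_mg_block <- function(v, mg = 1) {
  1 / (1 + (mg / 3.57) * exp(-0.062 * v))
}

#' Orientation arithmetic
#'
#' Orientations live on a 180-degree circle. `circ_orientation_diff()`
#' returns the absolute circular orientation difference (always in
#' `[0, 90]`).
#'
#' @param a,b Orientations in degrees.
#' @return Difference in degrees.
#' @export
circ_orientation_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Synaptic distribution models
#'
#' Named allocation profiles for stimulus-driven excitation, background
#' excitation, and background inhibition across the two dendritic trees.
#' `biologically_plausible` places 60% of both stimulus- and
#' background-driven synapses on the basal tree (40% apical), the split
#' reported for feedforward-dominated L2/3 input; `inverted` swaps the trees;
#' `even` splits 50/50. `control_background` is the biologically plausible
#' model under its original background distribution, and `even_background`
#' keeps the 60/40 stimulus split but distributes background synapses evenly
#' (excitatory 50/50; inhibitory 46.5/46.5 with a 7% somatic share).
#'
#' @param name One of `"biologically_plausible"`, `"even"`, `"inverted"`,
#'   `"control_background"`, `"even_background"`, or `"custom"` with the
#'   fraction arguments supplied.
#' @param basal_stim,apical_stim Stimulus-driven excitatory fractions.
#' @param basal_bg,apical_bg Background excitatory fractions.
#' @param basal_inhib,apical_inhib,soma_inhib Background inhibitory
#'   fractions (these three must sum to 1).
#' @return An `ab_distribution_model` (named list of fractions).
#' @export
distribution_model <- function(name = "biologically_plausible",
                               basal_stim = NULL, apical_stim = NULL,
                               basal_bg = NULL, apical_bg = NULL,
                               basal_inhib = NULL, apical_inhib = NULL,
                               soma_inhib = NULL) {
  presets <- list(
    biologically_plausible = list(c(.6, .4), c(.6, .4), c(.558, .372, .07)),
    control_background     = list(c(.6, .4), c(.6, .4), c(.558, .372, .07)),
    inverted               = list(c(.4, .6), c(.4, .6), c(.372, .558, .07)),
    even                   = list(c(.5, .5), c(.5, .5), c(.465, .465, .07)),
    even_background        = list(c(.6, .4), c(.5, .5), c(.465, .465, .07)))
  if (name == "custom") {
    p <- list(c(basal_stim, apical_stim), c(basal_bg, apical_bg),
              c(basal_inhib, apical_inhib, soma_inhib))
  } else {
    if (!name %in% names(presets)) {
      abort(paste0("unknown distribution model '", name, "'"),
            class = "ab_config_error")
    }
    p <- presets[[name]]
  }
  if (abs(sum(p[[1]]) - 1) > 1e-9 || abs(sum(p[[2]]) - 1) > 1e-9 ||
      abs(sum(p[[3]]) - 1) > 1e-9) {
    abort("distribution fractions must sum to 1 within each category",
          class = "ab_config_error")
  }
  structure(list(name = name,
                 stim = setNames(p[[1]], c("basal", "apical")),
                 bg = setNames(p[[2]], c("basal", "apical")),
                 inhib = setNames(p[[3]], c("basal", "apical", "soma"))),
            class = "ab_distribution_model")
}

#' Stimulus configuration
#'
#' Firing-rate parameters for the Poisson synaptic drive. Background-driven
#' synapses fire at `rate_background` throughout the run; stimulus-driven
#' synapses are silent before `onset` and thereafter fire at a rate that
#' falls off as a Gaussian of the circular orientation difference between
#' their preference and the stimulus, peaking at `rate_stim_peak`.
#'
#' @param theta_stim Stimulus orientation in degrees, or `NA` for a
#'   spontaneous (no-stimulus) run.
#' @param onset Stimulus onset, ms.
#' @param rate_stim_peak Peak stimulus-driven rate, Hz.
#' @param rate_background Background rate, Hz.
#' @param tuning_sigma_rate Rate-tuning width, degrees.
#' @return An `ab_stimulus_config`.
#' @export
stimulus_config <- function(theta_stim = 0, onset = 500,
                            rate_stim_peak = 0.3, rate_background = 0.11,
                            tuning_sigma_rate = 30) {
  if (rate_stim_peak < 0 || rate_background < 0) {
    abort("rates must be non-negative", class = "ab_config_error")
  }
  structure(list(theta_stim = theta_stim, onset = onset,
                 rate_stim_peak = rate_stim_peak,
                 rate_background = rate_background,
                 tuning_sigma_rate = tuning_sigma_rate),
            class = "ab_stimulus_config")
}

#' Orientation-tuned firing rate
#'
#' rate = rate_stim_peak exp(-D^2 / (2 sigma^2)) with D the circular
#' orientation difference between synapse preference and stimulus. Returns 0
#' when no stimulus is presented.
#'
#' @param theta_pref Synaptic orientation preference, degrees (vectorised).
#' @param theta_stim Stimulus orientation, degrees, or `NA`.
#' @param cfg An [stimulus_config()].
#' @return Rate in Hz.
#' @export
tuned_rate <- function(theta_pref, theta_stim, cfg = stimulus_config()) {
  if (is.na(theta_stim)) return(rep(0, length(theta_pref)))
  d <- circ_orientation_diff(theta_pref, theta_stim)
  cfg$rate_stim_peak * exp(-d^2 / (2 * cfg$tuning_sigma_rate^2))
}

#' Sample orientation preferences
#'
#' Draws from a Gaussian with the given mean and sigma, wrapped to the
#' orientation half-circle `[0, 180)`.
#'
#' @param n Number of draws.
#' @param mean Mean orientation, degrees.
#' @param sigma Standard deviation, degrees (>= 0).
#' @param seed Optional integer seed.
#' @return Angles in `[0, 180)`.
#' @export
sample_preferences <- function(n, mean = 0, sigma = 30, seed = NULL) {
  if (sigma < 0) abort("sigma must be non-negative", class = "ab_domain_error")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  (mean + rnorm(n, 0, sigma)) %% 180
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

largest_remainder <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(fracs))
}

#' Allocate synapses across the dendritic trees
#'
#' Places `n_total` synaptic sites on a morphology according to a
#' [distribution_model()]. Sites split into background (`bg_fraction`,
#' default 75%) and stimulus-driven; a fraction of background sites
#' (`inhib_fraction`) is inhibitory (GABA_A), allocated by the model's
#' inhibitory fractions including the somatic share. Counts per (tree, role)
#' follow largest-remainder rounding of the model fractions; within a tree,
#' locations are uniform per unit dendritic length. Each excitatory site
#' carries a co-located AMPA + NMDA pair sharing one presynaptic train, so
#' the returned table has two rows per excitatory site (same `site_id`).
#' Stimulus-driven sites receive an orientation preference drawn from a
#' wrapped Gaussian (apical mean `pref_mean_apical`, basal mean
#' `pref_mean_basal` -- unequal means implement dendritic disparity), and
#' apical stimulus-driven sites carry a 10 ms transmission delay (feedback
#' input arrives late).
#'
#' @param m An `ab_morphology`.
#' @param model An [distribution_model()].
#' @param n_total Total number of synaptic sites (>= 1).
#' @param bg_fraction Fraction of sites that are background-driven.
#' @param inhib_fraction Fraction of background sites that are inhibitory.
#' @param pref_mean_apical,pref_mean_basal Mean orientation preference per
#'   tree, degrees.
#' @param pref_sigma Preference sampling sigma, degrees.
#' @param apical_stim_delay Transmission delay for apical stimulus-driven
#'   sites, ms.
#' @param seed Integer seed; identical seeds give identical placements.
#' @return A tibble with one row per synapse (`synapse_id`, `site_id`,
#'   `segment_id`, `tree_label`, `pos` along the segment in `[0, 1]`,
#'   `kind`, `role`, `theta_pref`, `weight_scale`, `delay_ms`).
#' @export
allocate_synapses <- function(m, model = distribution_model(),
                              n_total, bg_fraction = 0.75,
                              inhib_fraction = 0.25,
                              pref_mean_apical = 0, pref_mean_basal = 0,
                              pref_sigma = 30, apical_stim_delay = 10,
                              seed = 1) {
  stopifnot(n_total >= 1)
  segs <- m$segments[m$segments$tree_label != "soma", , drop = FALSE]
  for (tr in c("apical", "basal")) {
    if (!any(segs$tree_label == tr)) {
      abort(paste0("morphology has no ", tr, " tree"),
            class = "ab_structure_error")
    }
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  n_stim <- round((1 - bg_fraction) * n_total)
  n_bg <- n_total - n_stim
  n_inhib <- round(inhib_fraction * n_bg)
  n_bg_exc <- n_bg - n_inhib

  stim_counts <- largest_remainder(n_stim, model$stim)
  bg_counts <- largest_remainder(n_bg_exc, model$bg)
  inhib_counts <- largest_remainder(n_inhib, model$inhib)

  place <- function(n, tree) {
    if (n == 0) return(tibble(segment_id = integer(), pos = numeric()))
    if (tree == "soma") {
      return(tibble(segment_id = rep(1L, n), pos = rep(0.5, n)))
    }
    ss <- segs[segs$tree_label == tree, , drop = FALSE]
    pick <- sample(nrow(ss), n, replace = TRUE, prob = ss$length)
    tibble(segment_id = ss$segment_id[pick], pos = runif(n))
  }

  rows <- list()
  add <- function(n, tree, role, kind_set) {
    if (n == 0) return()
    loc <- place(n, tree)
    pref <- if (role == "stimulus") {
      mu <- if (tree == "apical") pref_mean_apical else pref_mean_basal
      (mu + rnorm(n, 0, pref_sigma)) %% 180
    } else rep(NA_real_, n)
    delay <- if (role == "stimulus" && tree == "apical") apical_stim_delay else 0
    rows[[length(rows) + 1]] <<- tibble(
      site = seq_len(n), segment_id = loc$segment_id, tree_label = tree,
      pos = loc$pos, role = role, theta_pref = pref, delay_ms = delay,
      kinds = list(kind_set))
  }
  add(stim_counts[["basal"]], "basal", "stimulus", c("AMPA", "NMDA"))
  add(stim_counts[["apical"]], "apical", "stimulus", c("AMPA", "NMDA"))
  add(bg_counts[["basal"]], "basal", "background", c("AMPA", "NMDA"))
  add(bg_counts[["apical"]], "apical", "background", c("AMPA", "NMDA"))
  add(inhib_counts[["basal"]], "basal", "background", "GABA_A")
  add(inhib_counts[["apical"]], "apical", "background", "GABA_A")
  add(inhib_counts[["soma"]], "soma", "background", "GABA_A")

  sites <- bind_rows(rows)
  sites$site_id <- seq_len(nrow(sites))
  out <- tidyr::unnest(
    mutate(sites, kind = .data$kinds, kinds = NULL, site = NULL),
    "kind")
  out$synapse_id <- seq_len(nrow(out))
  out$weight_scale <- 1
  out[, c("synapse_id", "site_id", "segment_id", "tree_label", "pos",
          "kind", "role", "theta_pref", "weight_scale", "delay_ms")]
}

#' Generate Poisson presynaptic event trains
#'
#' Homogeneous Poisson trains per synaptic site: background sites fire at the
#' background rate over the whole run; stimulus-driven sites fire at their
#' [tuned_rate()] from stimulus onset onward. Each site draws from an
#' independent substream derived from the master seed, so trains are
#' reproducible site-by-site. Transmission delays are added to delivery
#' times; events delivered after `duration` are dropped.
#'
#' @param synapses Synapse table from [allocate_synapses()].
#' @param cfg An [stimulus_config()].
#' @param duration Run duration, ms.
#' @param seed Master integer seed.
#' @return A tibble of events (`site_id`, `t_ms`), sorted by time.
#' @export
generate_spike_trains <- function(synapses, cfg = stimulus_config(),
                                  duration = 2500, seed = 1) {
  stopifnot(duration > 0)
  sites <- synapses[!duplicated(synapses$site_id), , drop = FALSE]
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    if (s$role == "background") {
      rate <- cfg$rate_background; t0 <- 0; t1 <- duration
    } else {
      rate <- tuned_rate(s$theta_pref, cfg$theta_stim, cfg)
      t0 <- cfg$onset; t1 <- duration
    }
    if (rate <= 0 || t1 <= t0) next
    set.seed((seed * 1000003 + s$site_id) %% 2147483647)
    nev <- rpois(1, rate * (t1 - t0) / 1000)
    if (nev == 0) next
    tt <- sort(runif(nev, t0, t1)) + s$delay_ms
    tt <- tt[tt <= duration]
    if (length(tt)) out[[i]] <- tibble(site_id = s$site_id, t_ms = tt)
  }
  ev <- bind_rows(out)
  if (!nrow(ev)) return(tibble(site_id = integer(), t_ms = numeric()))
  arrange(ev, .data$t_ms)
}
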