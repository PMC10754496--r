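#' Iterative paired-pulse protocol (dendritic input-output curve)
#'
#' Profiles the nonlinearity of a single dendritic segment: for each synapse
#' count n, n synapses placed at the segment midpoint are activated
#' synchronously by two volleys 20 ms apart (50 Hz pair), while every other
#' compartment (soma included) is passive. The local peak depolarisation to
#' the first volley gives the actual input-output curve; the linear
#' expectation is n times the unitary response. The sodium phase drives AMPA
#' only (NMDA disabled) and locates the sodium-spike threshold with the
#' slope-and-amplitude criterion of [detect_dendritic_spike()]; the NMDA
#' phase adds the NMDA conductance, disables the target segment's sodium
#' channels (isolating the NMDA regenerativity from the much faster sodium
#' spike), and locates the plateau threshold with an amplitude-and-duration
#' criterion. NRLE is computed from the sodium-phase curve.
#'
#' @param m An `ab_morphology`.
#' @param segment_id Target dendritic segment.
#' @param n_values Synapse counts to test (must start at 1).
#' @param nmda_enabled Run the NMDA phase as well.
#' @param drive `"conductance"` for synaptic drive; `"current"` replaces the
#'   synapses with equivalent current pulses on a fully passive cell -- the
#'   linearity control, for which actual equals expected exactly.
#' @param passive,rules,ions Model parameters.
#' @param onset First volley time, ms.
#' @param pulse_interval Volley separation, ms (20 ms = 50 Hz).
#' @param duration Simulation window, ms.
#' @param slope_min,amp_min Sodium-spike criterion (mV/ms, mV).
#' @param nmda_halfwidth_ms NMDA plateau duration gate, ms.
#' @return An `ab_i3p`: per-n table (`n`, `actual_peak`, `expected_peak`,
#'   plus the NMDA-phase peaks when enabled), `sodium_threshold`,
#'   `nmda_threshold` (NA when not reached or not run), `nrle`, and the
#'   detection criterion echo. Supports [autoplot()].
#' @export
i3p <- function(m, segment_id, n_values = 1:200, nmda_enabled = TRUE,
                drive = c("conductance", "current"),
                passive = passive_params(), rules = default_density_rules(),
                ions = ion_params(), onset = 100, pulse_interval = 20,
                duration = 700, slope_min = 10, amp_min = 20,
                nmda_halfwidth_ms = 10) {
  drive <- match.arg(drive)
  if (length(n_values) < 1 || n_values[1] != 1) {
    abort("n_values must start at 1 (the unitary response anchors the curve)",
          class = "ab_domain_error")
  }
  segs <- m$segments
  if (!segment_id %in% segs$segment_id || segment_id == 1L) {
    abort(paste0("segment ", segment_id, " is not a dendritic segment"),
          class = "ab_lookup_error")
  }
  cfg <- sim_config(dt = 0.1, duration = duration, onset = 0,
                    record_segments = segment_id)
  t_volley <- c(onset, onset + pulse_interval)

  run_phase <- function(kinds) {
    if (drive == "current") {
      sys <- build_system(m, passive, passive_density_rules(), ions = ions)
      peaks <- vapply(n_values, function(n) {
        ic <- bind_rows(
          iclamp(segment_id, n * 0.01, t_volley[1], t_volley[1] + 1),
          iclamp(segment_id, n * 0.01, t_volley[2], t_volley[2] + 1))
        res <- run_simulation(sys, config = cfg, iclamps = ic)
        local_peak(res, segment_id, t_volley[1], pulse_interval)$peak
      }, numeric(1))
      return(list(peaks = peaks, detected = rep(FALSE, length(n_values))))
    }
    seg_tree <- segs$tree_label[match(segment_id, segs$segment_id)]
    syn <- tibble(synapse_id = seq_along(kinds), site_id = 1L,
                  segment_id = segment_id, tree_label = seg_tree,
                  pos = 0.5, kind = kinds, role = "background",
                  theta_pref = NA_real_, weight_scale = 1, delay_ms = 0)
    nmda_phase <- "NMDA" %in% kinds
    phase_rules <- rules
    if (nmda_phase) { # NMDA phase: target sodium disabled
      phase_rules$Na <- function(region, x, d) 0
      attr(phase_rules, "sim_scale") <- attr(rules, "sim_scale")
    }
    sys <- build_system(m, passive, phase_rules, synapses = syn, ions = ions,
                        active_segments = segment_id)
    trains <- tibble(site_id = 1L, t_ms = t_volley)
    peaks <- numeric(length(n_values))
    detected <- logical(length(n_values))
    for (i in seq_along(n_values)) {
      sys$synapses$weight_scale <- n_values[i]
      res <- run_simulation(sys, trains, cfg)
      lp <- local_peak(res, segment_id, t_volley[1], pulse_interval)
      peaks[i] <- lp$peak
      det <- detect_dendritic_spike(
        lp$v, lp$t, baseline = lp$baseline,
        slope_min = if (nmda_phase) NA else slope_min,
        amp_min = amp_min,
        min_halfwidth_ms = if (nmda_phase) nmda_halfwidth_ms else NULL)
      detected[i] <- det$detected
    }
    list(peaks = peaks, detected = detected)
  }

  na_phase <- run_phase("AMPA")
  threshold_of <- function(phase) {
    hit <- which(phase$detected)
    if (length(hit)) n_values[hit[1]] else NA_integer_
  }
  tab <- tibble(n = n_values, actual_peak = na_phase$peaks,
                expected_peak = n_values * na_phase$peaks[1])
  nmda_thr <- NA_integer_
  if (nmda_enabled && drive == "conductance") {
    nmda_phase <- run_phase(c("AMPA", "NMDA"))
    tab$actual_peak_nmda <- nmda_phase$peaks
    nmda_thr <- threshold_of(nmda_phase)
  }
  structure(list(
    segment_id = segment_id, table = tab,
    sodium_threshold = if (drive == "current") NA_integer_
                       else threshold_of(na_phase),
    nmda_threshold = nmda_thr,
    nrle = nrle(na_phase$peaks, n_values),
    criterion = list(slope_min = slope_min, amp_min = amp_min,
                     nmda_halfwidth_ms = nmda_halfwidth_ms, drive = drive)),
    class = "ab_i3p")
}

local_peak <- function(res, segment_id, t0, window) {
  col <- paste0("seg", segment_id)
  sel <- res$time >= t0 & res$time < t0 + window
  v <- res$traces[, col]
  baseline <- v[max(1, which(res$time >= t0)[1] - 1)]
  list(peak = max(v[sel]) - baseline, v = v[sel], t = res$time[sel],
       baseline = baseline)
}

#' @export
print.ab_i3p <- function(x, ...) {
  cat("<ab_i3p> segment ", x$segment_id,
      ": sodium threshold ", ifelse(is.na(x$sodium_threshold), "not reached",
                                    x$sodium_threshold),
      ", NMDA threshold ", ifelse(is.na(x$nmda_threshold), "not reached",
                                  x$nmda_threshold),
      ", NRLE ", round(x$nrle, 3), "\n", sep = "")
  invisible(x)
}

default_n_total <- function(m, density_per_um = 4.8) {
  s <- m$segments
  round(density_per_um * sum(s$length[s$tree_label != "soma"]))
}

# allocate + build for one model instantiation ("neuron")
model_instance <- function(m, model, alloc_seed, n_total = NULL,
                           disparity = 0, pref_sigma = 30, pref_rotation = 0,
                           bg_fraction = 0.75, inhib_fraction = 0.25,
                           passive = passive_params(),
                           rules = default_density_rules(),
                           ions = ion_params(), lambda_fraction = 0.1) {
  if (is.null(n_total)) n_total <- default_n_total(m)
  syn <- allocate_synapses(m, model, n_total = n_total,
                           bg_fraction = bg_fraction,
                           inhib_fraction = inhib_fraction,
                           pref_mean_apical = pref_rotation,
                           pref_mean_basal = pref_rotation + disparity,
                           pref_sigma = pref_sigma, seed = alloc_seed)
  sys <- build_system(m, passive, rules, synapses = syn, ions = ions,
                      lambda_fraction = lambda_fraction)
  list(syn = syn, sys = sys, n_total = n_total)
}

#' Orientation tuning experiment
#'
#' Runs the full model for every (orientation, trial) pair and derives the
#' orientation tuning curve. Each trial is an independent instantiation of
#' the neuron (fresh synapse placements and orientation preferences from the
#' trial seed); within a trial the instantiation is fixed and only the
#' Poisson event trains vary across orientations. Firing rate is the somatic
#' spike count between stimulus onset and the end of the run over that
#' window.
#'
#' @param m An `ab_morphology`.
#' @param model An [distribution_model()].
#' @param orientations Stimulus orientations, degrees.
#' @param n_trials Trials (independent neurons) per orientation.
#' @param seed Master seed.
#' @param n_total Total synaptic sites (default: ~1.5 per um of dendrite).
#' @param disparity Basal-tree mean preference relative to apical, degrees.
#' @param pref_rotation Global rotation added to both trees' preference
#'   means, degrees (the tuning curve is equivariant under it).
#' @param pref_sigma Preference sampling sigma, degrees.
#' @param duration,onset Run window, ms.
#' @param rate_stim_peak,rate_background,tuning_sigma_rate Drive rates
#'   (see [stimulus_config()]).
#' @param synapse_filter Optional function applied to each trial's synapse
#'   table before simulation (e.g. to remove one tree's stimulus input).
#' @param build_morphology Optional morphology the compartmental system is
#'   built on when it differs from the one synapses are allocated on (the
#'   ablation experiment allocates on the intact cell, simulates the
#'   ablated one).
#' @param ... Passed to `model_instance` (passive/rules/ions overrides).
#' @return An `ab_tuning`: `curve` (orientation, mean_rate, sem_rate,
#'   n_trials), `trials` (per-trial rates), `fit` (wrapped-Gaussian fit of
#'   the mean curve), `per_trial_metrics`, and a config echo. Supports
#'   [autoplot()], [tidy()], [glance()].
#' @export
tuning_experiment <- function(m, model = distribution_model(),
                              orientations = seq(0, 170, by = 10),
                              n_trials = 10, seed = 1, n_total = NULL,
                              disparity = 0, pref_rotation = 0,
                              pref_sigma = 30,
                              duration = 2500, onset = 500,
                              rate_stim_peak = 0.3, rate_background = 0.11,
                              tuning_sigma_rate = 30,
                              synapse_filter = NULL,
                              build_morphology = NULL, ...) {
  stopifnot(length(orientations) >= 2)
  cfg <- sim_config(duration = duration, onset = onset)
  rows <- list()
  prefs_by_trial <- list()
  for (trial in seq_len(n_trials)) {
    alloc_seed <- (seed + 7919L * trial) %% 2147483647L
    inst <- model_instance(m, model, alloc_seed, n_total = n_total,
                           disparity = disparity,
                           pref_rotation = pref_rotation,
                           pref_sigma = pref_sigma, ...)
    syn <- inst$syn
    sys <- inst$sys
    if (!is.null(synapse_filter) || !is.null(build_morphology)) {
      if (!is.null(synapse_filter)) syn <- synapse_filter(syn)
      sys <- build_system(if (is.null(build_morphology)) m
                          else build_morphology,
                          sys$passive, sys$rules, synapses = syn,
                          ions = sys$ions)
    }
    prefs_by_trial[[trial]] <-
      syn$theta_pref[syn$role == "stimulus" & !duplicated(syn$site_id)]
    for (k in seq_along(orientations)) {
      scfg <- stimulus_config(theta_stim = orientations[k], onset = onset,
                              rate_stim_peak = rate_stim_peak,
                              rate_background = rate_background,
                              tuning_sigma_rate = tuning_sigma_rate)
      trains <- generate_spike_trains(
        syn, scfg, duration = duration,
        seed = (alloc_seed + 104729L * k) %% 2147483647L)
      res <- run_simulation(sys, trains, cfg)
      nsp <- sum(res$spike_times >= onset & res$spike_times <= duration)
      rows[[length(rows) + 1]] <- tibble(
        orientation = orientations[k], trial = trial,
        rate = nsp / (duration - onset) * 1000)
    }
  }
  trials <- bind_rows(rows)
  curve <- summarise(group_by(trials, .data$orientation),
                     mean_rate = mean(.data$rate),
                     sem_rate = sd(.data$rate) / sqrt(n()),
                     n_trials = n(), .groups = "drop")
  fit <- fit_tuning_curve(curve)
  per_trial <- bind_rows(lapply(split(trials, trials$trial), function(df) {
    tm <- tuning_metrics(tibble(orientation = df$orientation,
                                mean_rate = df$rate))
    tm$trial <- df$trial[1]
    tm
  }))
  structure(list(curve = curve, trials = trials, fit = fit,
                 per_trial_metrics = per_trial,
                 stim_preferences = prefs_by_trial,
                 config_echo = list(model = unclass(model),
                                    orientations = orientations,
                                    n_trials = n_trials, seed = seed,
                                    disparity = disparity,
                                    pref_sigma = pref_sigma,
                                    rate_stim_peak = rate_stim_peak,
                                    rate_background = rate_background,
                                    tuning_sigma_rate = tuning_sigma_rate,
                                    duration = duration, onset = onset)),
            class = "ab_tuning")
}

#' @export
print.ab_tuning <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' @export
tidy.ab_tuning <- function(x, ...) x$curve

#' @export
glance.ab_tuning <- function(x, ...) glance(x$fit)

#' Remove one tree's stimulus-driven input
#'
#' Synapse-table filter for the input-removal experiment: drops
#' stimulus-driven synapses on the named tree.
#'
#' @param tree `"apical"` or `"basal"`.
#' @return A function suitable for `tuning_experiment(synapse_filter = )`.
#' @export
remove_stimulus_input <- function(tree) {
  force(tree)
  function(syn) syn[!(syn$role == "stimulus" & syn$tree_label == tree), ,
                    drop = FALSE]
}

#' Dendritic disparity experiment
#'
#' Apical-tree preferences keep mean 0 deg while the basal-tree mean is set
#' to each disparity D. For each D the tuning experiment is run, the
#' measured preferred orientation compared against the linear
#' (Euler-formula) expectation computed from the actually sampled synaptic
#' preferences, and the configuration flagged inadequate when 20% or more of
#' the trial neurons fail the tuning criteria (OSI >= 0.2 and width <=
#' 80 deg).
#'
#' @inheritParams tuning_experiment
#' @param disparities Basal mean preferences, degrees.
#' @return A tibble: per disparity the measured preference, Euler-expected
#'   preference, OSI, width, fraction of inadequate trials and the adequacy
#'   flag. The full `ab_tuning` objects are attached as the `"tunings"`
#'   attribute.
#' @export
disparity_experiment <- function(m, model = distribution_model(),
                                 disparities = seq(0, 90, by = 10),
                                 orientations = seq(0, 170, by = 10),
                                 n_trials = 10, seed = 1, ...) {
  out <- list(); tunings <- list()
  for (D in disparities) {
    tun <- tuning_experiment(m, model, orientations = orientations,
                             n_trials = n_trials, seed = seed,
                             disparity = D, ...)
    eulers <- vapply(tun$stim_preferences, function(p) {
      e <- expected_preference_euler(p)
      if (e$defined) e$preferred else NA_real_
    }, numeric(1))
    # circular mean of per-trial expectations on doubled angles
    z <- mean(exp(2i * pi / 180 * eulers[!is.na(eulers)]))
    euler_pref <- (Arg(z) * 90 / pi) %% 180
    pm <- tun$per_trial_metrics
    bad <- mean(!pm$defined | pm$osi < 0.2 | pm$width > 80)
    out[[length(out) + 1]] <- tibble(
      disparity = D, measured_pref = tun$fit$preferred,
      euler_pref = euler_pref, osi = tun$fit$osi, width = tun$fit$width,
      frac_inadequate = bad, adequate = bad < 0.2)
    tunings[[as.character(D)]] <- tun
  }
  res <- bind_rows(out)
  attr(res, "tunings") <- tunings
  res
}

#' Just-in-time intervention experiment with per-spike attribution
#'
#' For every somatic spike of a baseline run, the identical event train is
#' replayed twice: once with the apical-tree intervention and once with the
#' basal-tree intervention, each windowed around the pre-recorded spike
#' time. Ionic interventions nullify the tree's sodium conductance from 3 ms
#' before to 1 ms after the spike; synaptic interventions halve the tree's
#' stimulus-driven AMPA/NMDA weights from 30 ms before to 10 ms after. A
#' spike survives when the re-run still fires within +/- 5 ms of the
#' baseline time; the two survival flags classify each spike via
#' [classify_spike()]. Percentages are per-trial percentages averaged across
#' trials with their SEM.
#'
#' @inheritParams tuning_experiment
#' @param kind `"ionic"` (sodium nullification) or `"synaptic"` (AMPA/NMDA
#'   weight halving).
#' @param theta_stim Stimulus orientation, degrees (0 = preferred).
#' @param window_pre,window_post,scale Override the intervention window
#'   (ms) and scale; defaults follow `kind`.
#' @param match_window_ms Survival matching half-window, ms.
#' @param max_spikes_per_trial Cap on baseline spikes processed per trial
#'   (the first spikes of the run), to bound runtime on busy cells.
#' @param apical_gna_scale Whole-run scaling of the apical sodium density
#'   applied before everything else (sensitivity analysis).
#' @return An `ab_intervention`: `outcomes` (one row per baseline spike with
#'   survival flags and label), `summary` (per class: mean and SEM of the
#'   per-trial percentages), `n_spikes`.
#' @export
intervention_experiment <- function(m, model = distribution_model(),
                                    kind = c("ionic", "synaptic"),
                                    theta_stim = 0, n_trials = 3, seed = 1,
                                    n_total = NULL, duration = 2500,
                                    onset = 500, window_pre = NULL,
                                    window_post = NULL, scale = NULL,
                                    match_window_ms = 5,
                                    max_spikes_per_trial = Inf,
                                    apical_gna_scale = 1, ...) {
  kind <- match.arg(kind)
  par <- if (kind == "ionic") list(pre = 3, post = 1, sc = 0, param = "g_Na")
         else list(pre = 30, post = 10, sc = 0.5, param = "stim_syn_weight")
  if (!is.null(window_pre)) par$pre <- window_pre
  if (!is.null(window_post)) par$post <- window_post
  if (!is.null(scale)) par$sc <- scale
  cfg <- sim_config(duration = duration, onset = onset)
  outcomes <- list()
  for (trial in seq_len(n_trials)) {
    alloc_seed <- (seed + 7919L * trial) %% 2147483647L
    inst <- model_instance(m, model, alloc_seed, n_total = n_total, ...)
    sys <- inst$sys
    if (apical_gna_scale != 1) {
      sys <- sodium_block(sys, "apical", scale = apical_gna_scale)
    }
    scfg <- stimulus_config(theta_stim = theta_stim, onset = onset)
    trains <- generate_spike_trains(inst$syn, scfg, duration = duration,
                                    seed = (alloc_seed + 104729L) %% 2147483647L)
    base <- run_simulation(sys, trains, cfg)
    sp <- base$spike_times
    if (is.finite(max_spikes_per_trial) && length(sp) > max_spikes_per_trial) {
      sp <- sp[seq_len(max_spikes_per_trial)]
    }
    if (!length(sp)) {
      warning("trial ", trial, ": baseline run produced no somatic spikes")
      next
    }
    for (t_sp in sp) {
      surv <- vapply(c("apical", "basal"), function(tr) {
        ivn <- intervention_spec(tr, par$param, par$sc,
                                 t_sp - par$pre, t_sp + par$post)
        cfg2 <- cfg
        cfg2$duration <- min(duration,
                             ceiling((t_sp + par$post + match_window_ms + 1) /
                                       cfg$dt) * cfg$dt)
        res <- run_simulation(sys, trains, cfg2, interventions = ivn)
        any(abs(res$spike_times - t_sp) <= match_window_ms)
      }, logical(1))
      outcomes[[length(outcomes) + 1]] <- tibble(
        trial = trial, spike_time = t_sp,
        survived_apical = surv[["apical"]],
        survived_basal = surv[["basal"]])
    }
  }
  outcomes <- bind_rows(outcomes)
  if (!nrow(outcomes)) {
    return(structure(list(outcomes = outcomes, summary = tibble(),
                          n_spikes = 0L, kind = kind),
                     class = "ab_intervention"))
  }
  outcomes$label <- classify_spike(outcomes$survived_apical,
                                   outcomes$survived_basal)
  per_trial <- lapply(split(outcomes, outcomes$trial), function(df) {
    100 * table(df$label) / nrow(df)
  })
  pct <- do.call(rbind, per_trial)
  summ <- tibble(label = colnames(pct),
                 mean_pct = colMeans(pct),
                 sem_pct = apply(pct, 2, sd) / sqrt(nrow(pct)))
  structure(list(outcomes = outcomes, summary = summ,
                 n_spikes = nrow(outcomes), kind = kind,
                 params = par),
            class = "ab_intervention")
}

#' @export
print.ab_intervention <- function(x, ...) {
  cat("<ab_intervention> ", x$kind, ", ", x$n_spikes, " baseline spikes\n",
      sep = "")
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' @export
tidy.ab_intervention <- function(x, ...) x$summary

#' EPSP and spike attenuation probe
#'
#' Drives one dendritic segment and measures how much of the local
#' depolarisation survives at the soma. In `"epsp"` mode the membrane is
#' passive and the synaptic weight is calibrated by bisection until the
#' local peak reaches `target_mv` within `tol_mv` (default a 20 +/- 1 mV
#' local EPSP); in `"spike"` mode the target segment keeps its active
#' conductances and is driven past its sodium-spike threshold. Attenuation
#' is the difference of peaks (local minus somatic), in mV.
#'
#' @param m An `ab_morphology`.
#' @param segment_id Target segment (1 = the soma itself, attenuation 0).
#' @param mode `"epsp"` or `"spike"`.
#' @param target_mv Target local peak for `"epsp"` mode, mV.
#' @param tol_mv Calibration tolerance, mV.
#' @param n_drive Synapse count for `"spike"` mode (default: 2x the
#'   segment's sodium threshold found by a coarse sweep).
#' @param passive,rules,ions Model parameters.
#' @param max_weight Calibration upper bound (flagged unreachable beyond).
#' @return A one-row tibble: `segment_id`, `mode`, `local_peak`,
#'   `somatic_peak`, `attenuation`, `weight`, `achieved`.
#' @export
attenuation_probe <- function(m, segment_id, mode = c("epsp", "spike"),
                              target_mv = 20, tol_mv = 1, n_drive = NULL,
                              passive = passive_params(),
                              rules = default_density_rules(),
                              ions = ion_params(), max_weight = 5000) {
  mode <- match.arg(mode)
  cfg <- sim_config(dt = 0.1, duration = 300, onset = 0,
                    record_segments = if (segment_id == 1L) integer()
                                      else segment_id)
  measure <- function(sys, w) {
    sys$synapses$weight_scale <- w
    res <- run_simulation(sys, tibble(site_id = 1L, t_ms = 100), cfg)
    col <- if (segment_id == 1L) "seg1" else paste0("seg", segment_id)
    i0 <- which(res$time >= 100)[1] - 1
    soma <- res$traces[, "seg1"]
    loc <- res$traces[, col]
    list(local = max(loc[-seq_len(i0)]) - loc[i0],
         soma = max(soma[-seq_len(i0)]) - soma[i0])
  }
  syn_kinds <- if (mode == "epsp") "AMPA" else c("AMPA", "NMDA")
  seg_tree <- m$segments$tree_label[m$segments$segment_id == segment_id]
  syn <- tibble(synapse_id = seq_along(syn_kinds), site_id = 1L,
                segment_id = segment_id, tree_label = seg_tree, pos = 0.5,
                kind = syn_kinds, role = "background",
                theta_pref = NA_real_, weight_scale = 1, delay_ms = 0)
  if (mode == "epsp") {
    sys <- build_system(m, passive, passive_density_rules(), synapses = syn,
                        ions = ions)
    lo <- 0; hi <- 1
    p_hi <- measure(sys, hi)
    while (p_hi$local < target_mv && hi < max_weight) {
      lo <- hi; hi <- hi * 2
      p_hi <- measure(sys, hi)
    }
    if (p_hi$local < target_mv - tol_mv) {
      return(tibble(segment_id = segment_id, mode = mode,
                    local_peak = p_hi$local, somatic_peak = p_hi$soma,
                    attenuation = p_hi$local - p_hi$soma, weight = hi,
                    achieved = FALSE))
    }
    p <- p_hi; w <- hi
    for (it in 1:40) {
      if (abs(p$local - target_mv) <= tol_mv) break
      mid <- (lo + hi) / 2
      p_mid <- measure(sys, mid)
      if (p_mid$local < target_mv) lo <- mid else hi <- mid
      p <- p_mid; w <- mid
    }
    return(tibble(segment_id = segment_id, mode = mode, local_peak = p$local,
                  somatic_peak = p$soma, attenuation = p$local - p$soma,
                  weight = w, achieved = abs(p$local - target_mv) <= tol_mv))
  }
  # spike mode: active target segment, drive past sodium threshold
  if (segment_id == 1L) {
    abort("spike attenuation needs a dendritic segment", class = "ab_lookup_error")
  }
  if (is.null(n_drive)) {
    prof <- i3p(m, segment_id, n_values = c(1, seq(5, 120, by = 5)),
                nmda_enabled = FALSE, passive = passive, rules = rules,
                ions = ions)
    n_drive <- if (is.na(prof$sodium_threshold)) 120
               else 2 * prof$sodium_threshold
  }
  sys <- build_system(m, passive, rules, synapses = syn, ions = ions,
                      active_segments = segment_id)
  p <- measure(sys, n_drive)
  tibble(segment_id = segment_id, mode = mode, local_peak = p$local,
         somatic_peak = p$soma, attenuation = p$local - p$soma,
         weight = n_drive, achieved = TRUE)
}

#' Per-dendrite nonlinearity and attenuation profiles
#'
#' Runs the paired-pulse protocol and the attenuation probes over every
#' dendritic segment and joins the results onto the morphometrics table,
#' yielding the per-segment profile used by the morphometry-matched
#' comparisons ([matched_compare()]).
#'
#' @param m An `ab_morphology`.
#' @param n_values Synapse counts for the paired-pulse sweep.
#' @param spike_attenuation Also run the (slower) spike-attenuation probe.
#' @param ... Passed to [i3p()] and [attenuation_probe()].
#' @return A tibble, one row per dendritic segment: morphometrics plus
#'   `sodium_threshold`, `nmda_threshold`, `nrle`, `attenuation_epsp` and
#'   optionally `attenuation_spike`.
#' @export
dendrite_profiles <- function(m, n_values = c(1, seq(2, 80, by = 2)),
                              spike_attenuation = FALSE, ...) {
  mm <- morphometrics(m)
  rows <- lapply(mm$segment_id, function(sid) {
    prof <- i3p(m, sid, n_values = n_values, nmda_enabled = TRUE, ...)
    att <- attenuation_probe(m, sid, mode = "epsp", ...)
    out <- tibble(segment_id = sid,
                  sodium_threshold = prof$sodium_threshold,
                  nmda_threshold = prof$nmda_threshold,
                  nrle = prof$nrle,
                  attenuation_epsp = att$attenuation)
    if (spike_attenuation) {
      n_dr <- if (is.na(prof$sodium_threshold)) NULL
              else 2 * prof$sodium_threshold
      atts <- attenuation_probe(m, sid, mode = "spike", n_drive = n_dr, ...)
      out$attenuation_spike <- atts$attenuation
    }
    out
  })
  left_join(mm, bind_rows(rows), by = "segment_id")
}

#' Apical tree ablation experiment
#'
#' Removes the apical tree (compartments and synapses) and asks whether
#' somatic orientation tuning persists. Without homeostasis the remaining
#' drive is weaker and the preferred-orientation rate drops; with
#' `homeostatic = TRUE` a uniform scaling of the remaining excitatory
#' synaptic weights is auto-tuned (bisection) until the mean
#' preferred-orientation rate matches the intact cell within `rate_tol`,
#' emulating the homeostatic compensation that accompanies ablation in vivo.
#'
#' @inheritParams tuning_experiment
#' @param homeostatic Tune a compensatory excitatory weight scaling.
#' @param rate_tol Relative tolerance for the rate match.
#' @param orientations Orientations for the post-ablation tuning curve.
#' @return A list: intact and ablated preferred-orientation rates, the
#'   fitted homeostatic `weight_factor`, the post-ablation `ab_tuning`, and
#'   pre/post passive input resistances (MOhm).
#' @export
ablation_experiment <- function(m, model = distribution_model(),
                                orientations = seq(0, 170, by = 10),
                                n_trials = 2, seed = 1, n_total = NULL,
                                duration = 2500, onset = 500,
                                homeostatic = TRUE, rate_tol = 0.1, ...) {
  m2 <- ablate_apical_tree(m)
  cfg <- sim_config(duration = duration, onset = onset)
  drop_apical <- function(syn) syn[syn$tree_label != "apical", , drop = FALSE]

  pref_rate <- function(use_ablated, weight_factor) {
    rates <- vapply(seq_len(n_trials), function(trial) {
      alloc_seed <- (seed + 7919L * trial) %% 2147483647L
      inst <- model_instance(m, model, alloc_seed, n_total = n_total, ...)
      syn <- inst$syn
      if (use_ablated) {
        syn <- drop_apical(syn)
        syn$weight_scale[syn$kind %in% c("AMPA", "NMDA")] <- weight_factor
        sys <- build_system(m2, inst$sys$passive, inst$sys$rules,
                            synapses = syn, ions = inst$sys$ions)
      } else sys <- inst$sys
      trains <- generate_spike_trains(
        syn, stimulus_config(theta_stim = 0, onset = onset),
        duration = duration, seed = (alloc_seed + 104729L) %% 2147483647L)
      res <- run_simulation(sys, trains, cfg)
      sum(res$spike_times >= onset) / (duration - onset) * 1000
    }, numeric(1))
    mean(rates)
  }

  rate_intact <- pref_rate(FALSE, 1)
  rate_raw <- pref_rate(TRUE, 1)
  wf <- 1
  rate_homeo <- rate_raw
  if (homeostatic && rate_intact > 0) {
    lo <- 1; hi <- 1
    r_hi <- rate_raw
    while (r_hi < rate_intact && hi < 64) {
      lo <- hi; hi <- hi * 2
      r_hi <- pref_rate(TRUE, hi)
    }
    wf <- hi; rate_homeo <- r_hi
    for (it in 1:12) {
      if (abs(rate_homeo - rate_intact) <= rate_tol * rate_intact) break
      mid <- (lo + hi) / 2
      r_mid <- pref_rate(TRUE, mid)
      if (r_mid < rate_intact) lo <- mid else hi <- mid
      wf <- mid; rate_homeo <- r_mid
    }
  }

  tun <- tuning_experiment(
    m, model, orientations = orientations, n_trials = n_trials,
    seed = seed, n_total = n_total, duration = duration, onset = onset,
    build_morphology = m2,
    synapse_filter = function(syn) {
      syn <- drop_apical(syn)
      syn$weight_scale[syn$kind %in% c("AMPA", "NMDA")] <- wf
      syn
    }, ...)

  ir_pre <- input_resistance(build_system(m, rules = passive_density_rules()))
  ir_post <- input_resistance(build_system(m2, rules = passive_density_rules()))
  list(rate_intact = rate_intact, rate_ablated_raw = rate_raw,
       weight_factor = wf, rate_ablated_homeo = rate_homeo,
       tuning_ablated = tun, ir_intact = ir_pre, ir_ablated = ir_post)
}

#' Apical sodium conductance sensitivity sweep
#'
#' Re-runs the stimulated model with the apical sodium density scaled by
#' each factor and reports the somatic spike count (and optionally the
#' per-spike attribution classes) per scale. Spike counts are non-increasing
#' as the apical sodium conductance is reduced.
#'
#' @inheritParams intervention_experiment
#' @param scales Apical sodium density multipliers.
#' @param classes Also run the ionic intervention classification per scale.
#' @return A tibble: per scale the total spike count across trials, and
#'   when `classes = TRUE` the mean class percentages.
#' @export
sensitivity_sweep <- function(m, model = distribution_model(),
                              scales = c(1, 0.95, 0.90), theta_stim = 0,
                              n_trials = 2, seed = 1, n_total = NULL,
                              duration = 2500, onset = 500,
                              classes = FALSE,
                              max_spikes_per_trial = 20, ...) {
  rows <- list()
  for (sc in scales) {
    if (classes) {
      ivn <- intervention_experiment(
        m, model, kind = "ionic", theta_stim = theta_stim,
        n_trials = n_trials, seed = seed, n_total = n_total,
        duration = duration, onset = onset,
        max_spikes_per_trial = max_spikes_per_trial,
        apical_gna_scale = sc, ...)
      row <- tibble(scale = sc, n_spikes = ivn$n_spikes)
      for (lab in levels(ivn$outcomes$label)) {
        row[[paste0("pct_", lab)]] <-
          if (nrow(ivn$summary)) ivn$summary$mean_pct[ivn$summary$label == lab]
          else NA_real_
      }
    } else {
      nsp <- 0L
      cfg <- sim_config(duration = duration, onset = onset)
      for (trial in seq_len(n_trials)) {
        alloc_seed <- (seed + 7919L * trial) %% 2147483647L
        inst <- model_instance(m, model, alloc_seed, n_total = n_total, ...)
        sys <- sodium_block(inst$sys, "apical", scale = sc)
        trains <- generate_spike_trains(
          inst$syn, stimulus_config(theta_stim = theta_stim, onset = onset),
          duration = duration, seed = (alloc_seed + 104729L) %% 2147483647L)
        res <- run_simulation(sys, trains, cfg)
        nsp <- nsp + length(res$spike_times)
      }
      row <- tibble(scale = sc, n_spikes = nsp)
    }
    rows[[length(rows) + 1]] <- row
  }
  bind_rows(rows)
}
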