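#' Simulation configuration
#'
#' @param dt Integration / recording time step, ms (default 0.1, i.e. 10 kHz
#'   sampling; internal steps smaller than 0.1 ms are resampled to 10 kHz).
#' @param duration Run duration, ms.
#' @param onset Stimulus onset, ms (recorded for provenance; the drive
#'   generator owns the actual onset).
#' @param record_segments Segment ids to record (midpoint compartment), in
#'   addition to the soma, which is always recorded first.
#' @param v_init Initial voltage, mV (default: leak reversal).
#' @param spike_threshold Somatic spike detection threshold, mV.
#' @param refractory Spike detection refractory period, ms.
#' @param record_dt Recording interval, ms (defaults to 0.1 ms regardless of
#'   `dt`).
#' @return An `ab_sim_config`.
#' @export
sim_config <- function(dt = 0.1, duration = 2500, onset = 500,
                       record_segments = integer(), v_init = NULL,
                       spike_threshold = 0, refractory = 3,
                       record_dt = 0.1) {
  if (dt <= 0) abort("dt must be positive", class = "ab_config_error")
  if (duration < onset) {
    abort("duration must be at least the stimulus onset", class = "ab_config_error")
  }
  structure(list(dt = dt, duration = duration, onset = onset,
                 record_segments = record_segments, v_init = v_init,
                 spike_threshold = spike_threshold, refractory = refractory,
                 record_dt = record_dt),
            class = "ab_sim_config")
}

#' Time-windowed parameter intervention
#'
#' Scales a parameter on all compartments of one dendritic tree inside a
#' closed time window `[window_start, window_end]`, restoring it outside.
#' `scale = 0` on `g_Na` nullifies the tree's sodium conductance ("ionic"
#' intervention); `scale = 0.5` on `stim_syn_weight` halves the tree's
#' stimulus-driven AMPA/NMDA conductances ("synaptic" intervention). Gating
#' states keep evolving; only the conductance magnitude is scaled.
#'
#' @param target_tree `"apical"` or `"basal"`.
#' @param target_parameter `"g_Na"` or `"stim_syn_weight"`.
#' @param scale Multiplier (>= 0) applied inside the window.
#' @param window_start,window_end Window bounds, ms (`start < end`).
#' @return A one-row tibble.
#' @export
intervention_spec <- function(target_tree, target_parameter, scale,
                              window_start, window_end) {
  target_tree <- match.arg(target_tree, c("apical", "basal"))
  target_parameter <- match.arg(target_parameter, c("g_Na", "stim_syn_weight"))
  if (scale < 0) abort("scale must be >= 0", class = "ab_config_error")
  if (window_start >= window_end) {
    abort("window_start must be before window_end", class = "ab_config_error")
  }
  tibble(target_tree = target_tree, target_parameter = target_parameter,
         scale = scale, window_start = window_start, window_end = window_end)
}

#' Current clamp
#'
#' @param segment_id Segment to inject into (1 = soma).
#' @param amp_nA Amplitude, nA.
#' @param start,end Active window, ms.
#' @param pos Position along the segment in `[0, 1]`.
#' @return A one-row tibble.
#' @export
iclamp <- function(segment_id, amp_nA, start, end, pos = 0.5) {
  tibble(segment_id = segment_id, amp_nA = amp_nA, start = start, end = end,
         pos = pos)
}

tree_code <- function(tree_label) {
  unname(c(soma = 0L, apical = 1L, basal = 2L)[tree_label])
}

#' Build a compartmental system from a morphology
#'
#' Discretises each dendritic segment into compartments no longer than
#' `lambda_fraction` of the local passive length constant, evaluates the
#' channel density rules at each compartment's midpoint path distance and
#' diameter, and binds synapses to their compartments. The soma is a single
#' isopotential compartment (equivalent-area sphere).
#'
#' @param m An `ab_morphology`.
#' @param passive A [passive_params()] object.
#' @param rules An [default_density_rules()] rule set (use
#'   [passive_density_rules()] for a passive membrane).
#' @param synapses Optional synapse table from [allocate_synapses()].
#' @param ions An [ion_params()] object.
#' @param lambda_fraction Maximum compartment length as a fraction of the
#'   local lambda.
#' @param max_compartments Guard against accidental blow-ups.
#' @param active_segments Optional vector of segment ids that keep their
#'   active conductances; all other compartments are made passive (used by
#'   the paired-pulse and attenuation protocols).
#' @return An `ab_system`.
#' @export
build_system <- function(m, passive = passive_params(),
                         rules = default_density_rules(), synapses = NULL,
                         ions = ion_params(), lambda_fraction = 0.1,
                         max_compartments = 20000, active_segments = NULL) {
  validate_morphology(m, require_both_trees = FALSE)
  s <- m$segments
  soma_area_cm2 <- m$soma_area_um2 * 1e-8

  comp <- list()
  # soma compartment
  soma_gbar <- vapply(ab_channels, function(ch)
    conductance_at(rules, ch, region = "soma", x = 0, d = s$diameter[1]),
    numeric(1))
  comp[[1]] <- tibble(segment_id = 1L, tree = 0L, sub = 1L,
                      length_um = s$length[1], diameter_um = s$diameter[1],
                      area_cm2 = soma_area_cm2, path_distance = 0,
                      parent0 = -1L, r_half_Mohm = 0)
  seg_first_comp <- c(`1` = 1L)
  seg_last_comp <- c(`1` = 1L)
  seg_nseg <- c(`1` = 1L)
  gbar_rows <- list(soma_gbar)

  for (i in seq_len(nrow(s))[-1]) {
    L <- s$length[i]; d <- s$diameter[i]
    lam <- lambda_um(d, passive)
    n <- max(1L, ceiling(L / (lambda_fraction * lam)))
    Lc <- L / n
    start_dist <- s$path_distance[i] - L / 2
    active <- is.null(active_segments) || s$segment_id[i] %in% active_segments
    gb <- if (active) {
      function(x) vapply(ab_channels, function(ch)
        conductance_at(rules, ch, region = s$tree_label[i], x = x, d = d),
        numeric(1))
    } else {
      function(x) setNames(numeric(length(ab_channels)), ab_channels)
    }
    # half-cylinder axial resistance, MOhm
    r_half <- passive$r_a * (Lc / 2 * 1e-4) / (pi * (d / 2 * 1e-4)^2) * 1e-6
    first_idx <- length(comp) + 1L
    for (k in seq_len(n)) {
      xmid <- start_dist + (k - 0.5) * Lc
      parent0 <- if (k == 1) {
        seg_last_comp[[as.character(s$parent_id[i])]] - 1L
      } else {
        length(comp) - 1L
      }
      comp[[length(comp) + 1L]] <- tibble(
        segment_id = s$segment_id[i], tree = tree_code(s$tree_label[i]),
        sub = k, length_um = Lc, diameter_um = d,
        area_cm2 = pi * d * Lc * 1e-8, path_distance = xmid,
        parent0 = as.integer(parent0), r_half_Mohm = r_half)
      gbar_rows[[length(gbar_rows) + 1L]] <- gb(xmid)
    }
    key <- as.character(s$segment_id[i])
    seg_first_comp[key] <- first_idx
    seg_last_comp[key] <- length(comp)
    seg_nseg[key] <- n
    if (length(comp) > max_compartments) {
      abort(paste0("discretization exceeds ", max_compartments,
                   " compartments; increase lambda_fraction or raise the limit"),
            class = "ab_resource_error")
    }
  }
  comp <- bind_rows(comp)
  gbar <- do.call(rbind, gbar_rows) # mS/cm^2

  # axial coupling conductance to parent, uS: 1/(Rhalf_child + Rhalf_parent)
  g_ax <- numeric(nrow(comp))
  for (i in seq_len(nrow(comp))[-1]) {
    rp <- comp$r_half_Mohm[comp$parent0[i] + 1L]
    g_ax[i] <- 1 / (comp$r_half_Mohm[i] + rp) # 1/MOhm = uS
  }

  syn <- NULL
  if (!is.null(synapses) && nrow(synapses)) {
    kin <- synapse_kinetics()
    syn <- left_join(synapses, kin, by = "kind")
    cidx <- integer(nrow(syn))
    for (j in seq_len(nrow(syn))) {
      key <- as.character(syn$segment_id[j])
      n <- seg_nseg[[key]]
      k <- min(n, floor(syn$pos[j] * n) + 1L)
      cidx[j] <- seg_first_comp[[key]] + k - 1L
    }
    syn$comp <- cidx
  }

  structure(list(
    comp = comp, parent0 = comp$parent0, g_ax_uS = g_ax,
    gbar_mScm2 = gbar, passive = passive, ions = ions, rules = rules,
    synapses = syn, morphology = m,
    seg_mid_comp = vapply(as.character(s$segment_id), function(key) {
      as.integer(seg_first_comp[[key]] + ceiling(seg_nseg[[key]] / 2) - 1L)
    }, integer(1))),
    class = "ab_system")
}

#' @export
print.ab_system <- function(x, ...) {
  cat("<ab_system> ", nrow(x$comp), " compartments, ",
      if (is.null(x$synapses)) 0 else nrow(x$synapses), " synapses\n", sep = "")
  invisible(x)
}

#' Scale a channel density on one tree for the whole run
#'
#' Used for whole-run sodium blockage and the conductance sensitivity
#' analysis: multiplies the named channel's density on every compartment of
#' the target tree. The other tree's densities are untouched.
#'
#' @param system An `ab_system`.
#' @param tree `"apical"`, `"basal"`, or `"soma"`.
#' @param channel One of `ab_channels` (default `"Na"`).
#' @param scale Multiplier (0 blocks the channel).
#' @return The modified `ab_system`.
#' @export
sodium_block <- function(system, tree, channel = "Na", scale = 0) {
  code <- tree_code(match.arg(tree, c("apical", "basal", "soma")))
  rows <- system$comp$tree == code
  system$gbar_mScm2[rows, channel] <- system$gbar_mScm2[rows, channel] * scale
  system
}

#' Run a simulation
#'
#' Integrates the branched cable with active membranes and synaptic events
#' using an unconditionally stable implicit (backward-Euler) step; the tree
#' linear system is solved exactly each step and gating variables advance by
#' their exact exponential updates. Results are bit-reproducible for
#' identical inputs.
#'
#' @param system An `ab_system` from [build_system()].
#' @param trains Event table from [generate_spike_trains()] (site_id, t_ms),
#'   or `NULL` for no synaptic input.
#' @param config An [sim_config()].
#' @param interventions A tibble of [intervention_spec()] rows, or `NULL`.
#' @param iclamps A tibble of [iclamp()] rows, or `NULL`.
#' @param record_comps Optional extra compartment indices (rows of
#'   `system$comp`, see [comp_at()]) to record, appended after the segment
#'   midpoint sites as columns `comp<i>`.
#' @return An `ab_sim_result`: `time` (ms), `traces` (matrix, one column per
#'   recorded site, soma first), `spike_times` (ms, somatic), `config_echo`.
#' @export
run_simulation <- function(system, trains = NULL, config = sim_config(),
                           interventions = NULL, iclamps = NULL,
                           record_comps = integer()) {
  comp <- system$comp
  passive <- system$passive
  ions <- system$ions
  v_init <- if (is.null(config$v_init)) passive$e_leak else config$v_init

  area <- comp$area_cm2
  cm_nF <- passive$c_m * area * 1e3
  g_pas_uS <- passive$g_leak * area * 1e6
  # per-channel unit interpretation (see default_sim_scale), then
  # mS/cm^2 * cm^2 -> mS -> x1e3 uS
  sim_scale <- attr(system$rules, "sim_scale")
  if (is.null(sim_scale)) sim_scale <- setNames(rep(1, length(ab_channels)), ab_channels)
  gbar_uS <- sweep(system$gbar_mScm2, 2, sim_scale[colnames(system$gbar_mScm2)], `*`) *
    area * 1e3

  syn <- system$synapses
  if (is.null(syn)) syn <- tibble()
  have_syn <- nrow(syn) > 0
  if (have_syn && !is.null(trains) && nrow(trains)) {
    ev <- left_join(trains, syn[, c("synapse_id", "site_id", "comp",
                                    "weight_scale")],
                    by = "site_id", relationship = "many-to-many")
    ev <- arrange(ev, .data$t_ms)
    syn_index <- setNames(seq_len(nrow(syn)), syn$synapse_id)
    evt_time <- ev$t_ms
    evt_syn <- unname(syn_index[as.character(ev$synapse_id)]) - 1L
    evt_w <- ev$weight_scale
  } else {
    evt_time <- numeric(); evt_syn <- integer(); evt_w <- numeric()
  }

  if (is.null(interventions) || !nrow(interventions)) {
    ivn_tree <- integer(); ivn_param <- integer()
    ivn_scale <- numeric(); ivn_t0 <- numeric(); ivn_t1 <- numeric()
  } else {
    if (any(interventions$window_end > config$duration) ||
        any(interventions$window_start < 0)) {
      # windows anchored near run edges are clipped to the run
      interventions$window_start <- pmax(0, interventions$window_start)
      interventions$window_end <- pmin(config$duration, interventions$window_end)
    }
    ivn_tree <- tree_code(interventions$target_tree)
    ivn_param <- ifelse(interventions$target_parameter == "g_Na", 0L, 1L)
    ivn_scale <- interventions$scale
    ivn_t0 <- interventions$window_start
    ivn_t1 <- interventions$window_end
  }

  if (is.null(iclamps) || !nrow(iclamps)) {
    ic_comp <- integer(); ic_amp <- numeric(); ic_start <- numeric()
    ic_end <- numeric()
  } else {
    ic_comp <- vapply(seq_len(nrow(iclamps)), function(j) {
      comp_at(system, iclamps$segment_id[j], iclamps$pos[j]) - 1L
    }, integer(1))
    ic_amp <- iclamps$amp_nA; ic_start <- iclamps$start; ic_end <- iclamps$end
  }

  rec_segments <- unique(c(1L, config$record_segments))
  rec_idx <- c(vapply(rec_segments, function(sid) {
    system$seg_mid_comp[[as.character(sid)]]
  }, integer(1)), as.integer(record_comps))
  record_every <- max(1L, as.integer(round(config$record_dt / config$dt)))

  res <- cpp_run(
    parent = comp$parent0, cm_nF = cm_nF, g_ax_uS = system$g_ax_uS,
    g_pas_uS = g_pas_uS, e_pas = passive$e_leak,
    gbar_uS = as.matrix(gbar_uS), tree = comp$tree, area_cm2 = area,
    e_na = ions$e_na, e_k = ions$e_k, e_ca = ions$e_ca,
    ca_depth_um = ions$ca_depth, ca_taur_ms = ions$ca_tau,
    ca_inf_mM = ions$ca_inf, mg_mM = ions$mg,
    syn_comp = if (have_syn) syn$comp - 1L else integer(),
    syn_kind = if (have_syn) match(syn$kind, c("AMPA", "NMDA", "GABA_A")) - 1L
               else integer(),
    syn_role = if (have_syn) as.integer(syn$role == "stimulus") else integer(),
    syn_gmax_uS = if (have_syn) syn$g_max_nS * 1e-3 else numeric(),
    syn_tau1 = if (have_syn) syn$tau1 else numeric(),
    syn_tau2 = if (have_syn) syn$tau2 else numeric(),
    syn_e = if (have_syn) syn$reversal else numeric(),
    evt_time = evt_time, evt_syn = evt_syn, evt_w = evt_w,
    ic_comp = ic_comp, ic_amp_nA = ic_amp, ic_start = ic_start,
    ic_end = ic_end,
    ivn_tree = ivn_tree, ivn_param = ivn_param, ivn_scale = ivn_scale,
    ivn_t0 = ivn_t0, ivn_t1 = ivn_t1,
    dt = config$dt, duration = config$duration, v_init = v_init,
    record_idx = rec_idx - 1L, record_every = record_every)

  traces <- res$traces
  colnames(traces) <- c(paste0("seg", rec_segments),
                        if (length(record_comps)) paste0("comp", record_comps))
  spikes <- detect_somatic_spikes(traces[, 1], res$time,
                                  threshold = config$spike_threshold,
                                  refractory = config$refractory)
  structure(list(time = res$time, traces = traces, spike_times = spikes,
                 record_segments = rec_segments,
                 config_echo = list(config = unclass(config),
                                    passive = unclass(passive),
                                    ions = unclass(ions),
                                    n_compartments = nrow(comp),
                                    n_synapses = nrow(syn),
                                    n_events = length(evt_time),
                                    interventions = interventions)),
            class = "ab_sim_result")
}

#' @export
print.ab_sim_result <- function(x, ...) {
  cat("<ab_sim_result> ", round(max(x$time)), " ms, ",
      length(x$spike_times), " somatic spikes\n", sep = "")
  invisible(x)
}

#' Compartment index at a position along a segment
#'
#' @param system An `ab_system`.
#' @param segment_id Segment id.
#' @param pos Position along the segment in `[0, 1]`.
#' @return The row index into `system$comp`.
#' @export
comp_at <- function(system, segment_id, pos = 0.5) {
  rows <- which(system$comp$segment_id == segment_id)
  if (!length(rows)) {
    abort(paste0("segment ", segment_id, " not found"),
          class = "ab_lookup_error")
  }
  rows[min(length(rows), floor(pos * length(rows)) + 1L)]
}

#' Detect somatic spikes in a voltage trace
#'
#' Upward crossings of `threshold` separated by at least `refractory` ms;
#' crossing times are refined by linear interpolation between samples.
#'
#' @param v Voltage samples, mV.
#' @param time Sample times, ms (uniform).
#' @param threshold Crossing threshold, mV.
#' @param refractory Minimum spacing, ms.
#' @return Spike times, ms.
#' @export
detect_somatic_spikes <- function(v, time, threshold = 0, refractory = 3) {
  above <- v >= threshold
  up <- which(!above[-length(above)] & above[-1])
  if (!length(up)) return(numeric())
  frac <- (threshold - v[up]) / (v[up + 1] - v[up])
  tt <- time[up] + frac * (time[up + 1] - time[up])
  keep <- numeric()
  last <- -Inf
  for (t in tt) {
    if (t - last >= refractory) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep
}

#' Passive electrophysiological probes
#'
#' `input_resistance()` injects a somatic current step and reports the
#' steady-state voltage deflection over the injected current, in MOhm.
#' `membrane_time_constant()` fits a single exponential to the charging
#' transient.
#'
#' @param system An `ab_system`.
#' @param amp_nA Step amplitude, nA (hyperpolarising by default).
#' @param settle Pre-step settling time, ms.
#' @param step_dur Step duration, ms.
#' @param dt Time step, ms.
#' @return Resistance in MOhm / time constant in ms.
#' @export
input_resistance <- function(system, amp_nA = -0.04, settle = 500,
                             step_dur = 600, dt = 0.1) {
  cfg <- sim_config(dt = dt, duration = settle + step_dur, onset = 0)
  ic <- iclamp(1L, amp_nA, settle, settle + step_dur)
  res <- run_simulation(system, config = cfg, iclamps = ic)
  v <- res$traces[, 1]
  v0 <- v[max(which(res$time < settle))] # last sample before the step
  v1 <- tail(v, 1)
  (v1 - v0) / amp_nA # mV / nA = MOhm
}

#' @rdname input_resistance
#' @export
membrane_time_constant <- function(system, amp_nA = -0.04, settle = 500,
                                   step_dur = 600, dt = 0.1) {
  cfg <- sim_config(dt = dt, duration = settle + step_dur, onset = 0)
  ic <- iclamp(1L, amp_nA, settle, settle + step_dur)
  res <- run_simulation(system, config = cfg, iclamps = ic)
  sel <- res$time > settle & res$time <= settle + step_dur
  t <- res$time[sel] - settle
  v <- res$traces[sel, 1]
  v_inf <- tail(v, 1)
  y <- (v - v_inf) / (v[1] - v_inf)
  pos <- y > 1e-4
  fit <- stats::lm(log(y[pos]) ~ t[pos] - 1)
  -1 / unname(stats::coef(fit)[1])
}
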