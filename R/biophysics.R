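#' Membrane channel set
#'
#' The model carries seven voltage- (and calcium-) gated conductances on
#' every compartment -- fast sodium (Na), delayed-rectifier potassium (Kdr),
#' muscarinic potassium (Km), A-type transient potassium (KA), low-threshold
#' transient calcium (CaT), high-voltage-activated calcium (CaHVA) and
#' calcium-dependent potassium (KCa) -- plus a leak and a first-order
#' intracellular calcium pool with an ATP-pump style decay.
#'
#' @format A character vector of the seven channel names.
#' @export
ab_channels <- c("Na", "Kdr", "Km", "KA", "CaT", "CaHVA", "KCa")

# gate bookkeeping: which of the 11 engine gates belong to which channel,
# and the power each gate enters the open fraction with
ab_gate_info <- tibble(
  gate = c("na.m", "na.h", "kdr.n", "km.n", "ka.m", "ka.h",
           "cat.m", "cat.h", "cahva.m", "cahva.h", "kca.n"),
  channel = c("Na", "Na", "Kdr", "Km", "KA", "KA",
              "CaT", "CaT", "CaHVA", "CaHVA", "KCa"),
  power = c(3, 1, 1, 1, 4, 1, 2, 1, 2, 1, 1))

ab_channel_ion <- c(Na = "na", Kdr = "k", Km = "k", KA = "k",
                    CaT = "ca", CaHVA = "ca", KCa = "k")

#' Reversal potentials and calcium pool parameters
#'
#' @param e_na,e_k,e_ca Ionic reversal potentials, mV.
#' @param mg Extracellular magnesium concentration for the NMDA block, mM.
#' @param ca_depth Depth of the submembrane calcium shell, um.
#' @param ca_tau Calcium pump/decay time constant, ms.
#' @param ca_inf Resting calcium concentration, mM.
#' @return A named list of class `ab_ion_params`.
#' @export
ion_params <- function(e_na = 60, e_k = -80, e_ca = 140, mg = 1,
                       ca_depth = 0.1, ca_tau = 200, ca_inf = 1e-4) {
  structure(list(e_na = e_na, e_k = e_k, e_ca = e_ca, mg = mg,
                 ca_depth = ca_depth, ca_tau = ca_tau, ca_inf = ca_inf),
            class = "ab_ion_params")
}

#' Region- and geometry-dependent channel density rules
#'
#' The default rule set places the channel densities used throughout the
#' model: uniform sodium on both trees, a diameter-switched A-type density
#' (thin dendrites below 0.8 um carry a tenfold higher density), and calcium
#' channel densities that follow the path distance x from the soma -- a
#' truncated sinusoid along the apical tree and a linear ramp along the basal
#' tree. All densities are in mS/cm^2 and are clamped at zero (the apical
#' sinusoid is negative just below its 260 um cut-over; see the methods
#' vignette for the recorded discontinuity).
#'
#' @return An `ab_density_rules` object: a named list mapping each channel to
#'   `function(region, x, d)` returning mS/cm^2.
#' @examples
#' rules <- default_density_rules()
#' conductance_at(rules, "CaT", region = "basal", x = 100) # 0.036 mS/cm^2
#' @export
default_density_rules <- function() {
  sinus <- function(amp, x) pmax(0, amp * sin(0.009 * x + 0.88))
  rules <- list(
    Na = function(region, x, d) if (region == "soma") 0.505 else 0.303,
    Kdr = function(region, x, d) if (region == "soma") 0.05 else 1.5e-3,
    Km = function(region, x, d) if (region == "soma") 2.8e-3 else 1.27e-3,
    KA = function(region, x, d) {
      if (region == "soma") 5.4 else if (d <= 0.8) 108 else 10.8
    },
    CaT = function(region, x, d) {
      switch(region,
             soma = 0.03,
             apical = if (x <= 260) sinus(0.029, x) else 0.012,
             basal = 0.03 + 6e-5 * x)
    },
    CaHVA = function(region, x, d) {
      switch(region,
             soma = 0.05e-3,
             apical = if (x <= 260) sinus(0.049e-3, x) else 0.02e-3,
             basal = 0.05e-3 + 1e-7 * x)
    },
    KCa = function(region, x, d) 2.1e-3)
  structure(rules, class = "ab_density_rules",
            sim_scale = default_sim_scale())
}

#' Per-channel simulation unit interpretation
#'
#' The density rules carry the model's densities as printed, but the rows
#' for the fast sodium, delayed-rectifier and muscarinic channels are in the
#' simulator's native S/cm^2 convention (a uniform mS/cm^2 reading would put
#' the somatic sodium maximum current below the dendritic load conductance,
#' i.e. no action potential could ever fire, contradicting the documented
#' 66.1 mV AP and dendritic sodium spiking). `build_system()` therefore
#' multiplies those channels by 1000 when assembling compartment
#' conductances; the factor set is attached to the rule set as the
#' `sim_scale` attribute and can be overridden. See the methods vignette.
#'
#' @return Named numeric vector over `ab_channels`.
#' @export
default_sim_scale <- function() {
  c(Na = 1000, Kdr = 1000, Km = 1000, KA = 1, CaT = 1, CaHVA = 1, KCa = 1)
}

#' Passive rule set (all active densities zero)
#' @rdname default_density_rules
#' @export
passive_density_rules <- function() {
  rules <- setNames(
    rep(list(function(region, x, d) 0), length(ab_channels)), ab_channels)
  structure(rules, class = "ab_density_rules")
}

#' Evaluate a channel density rule
#'
#' @param rules An `ab_density_rules` rule set.
#' @param channel One of `ab_channels`.
#' @param segment Optionally, a one-row segment table (from a morphology)
#'   supplying `tree_label`, `path_distance` and `diameter`.
#' @param region,x,d Alternatively, the region (`"soma"`, `"apical"`,
#'   `"basal"`), path distance from the soma (um) and diameter (um).
#' @return Conductance density in mS/cm^2 (never negative).
#' @export
conductance_at <- function(rules, channel, segment = NULL,
                           region = NULL, x = NULL, d = NULL) {
  if (!channel %in% names(rules)) {
    abort(paste0("channel '", channel, "' not in rule set"),
          class = "ab_lookup_error")
  }
  if (!is.null(segment)) {
    region <- segment$tree_label[1]
    x <- segment$path_distance[1]
    d <- segment$diameter[1]
  }
  if (is.null(x)) x <- 0
  if (is.null(d)) d <- 1
  val <- rules[[channel]](region, x, d)
  max(0, val)
}

#' Channel gate kinetics at a voltage
#'
#' Steady-state activation and time constant for each of the 11 gating
#' variables, at membrane potential `v` and calcium concentration `ca`
#' (only the KCa gate depends on calcium). These are the kinetics the
#' simulation engine integrates.
#'
#' @param v Membrane potential, mV.
#' @param ca Intracellular calcium, mM.
#' @return A tibble with columns `gate`, `channel`, `power`, `inf`, `tau`.
#' @export
channel_kinetics <- function(v, ca = 1e-4) {
  tab <- cpp_gate_tables(v, ca)
  out <- ab_gate_info
  out$inf <- tab[, "inf"]
  out$tau <- tab[, "tau"]
  out
}

#' Initialise a channel state at steady state
#'
#' @param v Membrane potential, mV.
#' @param ions An [ion_params()] object.
#' @return An `ab_channel_state`: gates at their steady-state values for
#'   `v`, calcium at its resting concentration.
#' @export
channel_state_init <- function(v, ions = ion_params()) {
  kin <- channel_kinetics(v, ions$ca_inf)
  structure(list(gates = setNames(kin$inf, kin$gate), ca = ions$ca_inf,
                 ions = ions),
            class = "ab_channel_state")
}

#' Advance channel gating variables and calcium by one time step
#'
#' Each gate x follows first-order kinetics dx/dt = (x_inf(V) - x)/tau_x(V)
#' and is advanced with the exact exponential update
#' x <- x_inf + (x - x_inf) exp(-dt/tau), which keeps gates in `[0, 1]` for
#' any dt > 0. Calcium relaxes towards `ca_inf + influx * ca_tau` with the
#' pump time constant; `i_ca` is the calcium current density (uA/cm^2,
#' negative = inward).
#'
#' @param state An `ab_channel_state`.
#' @param v Membrane potential, mV.
#' @param dt Time step, ms (> 0).
#' @param i_ca Calcium current density, uA/cm^2.
#' @return The advanced `ab_channel_state`.
#' @export
step_channel_states <- function(state, v, dt, i_ca = 0) {
  if (dt <= 0) abort("dt must be positive", class = "ab_domain_error")
  if (!is.finite(v)) {
    abort("numerical-state error: non-finite voltage", class = "ab_numeric_error")
  }
  kin <- channel_kinetics(v, state$ca)
  state$gates <- kin$inf + (state$gates - kin$inf) * exp(-dt / kin$tau)
  names(state$gates) <- kin$gate
  ions <- state$ions
  # influx term: -i_ca[uA/cm^2] -> mA/cm^2, shell depth in um
  drive <- max(0, -1e4 * (i_ca * 1e-3) / (2 * 96485.309 * ions$ca_depth))
  target <- ions$ca_inf + drive * ions$ca_tau
  state$ca <- target + (state$ca - target) * exp(-dt / ions$ca_tau)
  state
}

#' Total ionic membrane current density
#'
#' Assembles I = sum_c g_c(V) (V - E_c) + g_leak (V - E_leak) from a channel
#' state and a set of channel densities, in uA/cm^2. With all channel
#' densities zero this reduces to the leak current.
#'
#' @param state An `ab_channel_state`.
#' @param v Membrane potential, mV.
#' @param densities Named numeric vector of channel densities, mS/cm^2
#'   (names from `ab_channels`; missing channels contribute nothing).
#' @param passive A [passive_params()] object for the leak term.
#' @return Current density, uA/cm^2 (positive = outward).
#' @export
membrane_current <- function(state, v, densities = NULL,
                             passive = passive_params()) {
  i <- passive$g_leak * 1e3 * (v - passive$e_leak)  # S/cm^2 mV -> uA/cm^2
  if (length(densities)) {
    ions <- state$ions
    erev <- c(na = ions$e_na, k = ions$e_k, ca = ions$e_ca)
    for (ch in names(densities)) {
      gi <- ab_gate_info[ab_gate_info$channel == ch, ]
      open <- prod(state$gates[gi$gate]^gi$power)
      i <- i + densities[[ch]] * open * (v - erev[[ab_channel_ion[[ch]]]])
    }
  }
  i
}
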