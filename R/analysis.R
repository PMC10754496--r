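#' Detect a dendritic spike in a local voltage trace
#'
#' A regenerative local event is declared when the maximum depolarisation
#' rate reaches `slope_min` (default 10 mV/ms) AND the peak depolarisation
#' reaches `amp_min` (default 20 mV) above baseline. For slow NMDA-type
#' plateau events an optional half-width gate (`min_halfwidth_ms`) can be
#' used instead of the slope gate. The criterion is config-exposed and is
#' reported alongside every threshold it produces.
#'
#' @param v Local voltage trace, mV (uniformly sampled).
#' @param time Sample times, ms.
#' @param baseline Baseline voltage, mV (default: first sample).
#' @param slope_min Minimum depolarisation rate, mV/ms (`NA` disables).
#' @param amp_min Minimum peak depolarisation above baseline, mV.
#' @param min_halfwidth_ms If non-`NULL`, additionally require the
#'   depolarisation to stay above the amplitude gate for at least this long
#'   (a sustained plateau rather than a brief transient).
#' @return A list: `detected`, `peak_amp` (mV), `max_slope` (mV/ms),
#'   `halfwidth_ms` (time above half peak), `plateau_ms` (time above
#'   `amp_min`).
#' @export
detect_dendritic_spike <- function(v, time, baseline = NULL,
                                   slope_min = 10, amp_min = 20,
                                   min_halfwidth_ms = NULL) {
  if (is.null(baseline)) baseline <- v[1]
  dep <- v - baseline
  peak <- max(dep)
  dtv <- diff(time)
  slope <- max(diff(v) / dtv)
  step_ms <- stats::median(dtv)
  halfwidth <- sum(dep >= peak / 2) * step_ms
  plateau <- sum(dep >= amp_min) * step_ms
  ok <- peak >= amp_min
  if (!is.na(slope_min) && is.null(min_halfwidth_ms)) ok <- ok && slope >= slope_min
  if (!is.null(min_halfwidth_ms)) ok <- ok && plateau >= min_halfwidth_ms
  list(detected = ok, peak_amp = peak, max_slope = slope,
       halfwidth_ms = halfwidth, plateau_ms = plateau)
}

#' Nonlinearity Relative to Linear Extrapolation (NRLE)
#'
#' Given measured peak responses for n = 1..N synchronously activated
#' synapses, the linear expectation for n synapses is n times the unitary
#' response. NRLE is the maximum over n >= 2 of actual(n) / (n actual(1)):
#' 1 for a linear dendrite, < 1 sublinear, > 1 supralinear.
#'
#' @param actual_peaks Peak responses for n = 1..N (N >= 2); `actual_peaks[1]`
#'   must be positive.
#' @param n Optionally, the synapse counts the peaks correspond to (the
#'   first entry must be 1).
#' @return The NRLE value.
#' @examples
#' nrle((1:10) * 0.5)      # exactly linear -> 1
#' nrle(sqrt(1:10))        # sublinear -> 1/sqrt(2)
#' @export
nrle <- function(actual_peaks, n = seq_along(actual_peaks)) {
  if (length(actual_peaks) < 2) {
    abort("NRLE needs responses for at least two synapse counts",
          class = "ab_domain_error")
  }
  if (n[1] != 1 || actual_peaks[1] <= 0) {
    abort("NRLE needs a positive unitary response at n = 1",
          class = "ab_domain_error")
  }
  max(actual_peaks[-1] / (n[-1] * actual_peaks[1]))
}

#' Orientation selectivity index
#'
#' OSI = (R_pref - R_orth) / (R_pref + R_orth).
#'
#' @param rate_pref,rate_orth Firing rates at the preferred and orthogonal
#'   orientations, Hz (non-negative).
#' @return OSI in `[0, 1]` (0 when both rates are 0).
#' @export
osi <- function(rate_pref, rate_orth) {
  tot <- rate_pref + rate_orth
  ifelse(tot > 0, (rate_pref - rate_orth) / tot, 0)
}

#' Fit a wrapped-Gaussian orientation tuning curve
#'
#' Fits R(theta) = b + A exp(-D(theta, theta_p)^2 / (2 sigma^2)) with D the
#' circular orientation difference, by coarse grid search over
#' (theta_p, sigma) with the linear parameters solved per grid point,
#' followed by a local refinement. Tuning width is reported as the fitted
#' sigma; OSI uses the fitted curve at theta_p and theta_p + 90.
#'
#' @param curve A tuning curve tibble with columns `orientation` (degrees)
#'   and `mean_rate` (Hz).
#' @return An `ab_tuning_fit` with elements `preferred`, `width`, `osi`,
#'   `rate_pref`, `rate_orth`, `baseline`, `amplitude`, `rss`, `defined`;
#'   supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_tuning_curve <- function(curve) {
  th <- curve$orientation
  r <- curve$mean_rate
  if (all(r <= 1e-12) || length(unique(th)) < 3) {
    return(structure(list(preferred = NA_real_, width = NA_real_,
                          osi = NA_real_, rate_pref = NA_real_,
                          rate_orth = NA_real_, baseline = NA_real_,
                          amplitude = NA_real_, rss = NA_real_,
                          defined = FALSE, curve = curve),
                     class = "ab_tuning_fit"))
  }
  model_rss <- function(p, s) {
    basis <- exp(-circ_orientation_diff(th, p)^2 / (2 * s^2))
    X <- cbind(1, basis)
    fit <- stats::lm.fit(X, r)
    cf <- fit$coefficients
    # amplitude constrained non-negative: fall back to flat fit
    if (is.na(cf[2]) || cf[2] < 0) {
      cf <- c(mean(r), 0)
      res <- r - cf[1]
    } else res <- fit$residuals
    list(rss = sum(res^2), b = cf[1], a = cf[2])
  }
  grid <- expand.grid(p = seq(0, 175, by = 5), s = c(10, 15, 20, 30, 45, 60, 80))
  rss <- mapply(function(p, s) model_rss(p, s)$rss, grid$p, grid$s)
  best <- grid[which.min(rss), ]
  clamp_s <- function(s) min(max(s, 3), 100) # degrees; widths beyond ~100
                                             # are meaningless on a half-circle
  opt <- optim(c(best$p, log(best$s)),
               function(par) model_rss(par[1] %% 180, clamp_s(exp(par[2])))$rss,
               method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  p_hat <- opt$par[1] %% 180
  s_hat <- clamp_s(exp(opt$par[2]))
  ab <- model_rss(p_hat, s_hat)
  eval_fit <- function(theta) {
    ab$b + ab$a * exp(-circ_orientation_diff(theta, p_hat)^2 / (2 * s_hat^2))
  }
  rp <- max(0, eval_fit(p_hat))
  ro <- max(0, eval_fit((p_hat + 90) %% 180))
  structure(list(preferred = p_hat, width = s_hat, osi = osi(rp, ro),
                 rate_pref = rp, rate_orth = ro, baseline = ab$b,
                 amplitude = ab$a, rss = ab$rss, defined = TRUE,
                 curve = curve),
            class = "ab_tuning_fit")
}

#' @export
print.ab_tuning_fit <- function(x, ...) {
  if (!x$defined) {
    cat("<ab_tuning_fit> undefined (flat or empty curve)\n")
  } else {
    cat(sprintf(
      "<ab_tuning_fit> preferred %.1f deg, width %.1f deg, OSI %.3f (R_pref %.2f Hz, R_orth %.2f Hz)\n",
      x$preferred, x$width, x$osi, x$rate_pref, x$rate_orth))
  }
  invisible(x)
}

#' @export
tidy.ab_tuning_fit <- function(x, ...) {
  tibble(term = c("preferred", "width", "osi", "rate_pref", "rate_orth",
                  "baseline", "amplitude"),
         estimate = c(x$preferred, x$width, x$osi, x$rate_pref, x$rate_orth,
                      x$baseline, x$amplitude))
}

#' @export
glance.ab_tuning_fit <- function(x, ...) {
  tibble(preferred = x$preferred, width = x$width, osi = x$osi,
         rate_pref = x$rate_pref, rate_orth = x$rate_orth, rss = x$rss,
         defined = x$defined)
}

#' Tuning metrics from a tuning curve
#'
#' Convenience wrapper around [fit_tuning_curve()] returning a one-row
#' tibble of the derived metrics (preferred orientation, tuning width = the
#' fitted wrapped-Gaussian sigma, OSI, rates at preferred and orthogonal).
#'
#' @param curve A tuning curve tibble (`orientation`, `mean_rate`).
#' @return A one-row tibble.
#' @export
tuning_metrics <- function(curve) {
  glance(fit_tuning_curve(curve))
}

#' Linear (Euler-formula) expectation of orientation preference
#'
#' Orientation preferences are doubled into full angles, summed as unit
#' phasors with the given weights, and the resultant's argument halved back:
#' theta = 1/2 arg(sum_j w_j exp(2 i theta_j)), mapped to `[0, 180)`. This is
#' the preference the neuron would adopt if every synapse contributed
#' linearly. When the resultant is (numerically) zero the expectation is
#' undefined and `NA` is returned with `defined = FALSE`.
#'
#' @param preferences Orientation preferences, degrees.
#' @param weights Non-negative weights (default: equal).
#' @return A list: `preferred` (degrees or `NA`), `resultant_length`
#'   (normalised, in `[0, 1]`), `defined`.
#' @examples
#' expected_preference_euler(c(0, 40))$preferred # 20
#' expected_preference_euler(c(0, 40), c(0.6, 0.4))$preferred # 15.24
#' @export
expected_preference_euler <- function(preferences, weights = NULL) {
  if (!length(preferences)) {
    abort("need at least one preference", class = "ab_domain_error")
  }
  if (is.null(weights)) weights <- rep(1, length(preferences))
  if (any(weights < 0) || sum(weights) == 0) {
    abort("weights must be non-negative and not all zero",
          class = "ab_domain_error")
  }
  z <- sum(weights * exp(2i * preferences * pi / 180))
  rl <- Mod(z) / sum(weights)
  if (rl < 1e-9) {
    return(list(preferred = NA_real_, resultant_length = rl, defined = FALSE))
  }
  list(preferred = (Arg(z) * 90 / pi) %% 180, resultant_length = rl,
       defined = TRUE)
}

#' Classify a somatic spike by its intervention survival pattern
#'
#' Given whether the spike survived the apical-tree and basal-tree
#' interventions, the four survival patterns partition the spikes:
#' lost only under the apical intervention -> `apically_driven`; lost only
#' under the basal one -> `basally_driven`; lost under both ->
#' `cooperative`; lost under neither -> `independent`.
#'
#' @param survived_apical,survived_basal Logical (vectorised).
#' @return A factor with the four labels.
#' @export
classify_spike <- function(survived_apical, survived_basal) {
  lab <- ifelse(!survived_apical & survived_basal, "apically_driven",
         ifelse(survived_apical & !survived_basal, "basally_driven",
         ifelse(!survived_apical & !survived_basal, "cooperative",
                "independent")))
  factor(lab, levels = c("apically_driven", "basally_driven",
                         "cooperative", "independent"))
}

#' Compare a response between apical and basal segments
#'
#' Two-sample comparison of a per-segment response between the trees, with
#' optional normalisation by a morphometric covariate (response / covariate,
#' the "similar length/diameter/volume" comparisons), optional named-segment
#' exclusion (re-running without an atypical data point), and a paired or
#' unpaired t-test.
#'
#' @param profiles A tibble with `tree_label` plus the response/covariate
#'   columns (e.g. the output of [dendrite_profiles()]).
#' @param response Name of the response column.
#' @param covariate Optional name of the covariate column.
#' @param normalize Divide response by covariate before comparing.
#' @param paired Use a dependent (paired) t-test; requires equal group sizes
#'   in matching order (same segments under two conditions).
#' @param exclude Segment ids to exclude, recorded in the output.
#' @return A one-row tibble: group means/sds/ns, mean difference
#'   (apical - basal), t statistic, p value, and the exclusions applied.
#' @export
matched_compare <- function(profiles, response, covariate = NULL,
                            normalize = FALSE, paired = FALSE,
                            exclude = NULL) {
  df <- profiles
  if (!is.null(exclude)) df <- df[!df$segment_id %in% exclude, , drop = FALSE]
  y <- df[[response]]
  if (normalize) {
    if (is.null(covariate)) {
      abort("normalize = TRUE needs a covariate column", class = "ab_config_error")
    }
    y <- y / df[[covariate]]
  }
  a <- y[df$tree_label == "apical"]
  b <- y[df$tree_label == "basal"]
  if (length(a) < 2 || length(b) < 2) {
    abort("each tree needs at least two segments for the comparison",
          class = "ab_stats_error")
  }
  tt <- if (identical(a, b)) {
    list(statistic = c(t = 0), p.value = 1)
  } else {
    t.test(a, b, paired = paired)
  }
  tibble(response = response,
         covariate = if (is.null(covariate)) NA_character_ else covariate,
         normalized = normalize, paired = paired,
         mean_apical = mean(a), sd_apical = sd(a), n_apical = length(a),
         mean_basal = mean(b), sd_basal = sd(b), n_basal = length(b),
         difference = mean(a) - mean(b),
         t_statistic = unname(tt$statistic), p_value = tt$p.value,
         excluded = paste(exclude, collapse = ","))
}
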