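#' Generate a synthetic layer-2/3-like morphology
#'
#' Builds a stereotypical pyramidal-cell layout: several unbranched basal
#' stems sprouting from the base of the soma, and one apical trunk whose tip
#' carries a binary tuft of the given depth. Default dimensions are chosen so
#' that basal path distances stay below ~180 um while a substantial fraction
#' of apical segments lies beyond it, mirroring the proximal-basal /
#' distal-apical anatomy of these cells. Deterministic under `seed`; the
#' result is a valid input to every protocol and can be written to SWC.
#'
#' @param n_basal_stems Number of basal stems.
#' @param basal_length_range Basal stem length range, um.
#' @param basal_diameter_range Basal stem diameter range, um.
#' @param apical_trunk_length,apical_trunk_diameter Trunk geometry, um.
#' @param tuft_branch_depth Binary tuft depth (depth d gives 2^(d+1) - 2
#'   tuft segments).
#' @param tuft_segment_length Tuft segment length, um.
#' @param tuft_diameter Diameter of first-level tuft segments, um.
#' @param taper Diameter multiplier per tuft level (floored at 0.4 um).
#' @param soma_diameter Equivalent-sphere soma diameter, um.
#' @param seed Integer seed.
#' @param path Optional SWC output path; the file round-trips through
#'   [load_swc()].
#' @return An `ab_morphology`.
#' @export
generate_synthetic_morphology <- function(n_basal_stems = 5,
                                          basal_length_range = c(80, 150),
                                          basal_diameter_range = c(0.9, 1.4),
                                          apical_trunk_length = 150,
                                          apical_trunk_diameter = 2,
                                          tuft_branch_depth = 3,
                                          tuft_segment_length = 60,
                                          tuft_diameter = 1.1,
                                          taper = 0.85,
                                          soma_diameter = 12,
                                          seed = 1, path = NULL) {
  stopifnot(n_basal_stems >= 1, tuft_branch_depth >= 1,
            all(basal_length_range > 0), all(basal_diameter_range > 0))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  rows <- list()
  add_seg <- function(parent_id, tree, length, diameter, start_dist) {
    id <- length(rows) + 2L
    rows[[length(rows) + 1]] <<- tibble(
      segment_id = id, parent_id = parent_id, tree_label = tree,
      length = length, diameter = diameter,
      path_distance = start_dist + length / 2)
    id
  }
  for (b in seq_len(n_basal_stems)) {
    add_seg(1L, "basal",
            runif(1, basal_length_range[1], basal_length_range[2]),
            runif(1, basal_diameter_range[1], basal_diameter_range[2]), 0)
  }
  trunk <- add_seg(1L, "apical", apical_trunk_length, apical_trunk_diameter, 0)
  grow_tuft <- function(parent_id, depth, start_dist) {
    if (depth > tuft_branch_depth) return(invisible())
    d <- max(0.4, tuft_diameter * taper^(depth - 1))
    for (k in 1:2) {
      id <- add_seg(parent_id, "apical", tuft_segment_length, d, start_dist)
      grow_tuft(id, depth + 1, start_dist + tuft_segment_length)
    }
  }
  grow_tuft(trunk, 1, apical_trunk_length)
  soma_row <- tibble(segment_id = 1L, parent_id = NA_integer_,
                     tree_label = "soma", length = soma_diameter,
                     diameter = soma_diameter, path_distance = 0)
  segments <- bind_rows(soma_row, bind_rows(rows))
  segments$branch_order <- compute_branch_order(segments)
  m <- new_morphology(segments, soma_area_um2 = pi * soma_diameter^2)
  validate_morphology(m)
  if (!is.null(path)) write_swc(m, path)
  m
}

#' Reduced experiment presets
#'
#' Named, seed-fixed configurations that exercise each protocol end-to-end
#' on the synthetic cell within a few minutes on one CPU: `"smoke"` (3
#' orientations x 2 trials of the tuning experiment), `"disparity_lite"`
#' (disparities 0/40/90), and `"intervention_lite"` (ionic intervention,
#' baseline capped at 20 spikes). Each preset echoes its full configuration.
#'
#' @return A named list of preset definitions (`protocol`, `params`,
#'   `seed`, `morphology_params`).
#' @export
reduced_experiment_presets <- function() {
  morph <- list(seed = 1)
  list(
    smoke = list(
      protocol = "tuning", seed = 42, morphology_params = morph,
      params = list(orientations = c(0, 40, 90), n_trials = 2)),
    disparity_lite = list(
      protocol = "disparity", seed = 42, morphology_params = morph,
      params = list(disparities = c(0, 40, 90),
                    orientations = seq(0, 160, by = 20), n_trials = 2)),
    intervention_lite = list(
      protocol = "intervention", seed = 42, morphology_params = morph,
      params = list(kind = "ionic", n_trials = 2,
                    max_spikes_per_trial = 10)))
}

#' Run a reduced preset by name
#'
#' @param name Preset name (see [reduced_experiment_presets()]).
#' @param m Optional morphology (default: the preset's synthetic cell).
#' @param ... Overrides merged over the preset's parameters.
#' @return The protocol's result object, with the effective configuration
#'   attached as the `"preset_config"` attribute.
#' @export
run_preset <- function(name, m = NULL, ...) {
  presets <- reduced_experiment_presets()
  if (!name %in% names(presets)) {
    abort(paste0("unknown preset '", name, "'"), class = "ab_config_error")
  }
  p <- presets[[name]]
  if (is.null(m)) {
    m <- do.call(generate_synthetic_morphology, p$morphology_params)
  }
  args <- utils::modifyList(c(list(m = m, seed = p$seed), p$params),
                            list(...))
  fn <- switch(p$protocol,
               tuning = tuning_experiment,
               disparity = disparity_experiment,
               intervention = intervention_experiment)
  res <- do.call(fn, args)
  attr(res, "preset_config") <- args[setdiff(names(args), "m")]
  res
}
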