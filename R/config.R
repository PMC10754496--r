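#' Parse a run configuration file
#'
#' Reads a YAML run configuration, validates it against the known schema
#' (unknown keys are rejected with their path), fills defaults, and returns
#' the effective configuration with every value made explicit, so a result
#' directory can always be reproduced from its echoed config. Writing the
#' echo back out and re-parsing it yields an identical configuration.
#'
#' @param path Path to a YAML file, or a named list already in memory.
#' @return An `ab_config`: the validated, default-filled configuration.
#' @export
parse_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) {
      abort(paste0("config file not found: ", path), class = "ab_io_error")
    }
    yaml::read_yaml(path)
  } else path
  defaults <- list(
    morphology = NULL,                 # SWC path; NULL -> synthetic cell
    model = "biologically_plausible",
    protocol = "tuning",
    n_total = NULL,
    bg_fraction = 0.75,
    inhib_fraction = 0.25,
    pref_sigma = 30,
    disparity = 0,
    rate_stim_peak = 0.3,
    rate_background = 0.11,
    tuning_sigma_rate = 30,
    dt = 0.1,
    duration = 2500,
    onset = 500,
    seed = 1,
    protocol_params = list(),
    out_dir = NULL)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "ab_config_error")
  }
  cfg <- utils::modifyList(defaults, raw, keep.null = TRUE)
  with(cfg, {
    if (dt <= 0) abort("config dt must be positive", class = "ab_config_error")
    if (duration < onset) {
      abort("config duration must be >= onset", class = "ab_config_error")
    }
    if (rate_stim_peak < 0 || rate_background < 0) {
      abort("config rates must be non-negative", class = "ab_config_error")
    }
  })
  known_protocols <- c("tuning", "disparity", "intervention", "i3p",
                       "attenuation", "ablation", "sensitivity")
  if (!cfg$protocol %in% known_protocols) {
    abort(paste0("unknown protocol '", cfg$protocol, "' (known: ",
                 paste(known_protocols, collapse = ", "), ")"),
          class = "ab_config_error")
  }
  distribution_model(cfg$model) # validates the model name
  structure(cfg, class = "ab_config")
}

#' @export
print.ab_config <- function(x, ...) {
  cat("<ab_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Write the effective configuration back to YAML
#'
#' @param cfg An `ab_config`.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
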