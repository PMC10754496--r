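#' Plot an orientation tuning experiment
#'
#' Mean rate per orientation with SEM error bars and the fitted
#' wrapped-Gaussian curve.
#'
#' @param object An `ab_tuning`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ab_tuning <- function(object, ...) {
  curve <- object$curve
  fit <- object$fit
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$orientation,
                                           y = .data$mean_rate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rate - .data$sem_rate,
                                        ymax = .data$mean_rate + .data$sem_rate),
                           width = 3) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "stimulus orientation (deg)",
                  y = "firing rate (Hz)")
  if (fit$defined) {
    th <- seq(0, 180, by = 1)
    pred <- tibble(orientation = th,
                   mean_rate = fit$baseline + fit$amplitude *
                     exp(-circ_orientation_diff(th, fit$preferred)^2 /
                           (2 * fit$width^2)))
    p <- p + ggplot2::geom_line(data = pred, colour = "red3") +
      ggplot2::labs(subtitle = sprintf("OSI %.2f, width %.0f deg, preferred %.0f deg",
                                       fit$osi, fit$width, fit$preferred))
  }
  p
}

#' Plot a dendritic input-output (paired-pulse) profile
#'
#' Actual vs expected (linear) peak response as a function of the number of
#' synchronously activated synapses; the divergence of the two curves is the
#' dendritic nonlinearity the NRLE index summarises.
#'
#' @param object An `ab_i3p`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ab_i3p <- function(object, ...) {
  tab <- tidyr::pivot_longer(object$table[, c("n", "actual_peak",
                                              "expected_peak")],
                             -"n", names_to = "curve", values_to = "peak")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$n, y = .data$peak,
                                    linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "synchronously activated synapses",
                  y = "local peak depolarisation (mV)",
                  subtitle = sprintf("segment %d, NRLE %.2f",
                                     object$segment_id, object$nrle))
}

#' Plot intervention outcome percentages
#'
#' Mean per-trial percentage of somatic spikes in each attribution class,
#' with SEM error bars.
#'
#' @param object An `ab_intervention`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ab_intervention <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$label, y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pct - .data$sem_pct,
                                        ymax = .data$mean_pct + .data$sem_pct),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "% of somatic spikes")
}

#' Plot a simulated voltage trace
#'
#' @param x An `ab_sim_result`.
#' @param sites Columns (recorded sites) to draw; default all.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_traces <- function(x, sites = NULL, ...) {
  tr <- as.data.frame(x$traces)
  if (!is.null(sites)) tr <- tr[, sites, drop = FALSE]
  tr$time <- x$time
  long <- tidyr::pivot_longer(tr, -"time", names_to = "site",
                              values_to = "v")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$v,
                                     colour = .data$site)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)")
}
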