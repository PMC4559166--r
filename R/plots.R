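#' @import ggplot2
NULL

#' Plot PCA orbits of expression change during evolution
#'
#' Each strain's trajectory through the first two principal components,
#' anchored at the parent sample, drawn as a connected orbit with points at
#' the sampled timepoints.
#'
#' @param object An `evo_pca` from [pca_orbits()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot evo_pca
#' @export
autoplot.evo_pca <- function(object, ...) {
  ev <- object$explained_variance
  ggplot(object$orbits, aes(x = .data$PC1, y = .data$PC2,
                            colour = .data$strain)) +
    geom_path(arrow = grid::arrow(length = grid::unit(2, "mm"),
                                  type = "closed")) +
    geom_point(size = 1.6) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
         colour = "strain") +
    theme_minimal()
}

#' Plot a mate-pair distance-deviation scan
#'
#' Window deviation scores along the genome with the flag threshold and
#' merged regions highlighted.
#'
#' @param object An `evo_scan` from [scan_distance_deviation()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot evo_scan
#' @export
autoplot.evo_scan <- function(object, ...) {
  p <- ggplot(object$windows, aes(x = (.data$start + .data$end) / 2,
                                  y = .data$z)) +
    geom_point(size = 0.4, alpha = 0.5) +
    geom_hline(yintercept = c(-1, 1) * object$z_threshold,
               linetype = "dashed", colour = "firebrick") +
    labs(x = "genome position (bp)", y = "median-distance deviation (SD)") +
    theme_minimal()
  if (nrow(object$regions)) {
    p <- p + geom_rect(data = object$regions,
                       aes(xmin = .data$start, xmax = .data$end),
                       ymin = -Inf, ymax = Inf, alpha = 0.15,
                       fill = "firebrick", inherit.aes = FALSE)
  }
  p
}

#' Plot a read-depth coverage profile with duplication calls
#'
#' @param profile An `evo_coverage` from [coverage_profile()].
#' @param calls Optional duplication calls from [detect_duplication()].
#' @return A ggplot.
#' @export
plot_coverage <- function(profile, calls = NULL) {
  p <- ggplot(profile, aes(x = (.data$start + .data$end) / 2,
                           y = .data$coverage)) +
    geom_step(linewidth = 0.3) +
    geom_hline(yintercept = median(profile$coverage), linetype = "dotted") +
    labs(x = "genome position (bp)", y = "fold coverage") +
    theme_minimal()
  if (!is.null(calls) && nrow(calls)) {
    p <- p + geom_rect(data = calls,
                       aes(xmin = .data$start, xmax = .data$end),
                       ymin = -Inf, ymax = Inf, alpha = 0.15,
                       fill = "steelblue", inherit.aes = FALSE)
  }
  p
}

#' Plot a mutation-fixation timeline
#'
#' One line per mutation over time: solid where the mutation is fixed in the
#' population, dashed where polymorphic (the two-peak regime), absent points
#' at the baseline.
#'
#' @param object An `evo_timeline` from [build_mutation_timeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot evo_timeline
#' @export
autoplot.evo_timeline <- function(object, ...) {
  ggplot(object$timeline,
         aes(x = .data$time_h, y = .data$frequency,
             group = .data$mutation, colour = .data$mutation)) +
    geom_line(aes(linetype = .data$frequency < object$upper)) +
    geom_point(aes(shape = .data$status), size = 1.8) +
    scale_linetype_manual(values = c(`TRUE` = "dashed", `FALSE` = "solid"),
                          guide = "none") +
    geom_hline(yintercept = c(object$lower, object$upper),
               linetype = "dotted", colour = "grey50") +
    labs(x = "time (h)", y = "population allele frequency") +
    theme_minimal()
}

#' Plot an OD600 series with its exponential-phase fit
#'
#' @param series The OD tibble (`time_h`, `od600`) the fit was made on.
#' @param fit An `evo_growth` from [specific_growth_rate()].
#' @return A ggplot on a log OD scale.
#' @export
plot_growth_fit <- function(series, fit) {
  ggplot(series, aes(x = .data$time_h, y = .data$od600)) +
    geom_point(size = 1.5) +
    geom_rect(xmin = fit$window[1], xmax = fit$window[2],
              ymin = -Inf, ymax = Inf, alpha = 0.05, fill = "steelblue") +
    geom_abline(slope = fit$mu / log(10),
                intercept = unname(coef(fit$fit)[1]) / log(10),
                colour = "firebrick") +
    scale_y_log10() +
    labs(x = "time (h)", y = "OD600",
         title = sprintf("mu = %.3f per hour", fit$mu)) +
    theme_minimal()
}
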