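#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a growth-rate fit
#'
#' @param x An `evo_growth` object.
#' @param ... Unused.
#' @return A one-row tibble: `mu`, `window_start_h`, `window_end_h`,
#'   `n_points`, `sigma`, `r_squared`.
#' @method tidy evo_growth
#' @export
tidy.evo_growth <- function(x, ...) {
  tibble(mu = x$mu, window_start_h = x$window[1], window_end_h = x$window[2],
         n_points = x$n_points, sigma = x$sigma, r_squared = x$r_squared)
}

#' Tidy a Dunnett comparison: one row per group vs control
#' @param x An `evo_dunnett` object.
#' @param ... Unused.
#' @method tidy evo_dunnett
#' @export
tidy.evo_dunnett <- function(x, ...) x$comparisons

#' One-row ANOVA summary of a Dunnett comparison
#' @param x An `evo_dunnett` object.
#' @param ... Unused.
#' @method glance evo_dunnett
#' @export
glance.evo_dunnett <- function(x, ...) x$anova

#' Tidy PCA scores with sample metadata
#' @param x An `evo_pca` object.
#' @param ... Unused.
#' @method tidy evo_pca
#' @export
tidy.evo_pca <- function(x, ...) x$scores

#' Explained-variance summary of a PCA
#' @param x An `evo_pca` object.
#' @param ... Unused.
#' @method glance evo_pca
#' @export
glance.evo_pca <- function(x, ...) {
  tibble(component = seq_along(x$explained_variance),
         explained_variance = x$explained_variance)
}

#' Tidy a two-platform consensus: the final call set
#' @param x An `evo_consensus` object.
#' @param ... Unused.
#' @method tidy evo_consensus
#' @export
tidy.evo_consensus <- function(x, ...) x$final

#' One-row summary of a two-platform consensus
#' @param x An `evo_consensus` object.
#' @param ... Unused.
#' @method glance evo_consensus
#' @export
glance.evo_consensus <- function(x, ...) {
  tibble(n_agreed = nrow(x$agreed), n_a_only = nrow(x$a_only),
         n_b_only = nrow(x$b_only),
         n_confirmed = sum(x$resolutions$status == "confirmed"),
         n_refuted = sum(x$resolutions$status == "refuted"),
         n_unresolved = sum(x$resolutions$status == "unresolved"),
         n_final = nrow(x$final))
}

#' Tidy a distance scan: the merged flagged regions
#' @param x An `evo_scan` object.
#' @param ... Unused.
#' @method tidy evo_scan
#' @export
tidy.evo_scan <- function(x, ...) x$regions

#' One-row summary of a distance scan
#' @param x An `evo_scan` object.
#' @param ... Unused.
#' @method glance evo_scan
#' @export
glance.evo_scan <- function(x, ...) {
  tibble(mean_distance = x$stats$mean_distance,
         sd_distance = x$stats$sd_distance, n_pairs = x$stats$n_pairs,
         n_windows = nrow(x$windows), n_flagged = sum(x$windows$flagged),
         n_regions = nrow(x$regions))
}

#' Tidy a mutation timeline: one row per (mutation, timepoint)
#' @param x An `evo_timeline` object.
#' @param ... Unused.
#' @method tidy evo_timeline
#' @export
tidy.evo_timeline <- function(x, ...) x$timeline

#' Per-mutation fixation summary of a timeline
#' @param x An `evo_timeline` object.
#' @param ... Unused.
#' @method glance evo_timeline
#' @export
glance.evo_timeline <- function(x, ...) x$summary

#' Tidy a scenario report: per planted event recovery
#' @param x An `evo_report` object.
#' @param ... Unused.
#' @method tidy evo_report
#' @export
tidy.evo_report <- function(x, ...) x$matches

#' One-row summary of a scenario report
#' @param x An `evo_report` object.
#' @param ... Unused.
#' @method glance evo_report
#' @export
glance.evo_report <- function(x, ...) {
  tibble(scenario = x$scenario, n_truth = x$counts$n_truth,
         n_recovered = x$counts$n_recovered,
         n_false_positive = x$counts$n_false_positive,
         masked_bp = attr(x$mask, "masked_bp"))
}
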