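#' Classify a population allele frequency as absent, polymorphic, or fixed
#'
#' Emulates scoring a population Sanger trace: a clean wild-type trace is
#' `absent`, two-peak signals indicate coexisting genotypes (`polymorphic`),
#' and a clean mutant trace is `fixed`. The thresholds reflect typical
#' chromatogram minor-peak sensitivity and are configurable. The
#' classification partitions `[0, 1]`: `absent` if `f < lower`, `polymorphic`
#' if `lower <= f < upper`, `fixed` if `f >= upper`.
#'
#' @param frequency Numeric vector of allele frequencies in `[0, 1]`.
#' @param lower,upper Class boundaries.
#' @return Character vector of statuses.
#' @export
classify_allele_status <- function(frequency, lower = 0.2, upper = 0.8) {
  if (any(frequency < 0 | frequency > 1, na.rm = TRUE)) {
    abort("allele frequencies must lie in [0, 1]",
          class = "evotrace_invalid_argument")
  }
  dplyr::case_when(
    is.na(frequency) ~ NA_character_,
    frequency < lower ~ "absent",
    frequency < upper ~ "polymorphic",
    TRUE ~ "fixed"
  )
}

#' Build a mutation-fixation timeline from population allele frequencies
#'
#' Classifies every (mutation, timepoint) cell and summarises, per mutation,
#' the first timepoint at which it was detected (polymorphic or fixed) and
#' first fixed. No monotonicity is assumed: a mutation may rise and fall
#' again, the signature of clonal interference, and is reported as observed.
#' Missing cells get an explicit `"missing"` status, never a silent fill.
#'
#' @param frequency_table A tibble: `mutation`, `time_h`, `frequency` (as
#'   from [simulate_population_timecourse()]).
#' @param lower,upper Passed to [classify_allele_status()].
#' @return A list of class `evo_timeline`: `timeline` (per-cell tibble with
#'   `status`) and `summary` (per-mutation tibble with `first_detected_h`,
#'   `first_fixed_h`, both `NA` when never reached).
#' @export
build_mutation_timeline <- function(frequency_table, lower = 0.2,
                                    upper = 0.8) {
  assert_columns(frequency_table, c("mutation", "time_h", "frequency"),
                 "frequency_table")
  timeline <- frequency_table |>
    tidyr::complete(.data$mutation, .data$time_h) |>
    mutate(status = dplyr::coalesce(
      classify_allele_status(.data$frequency, lower, upper), "missing")) |>
    arrange(.data$mutation, .data$time_h)
  summary <- timeline |>
    group_by(.data$mutation) |>
    summarise(
      first_detected_h = min(
        .data$time_h[.data$status %in% c("polymorphic", "fixed")], Inf),
      first_fixed_h = min(.data$time_h[.data$status == "fixed"], Inf),
      .groups = "drop") |>
    mutate(across(c("first_detected_h", "first_fixed_h"),
                  ~ ifelse(is.finite(.x), .x, NA_real_)))
  structure(list(timeline = timeline, summary = summary,
                 lower = lower, upper = upper),
            class = "evo_timeline")
}

#' @export
print.evo_timeline <- function(x, ...) {
  cat(sprintf("<evo_timeline> %d mutation(s) x %d timepoint(s)\n",
              dplyr::n_distinct(x$timeline$mutation),
              dplyr::n_distinct(x$timeline$time_h)))
  print(x$summary)
  invisible(x)
}

#' Summarise clone genotypes into genotype groups
#'
#' Given per-clone presence/absence scores at a set of loci (e.g. 48 clones
#' isolated from a population and Sanger-typed at two candidate loci), counts
#' clones per genotype signature. Signatures are labelled by the loci
#' carried, in the order of `loci`, with `"(none)"` for mutation-free clones,
#' and ordered from most to least derived signature.
#'
#' @param clone_genotypes A tibble with a `clone` column and one 0/1 (or
#'   logical) column per locus.
#' @param loci Character vector of locus column names; every clone must be
#'   scored (non-`NA`) at every locus.
#' @return A tibble: `signature`, `n`. Counts sum to the number of clones.
#' @export
genotype_clone_summary <- function(clone_genotypes, loci) {
  assert_columns(clone_genotypes, c("clone", loci), "clone_genotypes")
  if (!nrow(clone_genotypes)) {
    return(tibble(signature = character(), n = integer()))
  }
  score <- as.matrix(clone_genotypes[, loci, drop = FALSE])
  if (any(is.na(score))) {
    abort("every clone must be scored at every locus",
          class = "evotrace_invalid_argument")
  }
  score <- score != 0
  signature <- apply(score, 1L, function(r) {
    if (!any(r)) "(none)" else paste(loci[r], collapse = "+")
  })
  # order signatures by binary value of the locus pattern, most derived first
  value <- score %*% 2^(rev(seq_along(loci)) - 1)
  tibble(signature = signature, .value = as.vector(value)) |>
    dplyr::count(.data$signature, .data$.value) |>
    arrange(desc(.data$.value)) |>
    select("signature", "n")
}

#' Sample clone genotypes from a population at given locus frequencies
#'
#' Utility for round-trip checks: draws `n_clones` clones whose per-locus
#' genotypes are independent Bernoulli draws at the supplied frequencies
#' (nested frequencies, e.g. a locus only ever present together with another,
#' can be emulated by passing a `structure` matrix instead).
#'
#' @param n_clones Number of clones to draw.
#' @param locus_freqs Named numeric vector of per-locus allele frequencies.
#' @param seed Integer seed.
#' @return A tibble: `clone` plus one 0/1 column per locus.
#' @export
sample_clone_genotypes <- function(n_clones, locus_freqs, seed = 1L) {
  with_seed(seed, {
    out <- tibble(clone = sprintf("clone%02d", seq_len(n_clones)))
    for (locus in names(locus_freqs)) {
      out[[locus]] <- rbinom(n_clones, 1L, locus_freqs[[locus]])
    }
    out
  })
}
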