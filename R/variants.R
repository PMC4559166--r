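#' Configuration for point-mutation and small-indel calling
#'
#' Defaults mirror the thresholds used for population resequencing of evolved
#' bacterial strains: coverage of at least 10 reads, a variant-read fraction
#' of at least 0.6 (so only mutations carried by the majority of cells are
#' called), and a one-sided binomial tail probability below `1e-7` against
#' the platform error rate. The ratio is interpreted as variant reads over
#' total reads at the site; depth and ratio thresholds are inclusive, the
#' p-value threshold is strict.
#'
#' @param min_depth Minimum read depth (reads).
#' @param min_ratio Minimum variant-read fraction.
#' @param p_threshold Binomial tail p-value threshold (strict `<`).
#' @param error_rate Assumed per-base error rate of the platform.
#' @return A list of class `evo_caller_config`.
#' @export
caller_config <- function(min_depth = 10, min_ratio = 0.6,
                          p_threshold = 1e-7, error_rate = 0.005) {
  assert_scalar_number(min_depth, "min_depth", lower = 0)
  assert_scalar_number(min_ratio, "min_ratio", lower = 0, upper = 1)
  assert_scalar_number(p_threshold, "p_threshold", lower = 0, upper = 1)
  assert_scalar_number(error_rate, "error_rate", lower = 0, upper = 1,
                       strict_upper = TRUE)
  structure(list(min_depth = min_depth, min_ratio = min_ratio,
                 p_threshold = p_threshold, error_rate = error_rate),
            class = "evo_caller_config")
}

#' One-sided binomial tail probability of the observed variant support
#'
#' `P(X >= k | n, p)` for `X ~ Binomial(n, p)`: the probability of seeing at
#' least the observed number of variant reads by sequencing error alone. This
#' is the error-aware confidence score the caller thresholds at `p_threshold`.
#'
#' @param k Observed variant-read counts.
#' @param n Read depths.
#' @param p Per-base error rate.
#' @return Numeric vector of tail probabilities.
#' @export
binomial_tail <- function(k, n, p) {
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Call point mutations from a pileup
#'
#' A site is called iff `depth >= min_depth`, `variant_count / depth >=
#' min_ratio`, and the binomial tail probability of the variant support under
#' the platform error rate is `< p_threshold`. Calls are returned sorted by
#' position.
#'
#' @param pileup A pileup tibble (see [simulate_pileups()] /
#'   [read_pileup_tsv()]): columns `pos`, `ref`, `depth`, `variant_count`,
#'   optionally `alt` and `platform`.
#' @param config An [caller_config()] object.
#' @return A tibble of calls: `position`, `ref`, `alt`, `ratio`, `depth`,
#'   `p_value`, `platform`.
#' @export
call_point_mutations <- function(pileup, config = caller_config()) {
  assert_columns(pileup, c("pos", "depth", "variant_count"), "pileup")
  if (any(pileup$variant_count > pileup$depth, na.rm = TRUE)) {
    abort("variant_count exceeds depth", class = "evotrace_data_integrity")
  }
  calls <- pileup |>
    filter(.data$depth >= config$min_depth,
           .data$variant_count / .data$depth >= config$min_ratio) |>
    mutate(p_value = binomial_tail(.data$variant_count, .data$depth,
                                   config$error_rate)) |>
    filter(.data$p_value < config$p_threshold) |>
    arrange(.data$pos)
  tibble(
    position = calls$pos,
    ref = if ("ref" %in% names(calls)) calls$ref else NA_character_,
    alt = if ("alt" %in% names(calls)) {
      dplyr::coalesce(calls$alt, "N")
    } else "N",
    ratio = calls$variant_count / calls$depth,
    depth = calls$depth,
    p_value = calls$p_value,
    platform = if ("platform" %in% names(calls)) calls$platform else NA_character_
  )
}

#' Call small indels (< 500 bp) from pileup indel evidence
#'
#' Applies the same depth and ratio gates as the point-mutation caller to
#' indel-supporting read counts. Evidence for events of 500 bp or more is not
#' called here — such events belong to the mate-pair distance scan — and is
#' dropped with a warning.
#'
#' @inheritParams call_point_mutations
#' @return A tibble: `position`, `length` (signed bp, deletions negative),
#'   `ratio`, `depth`, `platform`.
#' @export
call_small_indels <- function(pileup, config = caller_config()) {
  assert_columns(pileup, c("pos", "depth", "indel_len", "indel_count"),
                 "pileup")
  ev <- filter(pileup, !is.na(.data$indel_len), .data$indel_count > 0)
  big <- abs(ev$indel_len) >= 500
  if (any(big)) {
    warning("indel evidence >= 500 bp ignored; use the distance scan for large events")
    ev <- ev[!big, ]
  }
  calls <- ev |>
    filter(.data$depth >= config$min_depth,
           .data$indel_count / .data$depth >= config$min_ratio) |>
    arrange(.data$pos)
  tibble(position = calls$pos,
         length = calls$indel_len,
         ratio = calls$indel_count / calls$depth,
         depth = calls$depth,
         platform = if ("platform" %in% names(calls)) calls$platform else NA_character_)
}

#' Reconcile point-mutation calls from two platforms
#'
#' Calls made by both platforms (matched on position and alternate base) are
#' accepted outright. Discrepant calls — made by one platform only — are
#' checked against a confirmation oracle (in real studies, Sanger
#' sequencing; in simulations, the planted truth table): confirmed calls are
#' accepted, refuted calls dropped. Positions the oracle cannot answer are
#' flagged `unresolved`, never silently accepted.
#'
#' @param calls_a,calls_b Call tibbles from [call_point_mutations()].
#' @param truth Optional oracle: a tibble of true variants with columns
#'   `position` and `alt`. `NULL` leaves all discrepancies unresolved.
#' @param oracle_domain Optional integer vector of positions the oracle can
#'   answer; queries outside it are `unresolved`. Default: all positions.
#' @return A list of class `evo_consensus`: `agreed`, `a_only`, `b_only`,
#'   `resolutions` (tibble: position, alt, platform, status), and `final`
#'   (agreed plus confirmed calls).
#' @export
consensus_calls <- function(calls_a, calls_b, truth = NULL,
                            oracle_domain = NULL) {
  key <- c("position", "alt")
  agreed <- inner_join(calls_a, select(calls_b, dplyr::all_of(key)), by = key)
  a_only <- anti_join(calls_a, calls_b, by = key)
  b_only <- anti_join(calls_b, calls_a, by = key)

  discrepant <- bind_rows(a_only, b_only)
  resolutions <- tibble(position = integer(), alt = character(),
                        platform = character(), status = character())
  confirmed <- discrepant[0, ]
  if (nrow(discrepant)) {
    status <- rep("unresolved", nrow(discrepant))
    if (!is.null(truth)) {
      answerable <- if (is.null(oracle_domain)) {
        rep(TRUE, nrow(discrepant))
      } else {
        discrepant$position %in% oracle_domain
      }
      is_true <- vapply(seq_len(nrow(discrepant)), function(i) {
        any(truth$position == discrepant$position[i] &
              truth$alt == discrepant$alt[i])
      }, logical(1))
      status[answerable & is_true] <- "confirmed"
      status[answerable & !is_true] <- "refuted"
    }
    resolutions <- tibble(position = discrepant$position,
                          alt = discrepant$alt,
                          platform = discrepant$platform,
                          status = status)
    confirmed <- discrepant[status == "confirmed", ]
  }
  structure(list(agreed = agreed, a_only = a_only, b_only = b_only,
                 resolutions = resolutions,
                 final = arrange(bind_rows(agreed, confirmed), .data$position)),
            class = "evo_consensus")
}

#' @export
print.evo_consensus <- function(x, ...) {
  cat(sprintf(paste0("<evo_consensus> %d agreed, %d platform-A-only, ",
                     "%d platform-B-only, %d final call(s)\n"),
              nrow(x$agreed), nrow(x$a_only), nrow(x$b_only), nrow(x$final)))
  if (nrow(x$resolutions)) {
    print(dplyr::count(x$resolutions, .data$status))
  }
  invisible(x)
}

#' Mask low-coverage regions
#'
#' Returns maximal intervals where depth is strictly below `min_reads` (the
#' regions a short-read pipeline cannot interrogate, typically repeated
#' sequence such as rRNA operons). Variant calls inside masks should be
#' suppressed and reported separately; see [apply_mask()].
#'
#' @param depth_track Either an integer vector of per-site depths (site `i`
#'   is position `i`) or a tibble with columns `pos` and `depth` covering the
#'   whole reference.
#' @param min_reads Depth threshold; sites with `depth < min_reads` are masked.
#' @return A tibble of 1-based closed intervals `start`, `end`, `length`,
#'   with attribute `masked_bp` = total masked bases.
#' @export
mask_low_coverage <- function(depth_track, min_reads = 10) {
  if (is.data.frame(depth_track)) {
    assert_columns(depth_track, c("pos", "depth"), "depth_track")
    depth <- depth_track$depth[order(depth_track$pos)]
  } else {
    depth <- depth_track
  }
  r <- rle(depth < min_reads)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- tibble(start = starts[keep], end = ends[keep],
                length = ends[keep] - starts[keep] + 1L)
  attr(out, "masked_bp") <- sum(out$length)
  out
}

#' Split calls into masked and unmasked sets
#'
#' @param calls A call tibble with a `position` column.
#' @param mask Mask intervals from [mask_low_coverage()].
#' @return A list with `kept` and `masked` call tibbles.
#' @export
apply_mask <- function(calls, mask) {
  if (!nrow(mask) || !nrow(calls)) {
    return(list(kept = calls, masked = calls[0, ]))
  }
  idx <- findInterval(calls$position, mask$start)
  inside <- idx >= 1L & calls$position <= mask$end[pmax(idx, 1L)]
  list(kept = calls[!inside, ], masked = calls[inside, ])
}

#' Remove variants already present in the parent strain
#'
#' Mutations found in the parent are ancestral, not evolved, and are
#' discarded. Matching is by position and alternate allele (and signed length
#' for indel calls).
#'
#' @param calls,parent_calls Call tibbles sharing a coordinate system.
#' @return `calls` without rows matching `parent_calls`.
#' @export
subtract_parent <- function(calls, parent_calls) {
  if (!nrow(parent_calls) || !nrow(calls)) return(calls)
  key <- intersect(c("position", "alt", "length"),
                   intersect(names(calls), names(parent_calls)))
  anti_join(calls, parent_calls, by = key)
}
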