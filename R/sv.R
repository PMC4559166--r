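#' Remove low-quality mapped pairs
#'
#' Drops pairs with mapping quality below `min_mapq` or containing any base
#' with quality below `min_baseq` (summarised per pair as `min_baseq`). Both
#' bounds are inclusive: a pair at exactly the threshold is retained.
#'
#' @param pairs A pair tibble (see [simulate_mate_pairs()]).
#' @param min_mapq Minimum mapping quality.
#' @param min_baseq Minimum per-pair base quality.
#' @return The filtered pair tibble.
#' @export
filter_pairs <- function(pairs, min_mapq = 10, min_baseq = 30) {
  assert_columns(pairs, c("mapq", "min_baseq"), "pairs")
  filter(pairs, .data$mapq >= .env$min_mapq,
         .data$min_baseq >= .env$min_baseq)
}

#' Genome-wide mate-pair distance statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) of the outer mapped
#' distance over both-mapped concordant pairs. Counterpart pairs (one read in
#' an IS element) are excluded: their genome-scale distances describe where
#' the element sits, not the library, and would swamp the baseline the
#' deviation scan compares against. They still enter window medians and IS
#' classification.
#'
#' @param pairs A pair tibble; rows with a missing `distance` (or with a
#'   `counterpart_locus`) do not count.
#' @return A one-row tibble: `mean_distance`, `sd_distance`, `n_pairs`.
#' @export
global_distance_stats <- function(pairs) {
  keep <- !is.na(pairs$distance)
  if ("counterpart_locus" %in% names(pairs)) {
    keep <- keep & is.na(pairs$counterpart_locus)
  }
  d <- pairs$distance[keep]
  if (length(d) < 2L) {
    abort("need at least 2 both-mapped pairs",
          class = "evotrace_insufficient_data")
  }
  tibble(mean_distance = mean(d), sd_distance = sd(d), n_pairs = length(d))
}

#' Scan for regions whose mate-pair distances deviate from the genome norm
#'
#' The reference is tiled with overlapping windows (`window_size` wide, every
#' `step` bp); each both-mapped pair is assigned to the windows containing its
#' fragment-leading (anchor) read, falling back to `left_pos` for plain pair
#' tables. A window with at least `min_pairs` pairs is flagged when the
#' *median* of its mapped distances lies more than `z_threshold` standard
#' deviations from the global mean (two-sided). Overlapping or adjacent
#' flagged windows are merged into maximal regions, whose statistics are then
#' recomputed from all pairs with `left_pos` inside the merged region. A
#' fixed deletion of `L` bp shifts spanning-pair distances up by `L`; an
#' insertion shifts them down.
#'
#' @param pairs A (quality-filtered) pair tibble.
#' @param stats Global distance statistics from [global_distance_stats()].
#' @param window_size Window width in bp; a good default is the library
#'   insert mean.
#' @param step Tiling step in bp (default `window_size / 4`).
#' @param min_pairs Minimum pairs per window for the window to be scored.
#' @param z_threshold Deviation threshold in SD units (two-sided).
#' @return A list of class `evo_scan`: `windows` (all scored windows with
#'   `start`, `end`, `median_distance`, `n_pairs`, `z`, `flagged`) and
#'   `regions` (merged flagged regions with recomputed statistics), plus the
#'   scan parameters.
#' @export
scan_distance_deviation <- function(pairs, stats = global_distance_stats(pairs),
                                    window_size = 1200,
                                    step = max(1, round(window_size / 4)),
                                    min_pairs = 20, z_threshold = 3) {
  if (stats$sd_distance <= 0) {
    abort("degenerate distance spread (sd = 0)",
          class = "evotrace_degenerate_spread")
  }
  mapped <- filter(pairs, !is.na(.data$distance))
  # pairs are keyed by the fragment's flank-side read (anchor_pos falls back
  # to left_pos for plain pair tables)
  key <- if ("anchor_pos" %in% names(mapped)) {
    dplyr::coalesce(mapped$anchor_pos, mapped$left_pos)
  } else {
    mapped$left_pos
  }
  mapped$.key <- key
  max_pos <- max(key)
  n_win <- max(1L, ceiling((max_pos - window_size) / step) + 1L)
  span <- max(1L, round(window_size / step)) # windows covering each step bin

  bin <- pmin(floor((key - 1) / step) + 1L, n_win + span - 1L)
  assign_tbl <- tibble(
    w = rep(bin, each = span) - rep(seq_len(span) - 1L, times = nrow(mapped)),
    distance = rep(mapped$distance, each = span)
  ) |>
    filter(.data$w >= 1L, .data$w <= n_win)

  windows <- assign_tbl |>
    group_by(.data$w) |>
    summarise(median_distance = median(.data$distance),
              n_pairs = dplyr::n(), .groups = "drop") |>
    mutate(start = (.data$w - 1L) * step + 1L,
           end = .data$start + window_size - 1L,
           z = (.data$median_distance - stats$mean_distance) /
             stats$sd_distance,
           flagged = .data$n_pairs >= min_pairs &
             abs(.data$z) > z_threshold) |>
    select("start", "end", "median_distance", "n_pairs", "z", "flagged")

  regions <- merge_flagged(windows, mapped, stats)
  structure(list(windows = windows, regions = regions, stats = stats,
                 window_size = window_size, step = step,
                 min_pairs = min_pairs, z_threshold = z_threshold),
            class = "evo_scan")
}

merge_flagged <- function(windows, mapped, stats) {
  fw <- filter(windows, .data$flagged) |> arrange(.data$start)
  if (!nrow(fw)) {
    return(tibble(start = integer(), end = integer(),
                  median_distance = numeric(), n_pairs = integer(),
                  z = numeric()))
  }
  grp <- cumsum(c(1L, as.integer(fw$start[-1] > head(fw$end, -1) + 1L)))
  # the regional median is taken over the peak window (max |z|) of each
  # merged region: windows away from the peak mix in pairs that do not span
  # the event and would dilute the size estimate
  fw |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    summarise(peak_start = .data$start[which.max(abs(.data$z))],
              peak_end = .data$end[which.max(abs(.data$z))],
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    purrr::pmap_dfr(function(start, end, peak_start, peak_end, ...) {
      d <- mapped$distance[mapped$.key >= peak_start &
                             mapped$.key <= peak_end]
      n_all <- sum(mapped$.key >= start & mapped$.key <= end)
      tibble(start = start, end = end,
             median_distance = median(d), n_pairs = n_all,
             z = (median(d) - stats$mean_distance) / stats$sd_distance)
    })
}

#' @export
print.evo_scan <- function(x, ...) {
  cat(sprintf("<evo_scan> %d windows scored, %d flagged, %d merged region(s)\n",
              nrow(x$windows), sum(x$windows$flagged), nrow(x$regions)))
  if (nrow(x$regions)) print(x$regions)
  invisible(x)
}

#' Classify a flagged region as a large insertion or deletion
#'
#' The sign of (regional median distance - global mean) gives the event kind:
#' spanning pairs stretch across a deletion (median above the mean) and
#' shorten across an insertion. The size estimate is the absolute deviation.
#' When enough pairs in (or near) the region have a counterpart read mapping
#' into one IS element, the insertion is classified as an IS-element
#' insertion. Insertions whose size approaches the library fragment length
#' lose their both-flank spanning pairs, so the raw estimate is biased low;
#' such calls carry `censored = TRUE`
#' (`insert_mean < size + 2 * read_length + 3 * insert_sd`).
#'
#' @param region One row of `scan$regions`.
#' @param pairs The pair tibble the scan ran on.
#' @param stats Global distance statistics.
#' @param is_catalog Optional IS catalog tibble (column `name`), used only to
#'   restrict counterpart names to known elements.
#' @param min_is_support Minimum counterpart pairs naming one IS element.
#' @param read_length Library read length in bp (for the censoring check).
#' @param insert_sd Library insert SD in bp (for the censoring check).
#' @param pad Extra bp around the region when collecting counterpart reads
#'   and breakpoint evidence.
#' @return A one-row tibble of class shared with [classify_regions()]:
#'   `kind`, `position` (breakpoint estimate), `size_estimate`, `is_element`,
#'   `support`, `z`, `censored`, `ambiguous_is`.
#' @export
classify_large_indel <- function(region, pairs, stats, is_catalog = NULL,
                                 min_is_support = 3, read_length = 50,
                                 insert_sd = stats$sd_distance,
                                 pad = stats$mean_distance) {
  delta <- region$median_distance - stats$mean_distance
  kind <- if (delta > 0) "deletion" else "insertion"
  size <- abs(delta)

  lo <- region$start - pad
  hi <- region$end + pad
  in_rng <- function(p) !is.na(p) & p >= lo & p <= hi
  near <- filter(pairs, in_rng(.data$left_pos) | in_rng(.data$right_pos))
  anom <- filter(near, !is.na(.data$distance),
                 abs(.data$distance - stats$mean_distance) >
                   3 * stats$sd_distance)
  # breakpoint: the anomalous pairs' read ends that fall inside the region
  # cluster at the local breakpoint (their mates may map far away)
  ends <- c(anom$left_pos, anom$right_pos)
  ends <- ends[!is.na(ends) & ends >= region$start & ends <= region$end]
  position <- if (length(ends)) {
    as.integer(round(median(ends)))
  } else {
    as.integer(round((region$start + region$end) / 2))
  }

  # counterpart-read evidence: pairs with one read in an IS element
  is_element <- NA_character_
  ambiguous <- FALSE
  cp <- filter(near, !is.na(.data$counterpart_locus))
  if (!is.null(is_catalog)) {
    cp <- filter(cp, .data$counterpart_locus %in% is_catalog$name)
  }
  if (nrow(cp)) {
    tab <- sort(table(cp$counterpart_locus), decreasing = TRUE)
    if (tab[1] >= min_is_support) {
      is_element <- names(tab)[1]
      ambiguous <- length(tab) > 1 && tab[2] >= min_is_support
    }
  }
  # counterpart reads into an IS element mean inserted novel sequence: an
  # insertion, whatever the sign of the (source-locus-contaminated) median
  if (!is.na(is_element) && kind == "deletion") {
    kind <- "insertion"
    size <- NA_real_ # median reflects the source-locus distance, not a size
  }
  censored <- kind == "insertion" &&
    (is.na(size) ||
       stats$mean_distance < size + 2 * read_length + 3 * insert_sd)

  tibble(kind = kind, position = position, size_estimate = size,
         is_element = is_element, support = nrow(anom),
         z = region$z, censored = censored, ambiguous_is = ambiguous)
}

#' Classify every flagged region of a distance scan
#'
#' @param scan An `evo_scan` from [scan_distance_deviation()].
#' @param pairs The pair tibble the scan ran on.
#' @param is_catalog Optional IS catalog tibble.
#' @param ... Passed on to [classify_large_indel()].
#' @return A tibble of large-indel calls, one row per region.
#' @export
classify_regions <- function(scan, pairs, is_catalog = NULL, ...) {
  regions <- scan$regions
  # counterpart reads flag a shadow region at the IS element's resident
  # source copy as well as at the insertion itself; calls at a source locus
  # are artifacts of the element's own sequence and are suppressed
  if (!is.null(is_catalog) && "source_start" %in% names(is_catalog) &&
      nrow(regions)) {
    src <- filter(is_catalog, !is.na(.data$source_start))
    shadow <- purrr::map_lgl(seq_len(nrow(regions)), function(i) {
      any(src$source_start <= regions$end[i] &
            src$source_start + src$length - 1L >= regions$start[i])
    })
    regions <- regions[!shadow, ]
  }
  if (!nrow(regions)) {
    return(tibble(kind = character(), position = integer(),
                  size_estimate = numeric(), is_element = character(),
                  support = integer(), z = numeric(), censored = logical(),
                  ambiguous_is = logical()))
  }
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    classify_large_indel(regions[i, ], pairs, scan$stats,
                         is_catalog = is_catalog, ...)
  })
}

#' Per-window read-depth profile
#'
#' Counts read starts (both ends of every mapped pair) in non-overlapping
#' windows and converts counts to fold coverage
#' (`count * read_length / window_size`).
#'
#' @param pairs A pair tibble.
#' @param window_size Window width in bp.
#' @param read_length Read length in bp.
#' @param genome_length Optional reference length; default spans the data.
#' @return A tibble of class `evo_coverage`: `start`, `end`, `n_starts`,
#'   `coverage`.
#' @export
coverage_profile <- function(pairs, window_size = 5000, read_length = 50,
                             genome_length = NULL) {
  starts <- c(pairs$left_pos, pairs$right_pos)
  starts <- starts[!is.na(starts)]
  L <- genome_length %||% if (length(starts)) max(starts) else window_size
  n_win <- max(1L, ceiling(L / window_size))
  counts <- tabulate(pmin(floor((starts - 1) / window_size) + 1L, n_win),
                     nbins = n_win)
  out <- tibble(start = (seq_len(n_win) - 1L) * window_size + 1L,
                end = pmin(seq_len(n_win) * window_size, as.integer(L)),
                n_starts = counts,
                coverage = counts * read_length / window_size)
  class(out) <- c("evo_coverage", class(out))
  out
}

#' Detect duplicated regions from a read-depth profile
#'
#' Reports maximal runs of at least `min_consecutive_windows` windows whose
#' coverage is at least `ratio_threshold` times the genome-wide median
#' window coverage. A single-copy tandem duplication carried by the whole
#' population doubles coverage (ratio ~ 2).
#'
#' @param profile An `evo_coverage` tibble from [coverage_profile()].
#' @param ratio_threshold Minimum coverage ratio vs the genome median.
#' @param min_consecutive_windows Minimum run length in windows.
#' @return A tibble of duplication calls: `start`, `end`, `length_bp`,
#'   `n_windows`, `mean_ratio`.
#' @export
detect_duplication <- function(profile, ratio_threshold = 1.5,
                               min_consecutive_windows = 10) {
  if (!nrow(profile)) {
    abort("empty coverage profile", class = "evotrace_invalid_argument")
  }
  med <- median(profile$coverage)
  if (med <= 0) {
    abort("genome median coverage is zero",
          class = "evotrace_insufficient_data")
  }
  ratio <- profile$coverage / med
  r <- rle(ratio >= ratio_threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_consecutive_windows
  purrr::map_dfr(which(keep), function(i) {
    idx <- seq(starts[i], ends[i])
    tibble(start = profile$start[starts[i]], end = profile$end[ends[i]],
           length_bp = profile$end[ends[i]] - profile$start[starts[i]] + 1L,
           n_windows = length(idx),
           mean_ratio = mean(ratio[idx]))
  })
}
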