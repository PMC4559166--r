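#' Configuration for the in-silico sequencing simulators
#'
#' Bundles the library and error parameters shared by [simulate_mate_pairs()]
#' and [simulate_pileups()]. The defaults follow a SOLiD-style mate-pair
#' library (2 x 50 bp reads, 1200 bp insert); an insert-size SD of 100 bp is a
#' free parameter of the simulator. A MiSeq-style profile is
#' `read_sim_config(insert_mean = 600, insert_sd = 60, read_length = 250)`.
#'
#' @param insert_mean Mean outer fragment length in bp (> 2 x `read_length`).
#' @param insert_sd SD of the fragment length in bp.
#' @param read_length Read length in bp.
#' @param pair_coverage Fold read coverage the pair simulator targets.
#' @param base_error_rate Per-base miscall probability in `[0, 1)`.
#' @param low_mapq_rate Fraction of pairs given a sub-threshold mapping quality.
#' @param low_baseq_rate Fraction of pairs given a sub-threshold base quality.
#' @param seed Default integer seed for simulators using this config.
#' @return A list of class `evo_read_config`.
#' @export
read_sim_config <- function(insert_mean = 1200, insert_sd = 100,
                            read_length = 50, pair_coverage = 50,
                            base_error_rate = 0.005,
                            low_mapq_rate = 0.02, low_baseq_rate = 0.02,
                            seed = 1L) {
  assert_scalar_number(insert_mean, "insert_mean",
                       lower = 2 * read_length, strict_lower = TRUE)
  assert_scalar_number(insert_sd, "insert_sd", lower = 0)
  assert_scalar_number(pair_coverage, "pair_coverage", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(base_error_rate, "base_error_rate", lower = 0,
                       upper = 1, strict_upper = TRUE)
  structure(list(insert_mean = insert_mean, insert_sd = insert_sd,
                 read_length = as.integer(read_length),
                 pair_coverage = pair_coverage,
                 base_error_rate = base_error_rate,
                 low_mapq_rate = low_mapq_rate,
                 low_baseq_rate = low_baseq_rate, seed = seed),
            class = "evo_read_config")
}

#' Simulate reference-mapped mate pairs from a sample genome
#'
#' Fragments are drawn with length ~ Normal(`insert_mean`, `insert_sd`) and
#' placed uniformly on the *sample* genome; each end read is then mapped back
#' to *reference* coordinates through the sample's lift-over, emulating
#' alignment of reads from a mutated genome against the unmutated reference.
#' A read lying at least 50 % inside inserted novel sequence is reported as a
#' counterpart read: when the insertion came from the IS catalog the read maps
#' to the element's resident source copy on the reference (so the pair gets a
#' genome-scale mapped distance, the signature real IS transpositions leave in
#' mate-pair data) and carries the element name in `counterpart_locus`;
#' novel sequence with no catalog source is unmapped.
#' The reported `distance` is the outer distance: leftmost mapped base of one
#' read to the rightmost mapped base of its mate, inclusive, so an event-free
#' pair has distance equal to its fragment length.
#'
#' @param sample An `evo_sample` from [plant_events()].
#' @param config An `evo_read_config`.
#' @param n_pairs Number of pairs; default derives from `pair_coverage`.
#' @param seed Integer seed (default `config$seed`).
#' @return A tibble of class `evo_pairs` with columns `pair_id`, `left_pos`,
#'   `right_pos`, `distance`, `anchor_pos`, `mapq`, `min_baseq`,
#'   `counterpart_locus`, `flag` (`"proper"`, `"counterpart"`, `"unmapped"`).
#' @export
simulate_mate_pairs <- function(sample, config = read_sim_config(),
                                n_pairs = NULL, seed = config$seed) {
  stopifnot(inherits(sample, "evo_sample"))
  Ls <- sample$length
  R <- config$read_length
  n <- n_pairs %||% round(config$pair_coverage * Ls / (2 * R))
  if (config$insert_mean + 6 * config$insert_sd >= Ls) {
    abort("fragments longer than the genome", class = "evotrace_invalid_argument")
  }
  with_seed(seed, {
    flen <- pmax(round(rnorm(n, config$insert_mean, config$insert_sd)),
                 2 * R)
    start <- floor(runif(n, 1, Ls - flen + 1))
    l_start <- start
    l_end <- start + R - 1L
    r_start <- start + flen - R
    r_end <- start + flen - 1L

    fp <- sample$footprints
    catalog <- sample$reference$is_catalog
    if (!"source_start" %in% names(catalog)) {
      catalog$source_start <- NA_integer_
    }
    fp$source_start <- catalog$source_start[match(fp$is_name, catalog$name)]
    novel_bp <- function(s, e) {
      ov <- numeric(length(s))
      for (i in seq_len(nrow(fp))) {
        ov <- ov + pmax(0, pmin(e, fp$samp_end[i]) -
                          pmax(s, fp$samp_start[i]) + 1)
      }
      ov
    }
    fp_name <- function(s, e) {
      nm <- rep(NA_character_, length(s))
      for (i in seq_len(nrow(fp))) {
        hit <- pmin(e, fp$samp_end[i]) >= pmax(s, fp$samp_start[i])
        nm[hit & is.na(nm)] <- fp$is_name[i]
      }
      nm
    }
    # counterpart mapping: a read from a transposed IS copy aligns to the
    # element's resident source locus on the reference
    fp_source_pos <- function(s, e) {
      pos <- rep(NA_integer_, length(s))
      for (i in seq_len(nrow(fp))) {
        if (is.na(fp$source_start[i])) next
        hit <- pmin(e, fp$samp_end[i]) >= pmax(s, fp$samp_start[i]) &
          is.na(pos)
        pos[hit] <- fp$source_start[i] +
          pmax(s[hit] - fp$samp_start[i], 0L)
      }
      pos
    }
    # move an anchor that starts/ends inside novel sequence to its edge
    adjust_fwd <- function(p) { # start anchors step right, out of the footprint
      for (i in seq_len(nrow(fp))) {
        inside <- p >= fp$samp_start[i] & p <= fp$samp_end[i]
        p[inside] <- fp$samp_end[i] + 1L
      }
      p
    }
    adjust_rev <- function(p) { # end anchors step left
      for (i in seq_len(nrow(fp))) {
        inside <- p >= fp$samp_start[i] & p <= fp$samp_end[i]
        p[inside] <- fp$samp_start[i] - 1L
      }
      p
    }

    left_novel <- novel_bp(l_start, l_end) >= R / 2
    right_novel <- novel_bp(r_start, r_end) >= R / 2

    left_pos <- right_pos <- rep(NA_integer_, n)
    ok_l <- !left_novel
    ok_r <- !right_novel
    left_pos[ok_l] <- sample_to_ref(sample, adjust_fwd(l_start[ok_l]))
    right_pos[ok_r] <- sample_to_ref(sample, adjust_rev(r_end[ok_r]))
    left_pos[left_novel] <- fp_source_pos(l_start[left_novel],
                                          l_end[left_novel])
    right_pos[right_novel] <- fp_source_pos(r_start[right_novel],
                                            r_end[right_novel])

    cp <- rep(NA_character_, n)
    cp[left_novel] <- fp_name(l_start[left_novel], l_end[left_novel])
    cp[right_novel & is.na(cp)] <-
      fp_name(r_start[right_novel & is.na(cp)], r_end[right_novel & is.na(cp)])

    both <- !is.na(left_pos) & !is.na(right_pos)
    # a pair straddling a tandem-duplication junction can map in reversed
    # order; report coordinates sorted, as an aligner would. For single-end
    # (counterpart) pairs both columns carry the one mapped coordinate.
    lp <- pmin(left_pos, right_pos, na.rm = TRUE)
    rp <- pmax(left_pos, right_pos, na.rm = TRUE)
    lp[is.na(left_pos) & is.na(right_pos)] <- NA_integer_
    rp[is.na(left_pos) & is.na(right_pos)] <- NA_integer_
    distance <- ifelse(both, rp - lp + 1L, NA_integer_)

    # scan key: the fragment's flank-side mapped read. For concordant pairs
    # this is the leftmost read; for counterpart pairs it is the read that
    # stayed outside the novel sequence, so the anomalous distance is keyed
    # at the insertion site, not at the IS source locus
    anchor <- lp
    anchor[left_novel & !right_novel] <- right_pos[left_novel & !right_novel]
    anchor[right_novel & !left_novel] <- left_pos[right_novel & !left_novel]

    flag <- dplyr::case_when(
      !is.na(cp) ~ "counterpart",
      both ~ "proper",
      TRUE ~ "unmapped"
    )
    mapq <- ifelse(runif(n) < config$low_mapq_rate,
                   sample(0:9, n, replace = TRUE), 60L)
    min_baseq <- ifelse(runif(n) < config$low_baseq_rate,
                        sample(20:29, n, replace = TRUE), 37L)

    out <- tibble(
      pair_id = seq_len(n),
      left_pos = as.integer(lp), right_pos = as.integer(rp),
      distance = as.integer(distance),
      anchor_pos = as.integer(anchor),
      mapq = as.integer(mapq), min_baseq = as.integer(min_baseq),
      counterpart_locus = cp, flag = flag
    )
    out <- filter(out, .data$flag != "unmapped" | !is.na(.data$anchor_pos))
    class(out) <- c("evo_pairs", class(out))
    attr(out, "config") <- config
    out
  })
}

#' Simulate per-site pileup counts for a sequenced population
#'
#' Per reference site, depth is Poisson(`coverage`), reduced across fixed
#' large-deletion footprints and raised across duplications in proportion to
#' the event's population frequency. Variant-supporting read counts are
#' binomial given depth, with success probability
#' `f * (1 - e) + (1 - f) * e` at SNV sites (`f` = population allele
#' fraction, `e` = per-base error rate) and `e` elsewhere. Small indels emit
#' indel-evidence counts at their position (reads spanning a short gap still
#' align across it, so depth there is not reduced).
#'
#' @param population A single `evo_sample` or a list of
#'   `list(sample = <evo_sample>, freq = <number>)` whose `freq` sum to 1.
#' @param config An `evo_read_config` (supplies `base_error_rate`).
#' @param coverage Mean fold coverage (default `config$pair_coverage`).
#' @param platform Label stored on every row (e.g. `"SOLiD"`, `"MiSeq"`).
#' @param seed Integer seed.
#' @return A tibble of class `evo_pileup`: `pos`, `ref`, `depth`,
#'   `variant_count`, `alt`, `indel_len`, `indel_count`, `platform`.
#' @export
simulate_pileups <- function(population, config = read_sim_config(),
                             coverage = config$pair_coverage,
                             platform = "SOLiD", seed = config$seed) {
  if (inherits(population, "evo_sample")) {
    population <- list(list(sample = population, freq = 1))
  }
  if (!length(population)) {
    abort("empty population", class = "evotrace_invalid_argument")
  }
  freqs <- vapply(population, function(m) m$freq, numeric(1))
  if (abs(sum(freqs) - 1) > 1e-8) {
    abort("population frequencies must sum to 1",
          class = "evotrace_invalid_argument")
  }
  ref <- population[[1L]]$sample$reference
  L <- ref$length
  e <- config$base_error_rate

  # aggregate per-site allele fractions across population members
  snv_f <- numeric(0); snv_pos <- integer(0); snv_alt <- character(0)
  indel_tab <- list()
  mult <- rep(1, L)
  for (m in population) {
    tr <- m$sample$truth
    for (i in seq_len(nrow(tr))) {
      k <- tr$kind[i]; p <- tr$position[i]; Lv <- tr$length[i]
      f <- m$freq * tr$allele_fraction[i]
      if (k == "snv") {
        j <- match(p, snv_pos)
        if (is.na(j)) {
          snv_pos <- c(snv_pos, p); snv_f <- c(snv_f, f)
          snv_alt <- c(snv_alt, tr$alt[i])
        } else snv_f[j] <- snv_f[j] + f
      } else if (k %in% c("small_insertion", "small_deletion")) {
        sgn <- if (k == "small_deletion") -Lv else Lv
        indel_tab[[length(indel_tab) + 1L]] <-
          tibble(pos = p, indel_len = as.integer(sgn), f = f)
      } else if (k == "large_deletion") {
        mult[p:(p + Lv - 1L)] <- mult[p:(p + Lv - 1L)] - f
      } else if (k == "duplication") {
        mult[p:(p + Lv - 1L)] <- mult[p:(p + Lv - 1L)] + f
      }
    }
  }
  indels <- if (length(indel_tab)) {
    group_by(bind_rows(indel_tab), .data$pos, .data$indel_len) |>
      summarise(f = sum(.data$f), .groups = "drop")
  } else tibble(pos = integer(), indel_len = integer(), f = numeric())

  with_seed(seed, {
    depth <- rpois(L, coverage * pmax(mult, 0))
    p_var <- rep(e, L)
    p_var[snv_pos] <- snv_f * (1 - e) + (1 - snv_f) * e
    variant_count <- rbinom(L, depth, p_var)
    alt <- rep(NA_character_, L)
    alt[snv_pos] <- snv_alt
    indel_len <- rep(NA_integer_, L)
    indel_count <- rep(0L, L)
    if (nrow(indels)) {
      indel_len[indels$pos] <- indels$indel_len
      indel_count[indels$pos] <-
        rbinom(nrow(indels), depth[indels$pos],
               indels$f * (1 - e) + (1 - indels$f) * e)
    }
    out <- tibble(
      pos = seq_len(L),
      ref = strsplit(ref$sequence, "", fixed = TRUE)[[1L]],
      depth = as.integer(depth),
      variant_count = as.integer(variant_count),
      alt = alt,
      indel_len = indel_len,
      indel_count = as.integer(indel_count),
      platform = platform
    )
    class(out) <- c("evo_pileup", class(out))
    out
  })
}
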