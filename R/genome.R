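#' Generate a synthetic bacterial reference genome
#'
#' Draws a random nucleotide sequence with a target GC content, places
#' non-overlapping gene annotations on it, and attaches a catalog of
#' insertion-sequence (IS) elements whose sequences can later be planted as
#' large insertions. The IS catalog carries an IS5-like element (1199 bp) and
#' an IS186-like element (1343 bp), the two element families that dominate
#' transposition events in long-term *E. coli* cultures.
#'
#' @param length Genome length in bp (> 0).
#' @param gc_fraction Target GC content in (0, 1).
#' @param n_genes Number of non-overlapping gene annotations to place.
#' @param seed Integer seed; output is reproducible for a fixed seed.
#' @param gene_length Typical gene length in bp used when placing annotations.
#'
#' @return An object of class `evo_genome`: a list with `sequence` (character
#'   scalar), `length`, `genes` (tibble: name, start, end, strand; 1-based
#'   closed intervals), and `is_catalog` (tibble: name, length, sequence).
#' @export
#' @examples
#' g <- generate_reference(10000, 0.5, n_genes = 5, seed = 1)
#' g$length
generate_reference <- function(length, gc_fraction = 0.508, n_genes = 20,
                               seed = 1, gene_length = 900) {
  assert_scalar_number(length, "length", lower = 1)
  assert_scalar_number(gc_fraction, "gc_fraction", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(n_genes, "n_genes", lower = 0)
  length <- as.integer(length)
  with_seed(seed, {
    sequence <- random_dna(length, gc_fraction)
    genes <- place_genes(length, n_genes, gene_length)
    is_catalog <- tibble(
      name = c("IS5", "IS186"),
      length = c(1199L, 1343L),
      sequence = c(random_dna(1199L, gc_fraction),
                   random_dna(1343L, gc_fraction))
    )
    # bacterial chromosomes carry resident copies of their IS elements; embed
    # one source copy of each so reads from transposed copies have a locus to
    # map back to (counterpart-read evidence). Skipped on very short genomes.
    is_catalog$source_start <- NA_integer_
    if (length >= 30000L) {
      src <- as.integer(round(c(0.02, 0.06) * length))
      for (i in seq_len(nrow(is_catalog))) {
        is_catalog$source_start[i] <- src[i]
        sequence <- paste0(
          substr(sequence, 1L, src[i] - 1L), is_catalog$sequence[i],
          substr(sequence, src[i] + is_catalog$length[i], length))
      }
    }
    structure(
      list(sequence = sequence, length = length, genes = genes,
           is_catalog = is_catalog, gc_fraction = gc_fraction, seed = seed),
      class = "evo_genome"
    )
  })
}

place_genes <- function(genome_length, n_genes, gene_length) {
  if (n_genes == 0L) {
    return(tibble(name = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  len <- pmin(pmax(round(rnorm(n_genes, gene_length, gene_length / 5)), 90),
              genome_length)
  # greedy placement on an even grid with jitter keeps genes non-overlapping
  slot <- floor(genome_length / n_genes)
  start <- pmax(1L, (seq_len(n_genes) - 1L) * slot +
                  floor(runif(n_genes, 1, pmax(2, slot - len))))
  end <- pmin(start + as.integer(len) - 1L, genome_length)
  keep <- c(TRUE, start[-1] > head(end, -1))
  tibble(
    name = sprintf("gene%03d", seq_len(n_genes)),
    start = as.integer(start), end = as.integer(end),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )[keep, ]
}

#' @export
print.evo_genome <- function(x, ...) {
  cat(sprintf("<evo_genome> %s bp, GC target %.3f, %d genes, %d IS elements\n",
              format(x$length, big.mark = ","), x$gc_fraction,
              nrow(x$genes), nrow(x$is_catalog)))
  invisible(x)
}

#' Construct a table of mutation events to plant
#'
#' Events use 1-based reference coordinates. Insertions are placed *after*
#' `position`; deletions and duplications start *at* `position`. Small events
#' are < 500 bp, large events >= 500 bp (insertions of IS elements are large
#' by construction). `alt` holds the replacement base for SNVs, the inserted
#' sequence for small insertions, or the IS-element name for large insertions.
#'
#' @param kind One of `"snv"`, `"small_insertion"`, `"small_deletion"`,
#'   `"large_insertion"`, `"large_deletion"`, `"duplication"`.
#' @param position 1-based reference coordinate.
#' @param length Event length in bp (0 for SNVs; for small insertions it may
#'   be omitted and is taken from `nchar(alt)`).
#' @param alt Replacement base, inserted sequence, or IS name (see above).
#' @param allele_fraction Fraction of the population carrying the event.
#'
#' @return A one-row tibble; bind rows to build an event set.
#' @export
planted_event <- function(kind, position, length = 0L, alt = NA_character_,
                          allele_fraction = 1) {
  kinds <- c("snv", "small_insertion", "small_deletion",
             "large_insertion", "large_deletion", "duplication")
  if (!kind %in% kinds) {
    abort(sprintf("unknown event kind '%s'", kind),
          class = "evotrace_invalid_argument")
  }
  if (kind == "small_insertion" && (is.na(length) || length == 0L) &&
      !is.na(alt)) {
    length <- nchar(alt)
  }
  assert_scalar_number(position, "position", lower = 1)
  assert_scalar_number(length, "length", lower = 0)
  assert_scalar_number(allele_fraction, "allele_fraction", lower = 0, upper = 1)
  if (grepl("small", kind) && length >= 500) {
    abort("small events must be < 500 bp", class = "evotrace_invalid_argument")
  }
  if (grepl("large|duplication", kind) && length < 500) {
    abort("large events must be >= 500 bp", class = "evotrace_invalid_argument")
  }
  tibble(kind = kind, position = as.integer(position),
         length = as.integer(length), alt = alt,
         allele_fraction = allele_fraction)
}

# signed length change an event causes on the sample sequence
event_delta <- function(kind, length) {
  dplyr::case_when(
    kind == "snv" ~ 0L,
    kind %in% c("small_insertion", "large_insertion", "duplication") ~ length,
    kind %in% c("small_deletion", "large_deletion") ~ -length,
    TRUE ~ 0L
  )
}

# reference footprint occupied by the event (1-based closed); insertions
# occupy the junction base so overlap checks catch events at the same spot
event_footprint <- function(events) {
  mutate(events,
         fp_start = .data$position,
         fp_end = if_else(.data$kind %in% c("small_deletion", "large_deletion",
                                            "duplication"),
                          .data$position + .data$length - 1L, .data$position))
}

#' Plant mutation events into a reference genome
#'
#' Edits the reference sequence right-to-left so that earlier coordinates stay
#' valid, and records a truth table plus a piecewise-monotone coordinate
#' lift-over between reference and sample coordinates. Large insertions pull
#' their sequence from the genome's IS catalog (truncated to the event length
#' when the catalog element is longer). Tandem duplications append a second
#' copy of the duplicated interval immediately after the first.
#'
#' @param genome An `evo_genome` from [generate_reference()].
#' @param events A tibble of events as built by [planted_event()].
#'
#' @return An object of class `evo_sample`: list with `sequence`, `length`,
#'   `truth` (the event table with realised `alt` values), `segments`
#'   (the lift-over map), `footprints` (novel inserted intervals in sample
#'   coordinates) and `reference` (the input genome).
#' @export
plant_events <- function(genome, events) {
  stopifnot(inherits(genome, "evo_genome"))
  if (nrow(events) == 0L) {
    events <- tibble(kind = character(), position = integer(),
                     length = integer(), alt = character(),
                     allele_fraction = numeric())
  }
  assert_columns(events, c("kind", "position", "length", "alt",
                           "allele_fraction"), "events")
  events <- arrange(events, .data$position)
  fp <- event_footprint(events)
  if (nrow(fp) > 1L && any(fp$fp_start[-1] <= head(fp$fp_end, -1))) {
    abort("planted events overlap on the reference",
          class = "evotrace_conflict")
  }
  if (nrow(fp) && (max(fp$fp_end) > genome$length || min(fp$fp_start) < 1)) {
    abort("event footprint outside the reference",
          class = "evotrace_invalid_argument")
  }

  # resolve inserted sequences and SNV alts up-front
  ins_seq <- character(nrow(events))
  alt <- events$alt
  for (i in seq_len(nrow(events))) {
    k <- events$kind[i]
    if (k == "large_insertion") {
      hit <- match(events$alt[i], genome$is_catalog$name)
      if (is.na(hit)) {
        abort(sprintf("unknown IS element '%s'", events$alt[i]),
              class = "evotrace_invalid_argument")
      }
      cat_seq <- genome$is_catalog$sequence[hit]
      if (events$length[i] > nchar(cat_seq)) {
        abort("large insertion longer than its IS catalog element",
              class = "evotrace_invalid_argument")
      }
      ins_seq[i] <- substr(cat_seq, 1L, events$length[i])
    } else if (k == "small_insertion") {
      ins_seq[i] <- events$alt[i]
    } else if (k == "snv") {
      ref_base <- substr(genome$sequence, events$position[i], events$position[i])
      if (is.na(alt[i]) || alt[i] == ref_base) {
        # keep the planted change real: rotate to the next base
        alt[i] <- DNA_BASES[match(ref_base, DNA_BASES) %% 4L + 1L]
      }
    }
  }
  events$alt <- alt

  # edit right-to-left
  seq <- genome$sequence
  for (i in rev(seq_len(nrow(events)))) {
    p <- events$position[i]
    L <- events$length[i]
    seq <- switch(
      events$kind[i],
      snv = paste0(substr(seq, 1L, p - 1L), events$alt[i],
                   substr(seq, p + 1L, nchar(seq))),
      small_insertion = ,
      large_insertion = paste0(substr(seq, 1L, p), ins_seq[i],
                               substr(seq, p + 1L, nchar(seq))),
      small_deletion = ,
      large_deletion = paste0(substr(seq, 1L, p - 1L),
                              substr(seq, p + L, nchar(seq))),
      duplication = paste0(substr(seq, 1L, p + L - 1L),
                           substr(seq, p, p + L - 1L),
                           substr(seq, p + L, nchar(seq)))
    )
  }

  lift <- build_liftover(genome$length, events)
  truth <- mutate(events, ref_base = ifelse(
    .data$kind == "snv",
    substr(genome$sequence, .data$position, .data$position), NA_character_))

  structure(
    list(sequence = seq, length = nchar(seq), truth = truth,
         segments = lift$segments, footprints = lift$footprints,
         reference = genome),
    class = "evo_sample"
  )
}

# segments: piecewise map between reference and sample coordinates.
# type "match": samp = ref + offset. type "dup": second copy mapping back.
# footprints: inserted novel sample intervals with the IS name when relevant.
build_liftover <- function(ref_length, events) {
  segs <- list()
  fps <- list()
  off <- 0L
  prev_ref <- 1L
  add_match <- function(ref_from, ref_to) {
    if (ref_to >= ref_from) {
      segs[[length(segs) + 1L]] <<- tibble(
        samp_start = ref_from + off, samp_end = ref_to + off,
        ref_start = ref_from, ref_end = ref_to, type = "match")
    }
  }
  for (i in seq_len(nrow(events))) {
    k <- events$kind[i]; p <- events$position[i]; L <- events$length[i]
    if (k == "snv") next
    if (k %in% c("small_insertion", "large_insertion")) {
      add_match(prev_ref, p)
      fps[[length(fps) + 1L]] <- tibble(
        samp_start = p + off + 1L, samp_end = p + off + L,
        is_name = if (k == "large_insertion") events$alt[i] else NA_character_,
        ref_anchor = p)
      off <- off + L
      prev_ref <- p + 1L
    } else if (k %in% c("small_deletion", "large_deletion")) {
      add_match(prev_ref, p - 1L)
      off <- off - L
      prev_ref <- p + L
    } else if (k == "duplication") {
      add_match(prev_ref, p + L - 1L)
      segs[[length(segs) + 1L]] <- tibble(
        samp_start = p + L + off, samp_end = p + 2L * L - 1L + off,
        ref_start = p, ref_end = p + L - 1L, type = "dup")
      off <- off + L
      prev_ref <- p + L
    }
  }
  add_match(prev_ref, ref_length)
  segments <- bind_rows(segs)
  footprints <- if (length(fps)) bind_rows(fps) else {
    tibble(samp_start = integer(), samp_end = integer(),
           is_name = character(), ref_anchor = integer())
  }
  list(segments = segments, footprints = footprints)
}

#' Map coordinates between reference and sample genomes
#'
#' `ref_to_sample()` maps reference positions to sample positions (positions
#' deleted from the sample map to `NA`; duplicated positions map to the first
#' copy). `sample_to_ref()` maps sample positions back to the reference
#' (positions inside inserted novel sequence map to `NA`; the second copy of a
#' duplication maps back onto the original interval). Outside event
#' footprints the two are exact inverses.
#'
#' @param sample An `evo_sample` from [plant_events()].
#' @param pos Integer vector of positions (1-based).
#' @return Integer vector of mapped positions, `NA` where unmappable.
#' @export
ref_to_sample <- function(sample, pos) {
  segs <- filter(sample$segments, .data$type == "match")
  idx <- findInterval(pos, segs$ref_start)
  out <- rep(NA_integer_, length(pos))
  ok <- !is.na(pos) & idx >= 1L & pos <= segs$ref_end[pmax(idx, 1L)]
  out[ok] <- segs$samp_start[idx[ok]] + (pos[ok] - segs$ref_start[idx[ok]])
  out
}

#' @rdname ref_to_sample
#' @export
sample_to_ref <- function(sample, pos) {
  segs <- arrange(sample$segments, .data$samp_start)
  idx <- findInterval(pos, segs$samp_start)
  out <- rep(NA_integer_, length(pos))
  ok <- !is.na(pos) & idx >= 1L & pos <= segs$samp_end[pmax(idx, 1L)]
  out[ok] <- segs$ref_start[idx[ok]] + (pos[ok] - segs$samp_start[idx[ok]])
  out
}

#' @export
print.evo_sample <- function(x, ...) {
  cat(sprintf("<evo_sample> %s bp (reference %s bp), %d planted event(s)\n",
              format(x$length, big.mark = ","),
              format(x$reference$length, big.mark = ","), nrow(x$truth)))
  invisible(x)
}
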