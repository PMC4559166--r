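#' Write a genome (or sample genome) as FASTA
#'
#' Uses Biostrings when available; otherwise writes 70-column wrapped FASTA
#' directly.
#'
#' @param x An `evo_genome` or `evo_sample`.
#' @param path Output file.
#' @param name Sequence name in the header.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(x, path, name = "synthetic") {
  seq <- if (inherits(x, "evo_sample")) x$sequence else x$sequence
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::DNAStringSet(stats::setNames(seq, name))
    Biostrings::writeXStringSet(ss, path)
  } else {
    chunks <- substring(seq, seq(1, nchar(seq), 70),
                        pmin(seq(1, nchar(seq), 70) + 69, nchar(seq)))
    writeLines(c(paste0(">", name), chunks), path)
  }
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file (single sequence).
#' @return An `evo_genome` with an empty gene table and the default IS catalog
#'   names (no sequences).
#' @export
read_genome_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    seq <- as.character(ss[[1L]])
  } else {
    lines <- readLines(path)
    seq <- paste(lines[!startsWith(lines, ">")], collapse = "")
  }
  structure(list(sequence = seq, length = nchar(seq),
                 genes = tibble(name = character(), start = integer(),
                                end = integer(), strand = character()),
                 is_catalog = tibble(name = character(), length = integer(),
                                     sequence = character()),
                 gc_fraction = NA_real_, seed = NA_integer_),
            class = "evo_genome")
}

#' Write and read a planted-event truth table as TSV
#'
#' Columns: kind, ref_pos_1based, length, alt, allele_fraction.
#' @param truth Truth tibble (from an `evo_sample`).
#' @param path TSV file.
#' @return `path` invisibly / the truth tibble.
#' @export
write_truth_tsv <- function(truth, path) {
  out <- tibble(kind = truth$kind, ref_pos_1based = truth$position,
                length = truth$length, alt = truth$alt,
                allele_fraction = truth$allele_fraction)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    dplyr::rename(position = "ref_pos_1based")
}

#' Write and read mapped pairs as TSV
#'
#' @param pairs Pair tibble.
#' @param path TSV file.
#' @return `path` invisibly / a pair tibble.
#' @export
write_pairs_tsv <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(out, c("left_pos", "right_pos", "mapq", "min_baseq"), "pairs")
  if (!"distance" %in% names(out)) {
    out$distance <- out$right_pos - out$left_pos + 1L
  }
  if (!"anchor_pos" %in% names(out)) {
    out$anchor_pos <- dplyr::coalesce(out$left_pos, out$right_pos)
  }
  if (!"counterpart_locus" %in% names(out)) {
    out$counterpart_locus <- NA_character_
  }
  out
}

#' Write and read mapped pairs as minimal SAM
#'
#' Emits the 11 mandatory SAM columns, one line per mapped read, with TLEN
#' carrying the signed outer distance; sequence and quality are `*`
#' placeholders (this package models mapped coordinates, not base-level
#' reads). The reader accepts any SAM whose pairs are identifiable by QNAME
#' and uses POS, PNEXT, MAPQ and TLEN only.
#'
#' @param pairs Pair tibble (both-mapped rows are written).
#' @param path SAM file.
#' @param genome_length Reference length for the `@SQ` header.
#' @param ref_name Reference sequence name.
#' @param read_length Read length used for rightmost-coordinate arithmetic.
#' @return `path` invisibly / a pair tibble.
#' @export
write_pairs_sam <- function(pairs, path, genome_length,
                            ref_name = "synthetic", read_length = 50) {
  mapped <- filter(pairs, !is.na(.data$left_pos), !is.na(.data$right_pos))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_name, as.integer(genome_length)))
  qname <- sprintf("pair%08d", mapped$pair_id)
  r1 <- sprintf("%s\t99\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*",
                qname, ref_name, mapped$left_pos, mapped$mapq, read_length,
                mapped$right_pos - read_length + 1L, mapped$distance)
  r2 <- sprintf("%s\t147\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*",
                qname, ref_name, mapped$right_pos - read_length + 1L,
                mapped$mapq, read_length, mapped$left_pos, -mapped$distance)
  writeLines(c(header, as.vector(rbind(r1, r2))), path)
  invisible(path)
}

#' @rdname write_pairs_sam
#' @export
read_pairs_sam <- function(path, read_length = 50) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  rec <- tibble(
    qname = vapply(f, `[[`, "", 1L),
    pos = as.integer(vapply(f, `[[`, "", 4L)),
    mapq = as.integer(vapply(f, `[[`, "", 5L)),
    tlen = as.integer(vapply(f, `[[`, "", 9L))
  )
  rec |>
    group_by(.data$qname) |>
    summarise(left_pos = min(.data$pos),
              right_pos = max(.data$pos) + read_length - 1L,
              distance = max(abs(.data$tlen)),
              mapq = min(.data$mapq), .groups = "drop") |>
    mutate(pair_id = row_number(),
           anchor_pos = .data$left_pos,
           min_baseq = NA_integer_,
           counterpart_locus = NA_character_,
           flag = "proper")
}

#' Read a pileup TSV
#'
#' Expected columns: `pos`, `ref`, `depth`, `variant_count`, and optionally
#' `alt`, `indel_len`, `indel_count`, `platform`.
#'
#' @param path TSV file.
#' @param platform Platform label to attach when the file lacks one.
#' @return A pileup tibble.
#' @export
read_pileup_tsv <- function(path, platform = NA_character_) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(out, c("pos", "depth", "variant_count"), "pileup")
  # columns of bare T/F bases parse as logicals; restore them
  for (col in intersect(c("ref", "alt"), names(out))) {
    if (is.logical(out[[col]])) {
      out[[col]] <- c("F", "T")[out[[col]] + 1L]
    }
  }
  if (!"platform" %in% names(out)) out$platform <- platform
  if (!"indel_len" %in% names(out)) out$indel_len <- NA_integer_
  if (!"indel_count" %in% names(out)) out$indel_count <- 0L
  out
}

#' Write point-mutation calls as a VCF-like TSV
#'
#' Columns CHROM, POS (1-based), REF, ALT, INFO (`ratio=..;depth=..;p=..;
#' platform=..`).
#'
#' @param calls Call tibble from [call_point_mutations()].
#' @param path Output TSV.
#' @param chrom Chromosome/contig label.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path, chrom = "synthetic") {
  out <- tibble(
    CHROM = chrom, POS = calls$position, REF = calls$ref, ALT = calls$alt,
    INFO = sprintf("ratio=%.4f;depth=%d;p=%.3g;platform=%s",
                   calls$ratio, calls$depth, calls$p_value, calls$platform))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write mask intervals as BED (0-based half-open)
#'
#' @param mask Mask tibble from [mask_low_coverage()] (1-based closed).
#' @param path Output BED file.
#' @param chrom Chromosome/contig label.
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(mask, path, chrom = "synthetic") {
  out <- tibble(chrom = chrom, start = mask$start - 1L, end = mask$end)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
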