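# small shared fixtures, built in code at test time

tiny_genome <- function(length = 50000, seed = 1, n_genes = 5) {
  generate_reference(length, gc_fraction = 0.5, n_genes = n_genes, seed = seed)
}

# a pileup tibble from explicit per-site counts
manual_pileup <- function(pos, depth, variant_count, ref = "A", alt = "T",
                          indel_len = NA_integer_, indel_count = 0L,
                          platform = "SOLiD") {
  tibble::tibble(pos = pos, ref = ref, depth = depth,
                 variant_count = variant_count, alt = alt,
                 indel_len = indel_len, indel_count = indel_count,
                 platform = platform)
}

# a minimal pair tibble from explicit distances
manual_pairs <- function(left_pos, distance, mapq = 60L, min_baseq = 37L,
                         counterpart = NA_character_) {
  tibble::tibble(pair_id = seq_along(left_pos),
                 left_pos = as.integer(left_pos),
                 right_pos = as.integer(left_pos + distance - 1L),
                 distance = as.integer(distance),
                 anchor_pos = as.integer(left_pos),
                 mapq = mapq, min_baseq = min_baseq,
                 counterpart_locus = counterpart,
                 flag = ifelse(is.na(counterpart), "proper", "counterpart"))
}

# synthetic point-mutation call table
manual_calls <- function(position, alt = "T", platform = "A") {
  tibble::tibble(position = as.integer(position), ref = "A", alt = alt,
                 ratio = 1, depth = 50L, p_value = 1e-20,
                 platform = platform)
}
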