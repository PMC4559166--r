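# coordinates in the fixture catalog live on the E. coli W3110 chromosome;
# they are rescaled proportionally onto the synthetic reference
W3110_LENGTH <- 4646332L

#' Built-in planted-event fixtures for evolved-strain scenarios
#'
#' Catalogs the mutation sets fixed in five independently evolved
#' ethanol-tolerant strains (B through F): SNVs, +1/+3 bp insertions, an
#' 88 bp and a 6775 bp deletion, IS5/IS186 insertions of 1195-1343 bp, and,
#' as a separate scenario, a 200 kbp tandem duplication. Genomic positions
#' are chromosome coordinates kept as metadata; [fixture_events()] rescales
#' them onto a synthetic reference. Event lengths are never rescaled.
#'
#' @return A named list of event tibbles (columns: gene, kind, w3110_pos,
#'   length, alt, allele_fraction).
#' @export
builtin_fixtures <- function() {
  fx <- function(gene, kind, pos, length, alt) {
    tibble(gene = gene, kind = kind, w3110_pos = as.integer(pos),
           length = as.integer(length), alt = alt, allele_fraction = 1)
  }
  list(
    strain_B = bind_rows(
      fx("hns", "large_insertion", 1294843, 1195, "IS5"),
      fx("yeaR", "large_insertion", 1881551, 1342, "IS186"),
      fx("iscR", "snv", 2660496, 0, "T"),
      fx("ilvG", "snv", 3685148, 0, "T")),
    strain_C = bind_rows(
      fx("nmpC_region", "large_deletion", 575013, 6775, NA),
      fx("nagE", "small_insertion", 705229, 3, "CCG"),
      fx("hns", "large_insertion", 1294843, 1195, "IS5"),
      fx("yeaY", "snv", 1892079, 0, "A"),
      fx("menC", "large_insertion", 2380504, 1343, "IS186"),
      fx("relA", "snv", 2910761, 0, "G"),
      fx("rpoC", "snv", 3448513, 0, "A"),
      fx("rpoA", "snv", 4200347, 0, "A")),
    strain_C_dup = fx("dup_region", "duplication", 1900000, 200000, NA),
    strain_D = bind_rows(
      fx("hns", "large_insertion", 1294843, 1195, "IS5"),
      fx("proQ", "snv", 1916977, 0, "T"),
      fx("ispG", "snv", 2639469, 0, "C"),
      fx("rpsD", "snv", 4198966, 0, "G"),
      fx("yjhA", "large_insertion", 4544220, 1199, "IS5")),
    strain_E = bind_rows(
      fx("hns", "large_insertion", 1294843, 1195, "IS5"),
      fx("cspC", "large_insertion", 1909109, 1199, "IS5"),
      fx("relA", "snv", 2910944, 0, "T"),
      fx("yhcM", "small_insertion", 3379114, 1, "C"),
      fx("atpE", "snv", 3715545, 0, "G")),
    strain_F = bind_rows(
      fx("miaB", "small_deletion", 694563, 88, NA),
      fx("cspC", "large_insertion", 1909109, 1199, "IS5"),
      fx("wzxC", "snv", 2120992, 0, "T"),
      fx("iscR", "snv", 2660468, 0, "A"),
      fx("relA", "snv", 2911891, 0, "G"))
  )
}

#' Rescale a fixture event set onto a synthetic reference
#'
#' Positions are mapped proportionally from chromosome coordinates onto
#' `[1, ref_length]`; event lengths stay exactly as catalogued. The reference
#' must be long enough for the rescaled footprints not to collide
#' (>= ~300 kb for the SNV/indel scenarios; >= 1 Mb for `strain_C_dup`).
#'
#' @param name Fixture name (see [builtin_fixtures()]), e.g. `"strain_F"`.
#' @param ref_length Synthetic reference length in bp.
#' @return An event tibble ready for [plant_events()].
#' @export
fixture_events <- function(name, ref_length) {
  fx <- builtin_fixtures()
  if (!name %in% names(fx)) {
    abort(sprintf("unknown fixture '%s' (have: %s)", name,
                  paste(names(fx), collapse = ", ")),
          class = "evotrace_invalid_argument")
  }
  ev <- fx[[name]] |>
    mutate(position = pmax(1L, as.integer(round(
      .data$w3110_pos / W3110_LENGTH * ref_length)))) |>
    select("kind", "position", "length", "alt", "allele_fraction", "gene",
           "w3110_pos")
  if (any(ev$position + ev$length > ref_length)) {
    abort("reference too short for this fixture's event footprints",
          class = "evotrace_invalid_argument")
  }
  ev
}

#' Configuration for an end-to-end scenario run
#'
#' Bundles the reference, sequencing and caller parameters for
#' [run_scenario()]. All thresholds default to the values used throughout the
#' package: variant ratio 0.6, depth 10, p < 1e-7, |z| > 3, mapq >= 10,
#' baseq >= 30, quantification limit 100.
#'
#' @param scenario Fixture name or `"null"` (no events planted).
#' @param ref_length Synthetic reference length in bp.
#' @param gc_fraction Reference GC content.
#' @param n_genes Gene annotations to place.
#' @param coverage Fold coverage for pileups and mate pairs.
#' @param solid,miseq Platform profiles ([read_sim_config()] objects).
#' @param caller Point-mutation/indel thresholds ([caller_config()]).
#' @param min_mapq,min_baseq Pair quality gates.
#' @param z_threshold Distance-scan deviation threshold.
#' @param dup_window,dup_ratio,dup_min_windows Duplication-detector settings.
#' @param seeds Named list of integer seeds per stage: `reference`,
#'   `pileup_a`, `pileup_b`, `pairs`.
#' @return A list of class `evo_run_config`.
#' @export
scenario_config <- function(scenario = "strain_F", ref_length = 5e5,
                            gc_fraction = 0.508, n_genes = 50, coverage = 50,
                            solid = read_sim_config(insert_mean = 1200,
                                                    insert_sd = 100,
                                                    read_length = 50,
                                                    pair_coverage = coverage),
                            miseq = read_sim_config(insert_mean = 600,
                                                    insert_sd = 60,
                                                    read_length = 250,
                                                    pair_coverage = coverage),
                            caller = caller_config(),
                            min_mapq = 10, min_baseq = 30, z_threshold = 3,
                            dup_window = 5000, dup_ratio = 1.5,
                            dup_min_windows = 10,
                            seeds = list(reference = 1L, pileup_a = 2L,
                                         pileup_b = 3L, pairs = 4L)) {
  structure(list(scenario = scenario, ref_length = ref_length,
                 gc_fraction = gc_fraction, n_genes = n_genes,
                 coverage = coverage, solid = solid, miseq = miseq,
                 caller = caller, min_mapq = min_mapq, min_baseq = min_baseq,
                 z_threshold = z_threshold, dup_window = dup_window,
                 dup_ratio = dup_ratio, dup_min_windows = dup_min_windows,
                 seeds = seeds),
            class = "evo_run_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run an end-to-end planted-truth scenario
#'
#' Generates a reference, plants the scenario's events, simulates two pileup
#' platforms and a mate-pair library, runs point-mutation calling on both
#' platforms with truth-oracle consensus, small-indel calling, low-coverage
#' masking, the mate-pair distance-deviation scan with IS classification, and
#' read-depth duplication detection, then reconciles every call against the
#' planted truth.
#'
#' @param config An [scenario_config()] object.
#' @param outdir Optional directory; when given, all stage outputs are
#'   written as TSVs headed by the config hash.
#' @return A list of class `evo_report`; see in particular `$matches` (per
#'   planted event: recovered by which stage) and `$counts`
#'   (`n_truth`, `n_recovered`, `n_false_positive`).
#' @export
run_scenario <- function(config = scenario_config(), outdir = NULL) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", what, conditionMessage(e)),
            class = "evotrace_stage_failure")
    })
  }
  genome <- stage("reference", generate_reference(
    config$ref_length, config$gc_fraction, config$n_genes,
    seed = config$seeds$reference))
  events <- if (identical(config$scenario, "null")) {
    tibble(kind = character(), position = integer(), length = integer(),
           alt = character(), allele_fraction = numeric())
  } else {
    stage("fixtures", fixture_events(config$scenario, config$ref_length))
  }
  sample <- stage("plant", plant_events(genome, events))
  truth <- sample$truth

  pu_a <- stage("pileup_solid", simulate_pileups(
    sample, config$solid, coverage = config$coverage, platform = "SOLiD",
    seed = config$seeds$pileup_a))
  pu_b <- stage("pileup_miseq", simulate_pileups(
    sample, config$miseq, coverage = config$coverage, platform = "MiSeq",
    seed = config$seeds$pileup_b))

  calls_a <- stage("call_a", call_point_mutations(pu_a, config$caller))
  calls_b <- stage("call_b", call_point_mutations(pu_b, config$caller))
  indels <- stage("indels", call_small_indels(pu_a, config$caller))
  mask <- stage("mask", mask_low_coverage(
    select(pu_a, "pos", "depth"), min_reads = config$caller$min_depth))

  truth_snv <- filter(truth, .data$kind == "snv")
  consensus <- stage("consensus", consensus_calls(
    calls_a, calls_b, truth = select(truth_snv, "position", "alt")))
  point_final <- apply_mask(consensus$final, mask)

  pairs <- stage("pairs", simulate_mate_pairs(
    sample, config$solid, seed = config$seeds$pairs))
  pairs_hq <- filter_pairs(pairs, config$min_mapq, config$min_baseq)
  stats <- stage("distance_stats", global_distance_stats(pairs_hq))
  scan <- stage("scan", scan_distance_deviation(
    pairs_hq, stats, window_size = config$solid$insert_mean,
    z_threshold = config$z_threshold))
  sv_calls <- stage("classify", classify_regions(
    scan, pairs_hq, is_catalog = genome$is_catalog,
    read_length = config$solid$read_length,
    insert_sd = config$solid$insert_sd))

  profile <- stage("coverage", coverage_profile(
    pairs_hq, window_size = config$dup_window,
    read_length = config$solid$read_length,
    genome_length = config$ref_length))
  dups <- stage("duplication", detect_duplication(
    profile, config$dup_ratio, config$dup_min_windows))

  matches <- match_truth(truth, point_final$kept, indels, sv_calls, dups,
                         tol = config$solid$insert_mean)
  n_fp <- count_false_positives(truth, point_final$kept, indels, sv_calls,
                                dups, tol = config$solid$insert_mean)

  report <- structure(list(
    scenario = config$scenario, config = config,
    config_hash = config_hash(config),
    genome = genome, truth = truth,
    point = list(calls_a = calls_a, calls_b = calls_b,
                 consensus = consensus, final = point_final$kept,
                 masked = point_final$masked),
    indels = indels, mask = mask,
    sv = list(stats = stats, scan = scan, calls = sv_calls),
    duplication = list(profile = profile, calls = dups),
    matches = matches,
    counts = list(n_truth = nrow(truth),
                  n_recovered = sum(matches$recovered),
                  n_false_positive = n_fp)
  ), class = "evo_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

# per planted event: was it recovered, and by which stage?
match_truth <- function(truth, points, indels, sv_calls, dups, tol) {
  if (!nrow(truth)) {
    return(tibble(kind = character(), position = integer(),
                  length = integer(), alt = character(), recovered = logical(),
                  matched_by = character()))
  }
  purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    hit <- NA_character_
    if (tr$kind == "snv") {
      if (any(points$position == tr$position & points$alt == tr$alt)) {
        hit <- "point_consensus"
      }
    } else if (tr$kind %in% c("small_insertion", "small_deletion")) {
      sgn <- if (tr$kind == "small_deletion") -tr$length else tr$length
      if (any(abs(indels$position - tr$position) <= 2 &
                indels$length == sgn)) {
        hit <- "small_indel"
      }
    } else if (tr$kind %in% c("large_insertion", "large_deletion")) {
      want <- if (tr$kind == "large_deletion") "deletion" else "insertion"
      near <- sv_calls$kind == want &
        (abs(sv_calls$position - tr$position) <= 2 * tol |
           abs(sv_calls$position - (tr$position + tr$length)) <= 2 * tol)
      if (tr$kind == "large_insertion" && any(near)) {
        near <- near & (is.na(sv_calls$is_element) |
                          sv_calls$is_element == tr$alt)
      }
      if (any(near)) hit <- "distance_scan"
    } else if (tr$kind == "duplication") {
      if (nrow(dups) && any(dups$start <= tr$position + tr$length &
                              dups$end >= tr$position)) {
        hit <- "read_depth"
      }
    }
    tibble(kind = tr$kind, position = tr$position, length = tr$length,
           alt = tr$alt, recovered = !is.na(hit), matched_by = hit)
  })
}

# calls with no planted event to explain them
count_false_positives <- function(truth, points, indels, sv_calls, dups, tol) {
  fp_point <- sum(!purrr::map_lgl(seq_len(nrow(points)), function(i) {
    any(truth$kind == "snv" & truth$position == points$position[i] &
          truth$alt == points$alt[i])
  }))
  fp_indel <- sum(!purrr::map_lgl(seq_len(nrow(indels)), function(i) {
    sgn <- ifelse(truth$kind == "small_deletion", -truth$length, truth$length)
    any(truth$kind %in% c("small_insertion", "small_deletion") &
          abs(truth$position - indels$position[i]) <= 2 &
          sgn == indels$length[i])
  }))
  # an SV call is explained by any large planted event (or duplication
  # junction) nearby; several calls for one event are redundancy, not FPs
  fp_sv <- sum(!purrr::map_lgl(seq_len(nrow(sv_calls)), function(i) {
    any(truth$kind %in% c("large_insertion", "large_deletion",
                          "duplication") &
          (abs(truth$position - sv_calls$position[i]) <= 2 * tol |
             abs(truth$position + truth$length - sv_calls$position[i]) <=
               2 * tol))
  }))
  fp_dup <- sum(!purrr::map_lgl(seq_len(nrow(dups)), function(i) {
    any(truth$kind == "duplication" &
          truth$position <= dups$end[i] &
          truth$position + truth$length >= dups$start[i])
  }))
  fp_point + fp_indel + fp_sv + fp_dup
}

#' @export
print.evo_report <- function(x, ...) {
  cat(sprintf("<evo_report> scenario '%s' (config %s)\n", x$scenario,
              substr(x$config_hash, 1, 8)))
  cat(sprintf("  planted: %d | recovered: %d | false positives: %d\n",
              x$counts$n_truth, x$counts$n_recovered,
              x$counts$n_false_positive))
  print(x$matches)
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# config_hash=%s", report$config_hash)
  wr <- function(df, file) {
    path <- file.path(outdir, file)
    writeLines(hdr, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  }
  wr(report$point$final, "point_calls.tsv")
  wr(report$indels, "small_indels.tsv")
  wr(report$sv$calls, "sv_calls.tsv")
  wr(report$duplication$calls, "duplications.tsv")
  wr(report$mask, "mask.tsv")
  wr(report$matches, "truth_matches.tsv")
  invisible(outdir)
}
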