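#' Simulate a multi-strain expression time course with shared dynamics
#'
#' Gene `g` in strain `s` at time `t` has expression
#' `baseline_g + amplitude_g * f_g(t) + noise`, where `f_g` is a smooth,
#' generally non-monotone trajectory *shared across strains*, emulating the
#' synchronized slow expression changes observed when independently evolved
#' populations converge phenotypically. Trajectories are cubic polynomials in
#' scaled time with random coefficients, normalised so `f_g(0) = 0` and
#' `max |f_g| = 1`. If `divergent_strain` is set, a contiguous block of genes
#' in that strain is multiplied by `divergent_factor` at all post-zero
#' timepoints, emulating a large genomic duplication that raises expression of
#' the genes it spans. Values are floored at `detection_floor`.
#'
#' @param n_genes Number of genes.
#' @param strains Number of evolved strains.
#' @param timepoints Sampling times in hours; must include 0 (the parent
#'   state). Defaults to the 0, 384, 744, 1224, 1824, 2496 h schedule.
#' @param shared_amplitude Typical trajectory amplitude (a.u.).
#' @param noise_sd SD of additive measurement noise (a.u.).
#' @param divergent_strain Optional strain index receiving the block up-shift.
#' @param divergent_frac Fraction of genes in the shifted block.
#' @param divergent_factor Multiplier applied to the shifted block.
#' @param baseline_mean Mean baseline expression (a.u.).
#' @param detection_floor Lower detection floor (a.u.).
#' @param seed Integer seed.
#' @return A list of class `evo_expression`: `values` (tibble, `gene` column
#'   plus one column per sample), `metadata` (tibble: sample, strain,
#'   time_h). The parent appears once, as sample `"parent"` with time 0, and
#'   each strain contributes one sample per post-zero timepoint.
#' @export
simulate_expression_timecourse <- function(n_genes = 500, strains = 6,
                                           timepoints = c(0, 384, 744, 1224,
                                                          1824, 2496),
                                           shared_amplitude = 200,
                                           noise_sd = 20,
                                           divergent_strain = NULL,
                                           divergent_frac = 0.1,
                                           divergent_factor = 2,
                                           baseline_mean = 500,
                                           detection_floor = 1,
                                           seed = 1L) {
  if (!0 %in% timepoints) {
    abort("timepoints must include 0 (the parent state)",
          class = "evotrace_invalid_argument")
  }
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    timepoints <- sort(timepoints)
    ts <- timepoints / max(timepoints)
    baseline <- exp(rnorm(n_genes, log(baseline_mean), 0.5))
    amplitude <- shared_amplitude * rnorm(n_genes) # signed: up or down
    # random cubic with f(0) = 0, scaled to unit max amplitude
    co <- matrix(rnorm(3L * n_genes), ncol = 3L)
    f <- sapply(seq_along(ts), function(j) {
      co[, 1L] * ts[j] + co[, 2L] * ts[j]^2 + co[, 3L] * ts[j]^3
    })
    fmax <- pmax(apply(abs(f), 1L, max), 1e-12)
    f <- f / fmax

    meta <- tidyr::expand_grid(strain = sprintf("strain_%s", LETTERS[1:strains]),
                               time_h = timepoints) |>
      mutate(sample = paste0(.data$strain, "_", .data$time_h))
    meta <- bind_rows(tibble(strain = "parent", time_h = 0,
                             sample = "parent"), meta)

    block <- if (!is.null(divergent_strain)) {
      n_block <- max(1L, round(divergent_frac * n_genes))
      start <- sample.int(n_genes - n_block + 1L, 1L)
      seq(start, start + n_block - 1L)
    } else integer(0)

    vals <- matrix(0, nrow = n_genes, ncol = nrow(meta),
                   dimnames = list(NULL, meta$sample))
    for (j in seq_len(nrow(meta))) {
      tj <- match(meta$time_h[j], timepoints)
      mu <- baseline + amplitude * f[, tj]
      if (meta$strain[j] != "parent" && meta$time_h[j] > 0 &&
          !is.null(divergent_strain) &&
          meta$strain[j] == sprintf("strain_%s", LETTERS[divergent_strain])) {
        mu[block] <- mu[block] * divergent_factor
      }
      vals[, j] <- pmax(mu + rnorm(n_genes, 0, noise_sd), detection_floor)
    }
    values <- bind_cols(tibble(gene = sprintf("gene%04d", seq_len(n_genes))),
                        as_tibble(vals))
    structure(list(values = values, metadata = meta,
                   divergent_block = block),
              class = "evo_expression")
  })
}

#' Simulate a metabolite concentration table for parent and evolved strains
#'
#' Each metabolite gets a parent concentration (log-normal, micromolar scale)
#' and a log10 concentration shift shared across strains
#' (`~ Normal(0, shared_logshift_sd)`), plus independent per-strain noise
#' (`~ Normal(0, noise_sd)` on the log10 scale). With `noise_sd = 0` all
#' strains shift identically; with `shared_logshift_sd = 0` strain changes are
#' pure noise and pairwise change correlations vanish.
#'
#' @param n_metabolites Number of metabolites (default 83, the panel size a
#'   CE-TOFMS amino-acid/central-metabolism assay typically quantifies).
#' @param strains Number of evolved strains.
#' @param shared_logshift_sd SD of the shared log10 shift.
#' @param noise_sd SD of per-strain log10 noise.
#' @param parent_mean_log10 Mean parent log10 concentration (micromolar).
#' @param seed Integer seed.
#' @return A tibble: `metabolite`, `parent`, one column per strain (uM).
#' @export
simulate_metabolome <- function(n_metabolites = 83, strains = 6,
                                shared_logshift_sd = 0.5, noise_sd = 0.1,
                                parent_mean_log10 = 2, seed = 1L) {
  assert_scalar_number(n_metabolites, "n_metabolites", lower = 1)
  assert_scalar_number(strains, "strains", lower = 1)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  with_seed(seed, {
    parent <- 10^rnorm(n_metabolites, parent_mean_log10, 0.6)
    shift <- rnorm(n_metabolites, 0, shared_logshift_sd)
    out <- tibble(metabolite = sprintf("met%03d", seq_len(n_metabolites)),
                  parent = parent)
    for (s in seq_len(strains)) {
      out[[sprintf("strain_%s", LETTERS[s])]] <-
        parent * 10^(shift + rnorm(n_metabolites, 0, noise_sd))
    }
    out
  })
}

#' Simulate an OD600 growth series in exponential phase
#'
#' `od(t) = od0 * exp(mu * t) * (1 + noise)`, sampled every `interval` hours.
#'
#' @param mu Specific growth rate (per hour).
#' @param od0 Initial optical density (> 0).
#' @param duration Total duration in hours.
#' @param interval Sampling interval in hours.
#' @param noise_sd SD of multiplicative noise.
#' @param seed Integer seed.
#' @return A tibble: `time_h`, `od600`.
#' @export
simulate_od_series <- function(mu = 0.2, od0 = 0.05, duration = 10,
                               interval = 0.5, noise_sd = 0.02, seed = 1L) {
  assert_scalar_number(od0, "od0", lower = 0, strict_lower = TRUE)
  with_seed(seed, {
    time_h <- seq(0, duration, by = interval)
    od <- od0 * exp(mu * time_h) * (1 + rnorm(length(time_h), 0, noise_sd))
    tibble(time_h = time_h, od600 = pmax(od, 1e-6))
  })
}

#' Lay out population allele-frequency trajectories as a tidy table
#'
#' Frequencies are taken as given (the generator does not add noise), so
#' non-monotone trajectories — the signature of clonal interference — are
#' stored exactly as supplied.
#'
#' @param mutations Character vector of mutation labels.
#' @param frequency_trajectories A list (one numeric vector per mutation) of
#'   allele frequencies in `[0, 1]`, each of length `length(timepoints)`.
#' @param timepoints Sampling times in hours. Defaults to the 12-point
#'   216-2232 h schedule used for fixation-timing assays.
#' @return A tibble: `mutation`, `time_h`, `frequency`.
#' @export
simulate_population_timecourse <- function(mutations, frequency_trajectories,
                                           timepoints = c(216, 384, 576, 744,
                                                          888, 1056, 1224, 1392,
                                                          1584, 1824, 1968,
                                                          2232)) {
  stopifnot(length(mutations) == length(frequency_trajectories))
  for (tr in frequency_trajectories) {
    if (length(tr) != length(timepoints)) {
      abort("each trajectory must have one frequency per timepoint",
            class = "evotrace_invalid_argument")
    }
    if (any(tr < 0 | tr > 1, na.rm = TRUE)) {
      abort("allele frequencies must lie in [0, 1]",
            class = "evotrace_invalid_argument")
    }
  }
  purrr::map2_dfr(mutations, frequency_trajectories, function(m, tr) {
    tibble(mutation = m, time_h = timepoints, frequency = tr)
  })
}
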