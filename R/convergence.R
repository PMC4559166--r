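#' Quantile-normalise an expression matrix
#'
#' Forces every sample column to share one common value distribution — the
#' across-column mean of sorted values — while preserving each column's rank
#' order. Tied entries within a column receive the mean of the reference
#' values their positions span. The operation is idempotent.
#'
#' @param df A tibble whose first column (or `feature_col`) identifies the
#'   feature and whose remaining columns are numeric samples.
#' @param feature_col Name or index of the feature-ID column.
#' @return The tibble with sample columns normalised.
#' @export
quantile_normalize <- function(df, feature_col = 1L) {
  m <- as_matrix_features(df, feature_col)
  if (ncol(m$values) < 2L) {
    abort("quantile normalisation needs at least 2 sample columns",
          class = "evotrace_invalid_argument")
  }
  if (any(is.na(m$values))) {
    abort("matrix must be complete (no NA)",
          class = "evotrace_invalid_argument")
  }
  ref <- rowMeans(apply(m$values, 2L, sort))
  out <- apply(m$values, 2L, function(x) {
    o <- order(x)
    res <- numeric(length(x))
    # x[o] is sorted, so tied values form contiguous groups; ave() hands each
    # group the mean of the reference values it spans
    res[o] <- stats::ave(ref, x[o], FUN = mean)
    res
  })
  rebuild_features(m, out)
}

#' Drop features not quantified in every sample
#'
#' Keeps a feature iff its value exceeds the quantification limit in *every*
#' sample, the standard guard against working with intensities too low to be
#' quantitative.
#'
#' @inheritParams quantile_normalize
#' @param limit Quantification limit (strict `>` to keep); default 100 a.u.
#' @return The filtered tibble, with attribute `n_kept`.
#' @export
filter_quantification_limit <- function(df, limit = 100, feature_col = 1L) {
  m <- as_matrix_features(df, feature_col)
  keep <- apply(m$values > limit, 1L, all)
  out <- df[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  out
}

#' Log-transformed ratios against a reference (parent) sample
#'
#' Every entry becomes `log(value / reference, base)`; the reference column
#' itself maps to all zeros.
#'
#' @inheritParams quantile_normalize
#' @param reference Name of the reference (parent) sample column.
#' @param base Logarithm base (default 10).
#' @return The tibble of log-ratios.
#' @export
log_ratio_vs_reference <- function(df, reference, base = 10,
                                   feature_col = 1L) {
  m <- as_matrix_features(df, feature_col)
  if (!reference %in% colnames(m$values)) {
    abort(sprintf("reference column '%s' not found", reference),
          class = "evotrace_invalid_argument")
  }
  ref <- m$values[, reference]
  if (any(ref <= 0)) {
    abort("reference values must be positive; filter below the quantification limit first",
          class = "evotrace_data_integrity")
  }
  out <- log(sweep(m$values, 1L, ref, "/"), base = base)
  rebuild_features(m, out)
}

#' PCA of expression profiles with per-strain time-ordered orbits
#'
#' Samples are projected into the plane of the first two principal components
#' of the gene-centered matrix (singular-value decomposition via
#' [stats::prcomp()]; genes are variables, samples observations). Each
#' strain's scores, ordered by timepoint and anchored at the parent sample,
#' form its trajectory ("orbit") through expression space; independently
#' evolved strains that converge phenotypically trace similar orbits.
#'
#' @param df A feature x sample tibble (typically log10 expression of
#'   limit-filtered genes).
#' @param metadata A tibble with columns `sample`, `strain`, `time_h`
#'   covering every sample column.
#' @param feature_col Name or index of the feature-ID column.
#' @param parent Strain label of the anchor sample (default `"parent"`).
#' @return A list of class `evo_pca`: `scores` (sample, strain, time_h, PC
#'   columns), `loadings`, `explained_variance`, `orbits` (scores ordered by
#'   time within strain, parent prepended).
#' @export
pca_orbits <- function(df, metadata, feature_col = 1L, parent = "parent") {
  m <- as_matrix_features(df, feature_col)
  assert_columns(metadata, c("sample", "strain", "time_h"), "metadata")
  if (!all(colnames(m$values) %in% metadata$sample)) {
    abort("metadata must cover every sample column",
          class = "evotrace_invalid_argument")
  }
  if (ncol(m$values) < 3L) {
    abort("PCA needs at least 3 samples", class = "evotrace_invalid_argument")
  }
  x <- t(m$values) # samples x genes
  if (all(abs(sweep(x, 2L, colMeans(x))) < 1e-12)) {
    abort("constant matrix has no variance to decompose",
          class = "evotrace_degenerate_variance")
  }
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  scores <- as_tibble(p$x, rownames = "sample") |>
    left_join(metadata, by = "sample") |>
    select("sample", "strain", "time_h", dplyr::starts_with("PC"))
  parent_row <- filter(scores, .data$strain == parent)
  orbits <- scores |>
    filter(.data$strain != parent) |>
    group_by(.data$strain) |>
    dplyr::group_modify(function(g, key) {
      bind_rows(select(parent_row, -"strain"), arrange(g, .data$time_h))
    }) |>
    ungroup()
  structure(list(scores = scores, loadings = p$rotation,
                 explained_variance = ev, orbits = orbits, parent = parent),
            class = "evo_pca")
}

#' @export
print.evo_pca <- function(x, ...) {
  cat(sprintf("<evo_pca> %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$explained_variance[1],
              100 * x$explained_variance[2]))
  invisible(x)
}

#' Pairwise correlation of per-strain change vectors
#'
#' Pearson correlation of gene-wise (or metabolite-wise) log-ratios for every
#' pair of strains. High off-diagonal correlations mean the strains changed
#' the same features in the same direction — the quantitative signature of
#' phenotypic convergence. Zero-variance columns yield `NA` with a warning.
#'
#' @param df A feature x strain tibble of log-ratios vs the parent.
#' @param feature_col Name or index of the feature-ID column.
#' @return A square tibble: `strain` column plus one numeric column per
#'   strain; unit diagonal.
#' @export
pairwise_change_correlation <- function(df, feature_col = 1L) {
  m <- as_matrix_features(df, feature_col)
  sds <- apply(m$values, 2L, sd)
  if (any(sds == 0)) {
    warning("zero-variance change vector(s): ",
            paste(colnames(m$values)[sds == 0], collapse = ", "),
            "; correlations set to NA")
  }
  cm <- suppressWarnings(cor(m$values))
  diag(cm) <- 1
  bind_cols(tibble(strain = colnames(cm)), as_tibble(cm))
}

#' Absolute metabolite quantification from relative peak areas
#'
#' CE-TOFMS-style quantification: the analyte peak area is first normalised
#' to the internal-standard peak area within each run, then the sample's
#' relative area is compared with that of a chemical standard of known
#' concentration:
#' `conc = ((sample_area / sample_is_area) / (std_area / std_is_area)) * std_conc`.
#'
#' @param sample_area Analyte peak area in the biological sample (0 = below
#'   detection, returns 0).
#' @param sample_is_area Internal-standard peak area in the sample run (> 0).
#' @param std_area Analyte peak area in the standard mixture (> 0).
#' @param std_is_area Internal-standard peak area in the standard run (> 0).
#' @param std_conc Standard concentration (e.g. 50 uM).
#' @return Concentration in the same units as `std_conc`. Vectorised.
#' @export
quantify_metabolite <- function(sample_area, sample_is_area, std_area,
                                std_is_area, std_conc = 50) {
  if (any(sample_is_area <= 0) || any(std_is_area <= 0)) {
    abort("internal-standard peak areas must be positive",
          class = "evotrace_data_integrity")
  }
  if (any(std_area <= 0)) {
    abort("standard peak areas must be positive",
          class = "evotrace_data_integrity")
  }
  if (any(sample_area < 0)) {
    abort("peak areas cannot be negative", class = "evotrace_invalid_argument")
  }
  (sample_area / sample_is_area) / (std_area / std_is_area) * std_conc
}

# --- matrix <-> tibble helpers -------------------------------------------

as_matrix_features <- function(df, feature_col) {
  if (is.numeric(feature_col)) feature_col <- names(df)[feature_col]
  vals <- as.matrix(df[, setdiff(names(df), feature_col), drop = FALSE])
  if (!is.numeric(vals)) {
    abort("sample columns must all be numeric",
          class = "evotrace_invalid_argument")
  }
  list(features = df[[feature_col]], feature_col = feature_col, values = vals)
}

rebuild_features <- function(m, values) {
  out <- as_tibble(values)
  out <- bind_cols(tibble(!!m$feature_col := m$features), out)
  out
}
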