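test_that("quantile normalisation matches the closed-form two-column case", {
  df <- tibble::tibble(gene = c("g1", "g2"), s1 = c(1, 3), s2 = c(2, 4))
  qn <- quantile_normalize(df)
  expect_equal(qn$s1, c(1.5, 3.5))
  expect_equal(qn$s2, c(1.5, 3.5))
  # identical columns are unchanged
  df2 <- tibble::tibble(gene = c("g1", "g2"), s1 = c(5, 1), s2 = c(5, 1))
  expect_equal(quantile_normalize(df2), df2)
})

test_that("quantile normalisation is idempotent and equalises multisets", {
  set.seed(61)
  df <- dplyr::bind_cols(
    tibble::tibble(gene = sprintf("g%03d", 1:200)),
    tibble::as_tibble(matrix(rlnorm(200 * 5, 5, 1), ncol = 5,
                             dimnames = list(NULL, paste0("s", 1:5)))))
  qn <- quantile_normalize(df)
  m <- as.matrix(qn[, -1])
  # all column value multisets identical
  for (j in 2:5) expect_equal(sort(m[, j]), sort(m[, 1]))
  # rank order preserved within each column
  m0 <- as.matrix(df[, -1])
  for (j in 1:5) expect_equal(order(m[, j]), order(m0[, j]))
  # idempotence to 1e-12
  qn2 <- quantile_normalize(qn)
  expect_lt(max(abs(as.matrix(qn2[, -1]) - m)), 1e-12)
})

test_that("quantile normalisation agrees with the limma implementation", {
  skip_if_not_installed("limma")
  set.seed(62)
  m <- matrix(rlnorm(120 * 4, 4, 1.5), ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  df <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%03d", 1:120)),
                         tibble::as_tibble(m))
  ours <- as.matrix(quantile_normalize(df)[, -1])
  ref <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_lt(max(abs(ours - ref)), 1e-9)
})

test_that("the quantification limit keeps genes above it in every sample", {
  df <- tibble::tibble(gene = c("g1", "g2", "g3"),
                       s1 = c(99, 101, 500), s2 = c(500, 150, 500))
  kept <- filter_quantification_limit(df, limit = 100)
  expect_equal(kept$gene, c("g2", "g3")) # one sample at 99 drops g1
  expect_equal(attr(kept, "n_kept"), 2L)
  all_pos <- filter_quantification_limit(df, limit = 0)
  expect_equal(nrow(all_pos), 3L)
})

test_that("log-ratios are zero at the reference and linear in log space", {
  df <- tibble::tibble(gene = c("g1", "g2", "g3"),
                       parent = c(100, 100, 100),
                       s1 = c(100, 1000, 10))
  lr <- log_ratio_vs_reference(df, "parent")
  expect_equal(lr$parent, c(0, 0, 0))
  expect_equal(lr$s1, c(0, 1, -1))
  df$parent[2] <- 0
  expect_error(log_ratio_vs_reference(df, "parent"),
               class = "evotrace_data_integrity")
})

test_that("PCA conserves variance and pairwise distances (rotation only)", {
  set.seed(63)
  n_g <- 100; n_s <- 9
  m <- matrix(rnorm(n_g * n_s, 8, 2), ncol = n_s,
              dimnames = list(NULL, paste0("s", 1:n_s)))
  df <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%03d", 1:n_g)),
                         tibble::as_tibble(m))
  meta <- tibble::tibble(sample = paste0("s", 1:n_s),
                         strain = c("parent", rep(c("a", "b"), each = 4)),
                         time_h = c(0, rep(c(1, 2, 3, 4), 2)))
  p <- pca_orbits(df, meta, parent = "parent")
  scores <- as.matrix(dplyr::select(p$scores, dplyr::starts_with("PC")))
  centered <- scale(t(m), center = TRUE, scale = FALSE)
  expect_equal(sum(scores^2), sum(centered^2), tolerance = 1e-9)
  expect_equal(as.matrix(dist(scores)), as.matrix(dist(centered)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_lte(sum(p$explained_variance), 1 + 1e-12)
})

test_that("samples on a line in gene space put all variance on PC1", {
  t_vals <- 0:4
  m <- outer(rnorm(50), t_vals) + 5 # rank-1 structure
  colnames(m) <- paste0("s", 1:5)
  df <- dplyr::bind_cols(tibble::tibble(gene = sprintf("g%02d", 1:50)),
                         tibble::as_tibble(m))
  meta <- tibble::tibble(sample = paste0("s", 1:5),
                         strain = c("parent", rep("a", 4)),
                         time_h = c(0, 1, 2, 3, 4))
  p <- pca_orbits(df, meta)
  expect_equal(p$explained_variance[1], 1, tolerance = 1e-12)
  const <- df
  const[, -1] <- 1
  expect_error(pca_orbits(const, meta),
               class = "evotrace_degenerate_variance")
})

test_that("noise-free shared trajectories give identical strain orbits", {
  ex <- simulate_expression_timecourse(n_genes = 150, strains = 3,
                                       noise_sd = 0, seed = 64)
  lf <- log_ratio_vs_reference(
    filter_quantification_limit(ex$values, limit = 0), "parent")
  p <- pca_orbits(lf, ex$metadata)
  orb <- lapply(split(p$orbits, p$orbits$strain), function(g) {
    as.matrix(g[order(g$time_h), c("PC1", "PC2")])
  })
  expect_equal(orb$strain_A, orb$strain_B, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(orb$strain_A, orb$strain_C, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a divergent strain stands apart in orbit and correlation", {
  ex <- simulate_expression_timecourse(n_genes = 400, strains = 4,
                                       shared_amplitude = 200, noise_sd = 5,
                                       divergent_strain = 2, seed = 65)
  lf <- log_ratio_vs_reference(
    filter_quantification_limit(ex$values, limit = 1), "parent")
  endpoints <- dplyr::select(lf, "gene", dplyr::ends_with("_2496"))
  cm <- pairwise_change_correlation(endpoints)
  mat <- as.matrix(cm[, -1])
  rownames(mat) <- cm$strain
  div <- "strain_B_2496"
  others <- setdiff(cm$strain, div)
  div_cors <- mat[div, others]
  other_cors <- mat[others, others][upper.tri(matrix(0, 3, 3))]
  expect_true(max(div_cors) < min(other_cors))
  # and its orbit sits farthest from the consensus orbit
  p <- pca_orbits(lf, ex$metadata)
  orb <- dplyr::filter(p$orbits, .data$time_h > 0)
  consensus <- orb |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(c1 = mean(.data$PC1), c2 = mean(.data$PC2))
  dist_to_consensus <- orb |>
    dplyr::left_join(consensus, by = "time_h") |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(d = mean(sqrt((.data$PC1 - .data$c1)^2 +
                                     (.data$PC2 - .data$c2)^2)))
  expect_equal(dist_to_consensus$strain[which.max(dist_to_consensus$d)],
               "strain_B")
})

test_that("pairwise change correlations behave at the extremes", {
  v <- rnorm(2420)
  df <- tibble::tibble(gene = seq_along(v), a = v, b = v, c = -v)
  cm <- pairwise_change_correlation(df)
  expect_equal(cm$a[cm$strain == "b"], 1)
  expect_equal(cm$a[cm$strain == "c"], -1)
  expect_equal(cm$a[cm$strain == "a"], 1)
  # independent noise vectors at n = 2420 genes decorrelate
  set.seed(66)
  hits <- 0L
  for (i in 1:20) {
    df2 <- tibble::tibble(gene = 1:2420, a = rnorm(2420), b = rnorm(2420))
    if (abs(pairwise_change_correlation(df2)$a[2]) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
  # zero-variance vectors flag as NA with a warning
  df3 <- tibble::tibble(gene = 1:10, a = rnorm(10), b = rep(1, 10))
  expect_warning(cm3 <- pairwise_change_correlation(df3), "zero-variance")
  expect_true(is.na(cm3$b[cm3$strain == "a"]))
})

test_that("metabolite quantification is the standard relative-area formula", {
  # sample relative area equal to the standard's: the standard concentration
  expect_equal(quantify_metabolite(10, 5, 20, 10, std_conc = 50), 50)
  expect_equal(quantify_metabolite(20, 5, 20, 10, std_conc = 50), 100)
  expect_equal(quantify_metabolite(0, 5, 20, 10, std_conc = 50), 0)
  expect_error(quantify_metabolite(10, 0, 20, 10),
               class = "evotrace_data_integrity")
  expect_error(quantify_metabolite(10, 5, 20, 0),
               class = "evotrace_data_integrity")
})

test_that("metabolome simulation honours its convergence dials", {
  mt <- simulate_metabolome(seed = 67)
  expect_equal(nrow(mt), 83L)
  expect_true(all(mt$parent > 0))
  # noise_sd = 0: all strain-pair change correlations are exactly 1
  mt0 <- simulate_metabolome(n_metabolites = 60, strains = 3, noise_sd = 0,
                             seed = 68)
  lr <- log_ratio_vs_reference(mt0, "parent", feature_col = "metabolite")
  cm <- pairwise_change_correlation(
    dplyr::select(lr, -"parent"), feature_col = "metabolite")
  expect_equal(cm$strain_A[cm$strain == "strain_B"], 1)
  # shared shift 0, noise > 0: correlations near zero
  r <- replicate(5, {
    mtn <- simulate_metabolome(n_metabolites = 80, strains = 2,
                               shared_logshift_sd = 0, noise_sd = 0.3,
                               seed = sample.int(1e6, 1))
    lrn <- log_ratio_vs_reference(mtn, "parent", feature_col = "metabolite")
    cmn <- pairwise_change_correlation(dplyr::select(lrn, -"parent"),
                                       feature_col = "metabolite")
    cmn$strain_A[cmn$strain == "strain_B"]
  })
  expect_lt(abs(mean(r)), 0.15)
})
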