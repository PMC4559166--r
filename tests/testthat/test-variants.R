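test_that("binomial tail matches an exhaustive-summation oracle", {
  exhaustive <- function(k, n, p) sum(stats::dbinom(k:n, n, p))
  for (n in c(10, 25, 50, 100)) {
    for (k in unique(pmin(n, c(1, 3, n %/% 2, n - 1, n)))) {
      for (p in c(0.001, 0.005, 0.05)) {
        expect_lt(abs(binomial_tail(k, n, p) - exhaustive(k, n, p)) /
                    max(exhaustive(k, n, p), 1e-300), 1e-12)
      }
    }
  }
})

test_that("point-mutation calling applies depth, ratio and p-value gates", {
  cfg <- caller_config(error_rate = 0.01)
  pu <- manual_pileup(pos = c(100, 200, 300),
                      depth = c(20L, 9L, 20L),
                      variant_count = c(15L, 9L, 11L))
  calls <- call_point_mutations(pu, cfg)
  # depth 20 / 15 variants: ratio 0.75, tail P(X>=15 | 20, 0.01) << 1e-7
  expect_equal(calls$position, 100)
  expect_equal(calls$ratio, 0.75)
  expect_lt(calls$p_value, 1e-7)
  # depth 9 fails min_depth = 10 even at ratio 1; ratio 0.55 fails min_ratio
  expect_false(any(calls$position %in% c(200, 300)))
  # boundary inclusivity: depth exactly 10, ratio exactly 0.6
  pu_b <- manual_pileup(pos = 50, depth = 10L, variant_count = 6L)
  expect_equal(nrow(call_point_mutations(pu_b, cfg)), 1L)
})

test_that("variant counts above depth are a data-integrity error", {
  expect_error(
    call_point_mutations(manual_pileup(1, 10L, 11L)),
    class = "evotrace_data_integrity")
})

test_that("tightening any threshold never adds a point-mutation call", {
  set.seed(21)
  pu <- manual_pileup(pos = 1:500,
                      depth = rpois(500, 30),
                      variant_count = 0L)
  pu$variant_count <- rbinom(500, pu$depth, runif(500))
  base <- caller_config(min_depth = 10, min_ratio = 0.5, p_threshold = 1e-5,
                        error_rate = 0.01)
  n0 <- nrow(call_point_mutations(pu, base))
  for (cfg in list(caller_config(min_depth = 20, min_ratio = 0.5,
                                 p_threshold = 1e-5, error_rate = 0.01),
                   caller_config(min_depth = 10, min_ratio = 0.8,
                                 p_threshold = 1e-5, error_rate = 0.01),
                   caller_config(min_depth = 10, min_ratio = 0.5,
                                 p_threshold = 1e-9, error_rate = 0.01))) {
    strict <- call_point_mutations(pu, cfg)
    expect_lte(nrow(strict), n0)
    lax <- call_point_mutations(pu, base)
    expect_true(all(strict$position %in% lax$position))
  }
})

test_that("small-indel calling reports signed lengths under the same gates", {
  cfg <- caller_config()
  pu <- manual_pileup(pos = c(10, 20, 30), depth = 50L, variant_count = 0L,
                      indel_len = c(-88L, 1L, 10L),
                      indel_count = c(50L, 50L, 15L))
  calls <- call_small_indels(pu, cfg)
  expect_equal(calls$length, c(-88L, 1L)) # ratio 0.3 at pos 30 not called
  expect_equal(calls$ratio[1], 1)
  # evidence >= 500 bp belongs to the distance scan
  pu_big <- manual_pileup(pos = 5, depth = 50L, variant_count = 0L,
                          indel_len = -6775L, indel_count = 50L)
  expect_warning(big <- call_small_indels(pu_big, cfg), "500 bp")
  expect_equal(nrow(big), 0L)
})

test_that("consensus keeps agreed calls and arbitrates discrepancies", {
  a <- manual_calls(c(100, 200), platform = "A")
  b <- manual_calls(c(200, 300), platform = "B")
  truth <- tibble::tibble(position = c(100L, 200L), alt = "T")
  cons <- consensus_calls(a, b, truth)
  # m1 confirmed true, m2 agreed, m3 refuted
  expect_setequal(cons$final$position, c(100, 200))
  expect_equal(nrow(cons$agreed), 1L)
  expect_equal(sort(cons$resolutions$status), c("confirmed", "refuted"))
  # identical call sets issue no oracle queries
  cons2 <- consensus_calls(a, a, truth)
  expect_equal(nrow(cons2$resolutions), 0L)
  # positions outside the oracle's domain stay unresolved, never accepted
  cons3 <- consensus_calls(a, b, truth, oracle_domain = c(200L))
  expect_true(all(cons3$resolutions$status == "unresolved"))
  expect_setequal(cons3$final$position, 200)
  g <- glance(cons3)
  expect_equal(g$n_unresolved, 2L)
})

test_that("platform-count bookkeeping reproduces a 136/138/135 -> 138 merge", {
  # 135 shared calls; A adds 1 private, B adds 3 private; the oracle confirms
  # three of the four discrepant calls and refutes one
  shared <- manual_calls(seq(1000, by = 10, length.out = 135))
  a <- dplyr::bind_rows(shared, manual_calls(5000, platform = "A"))
  b <- dplyr::bind_rows(shared, manual_calls(c(6000, 7000, 8000),
                                             platform = "B"))
  expect_equal(nrow(a), 136L)
  expect_equal(nrow(b), 138L)
  truth <- tibble::tibble(position = c(shared$position, 5000L, 6000L, 7000L),
                          alt = "T")
  cons <- consensus_calls(a, b, truth)
  expect_equal(nrow(cons$agreed), 135L)
  expect_equal(sum(cons$resolutions$status == "confirmed"), 3L)
  expect_equal(sum(cons$resolutions$status == "refuted"), 1L)
  expect_equal(nrow(cons$final), 138L)
})

test_that("low-coverage masking uses strict < with maximal intervals", {
  expect_equal(nrow(mask_low_coverage(rep(50L, 100))), 0L)
  m <- mask_low_coverage(c(rep(50L, 10), rep(0L, 500), rep(50L, 10)))
  expect_equal(nrow(m), 1L)
  expect_equal(m$length, 500L)
  expect_equal(attr(m, "masked_bp"), 500L)
  # depths {9, 10, 9}: two 1 bp intervals, 10 is not masked
  m2 <- mask_low_coverage(c(9L, 10L, 9L))
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$length, c(1L, 1L))
  # calls inside masks are reported separately, not dropped silently
  calls <- manual_calls(c(5, 300, 525))
  sp <- apply_mask(calls, m)
  expect_equal(sp$kept$position, c(5, 525))
  expect_equal(sp$masked$position, 300)
})

test_that("parent subtraction removes exactly the ancestral calls", {
  calls <- manual_calls(c(100, 200, 300))
  expect_identical(subtract_parent(calls, calls[0, ]), calls)
  expect_equal(nrow(subtract_parent(calls, calls)), 0L)
  expect_identical(subtract_parent(calls, manual_calls(c(900, 950))), calls)
  partial <- subtract_parent(calls, manual_calls(200))
  expect_setequal(partial$position, c(100, 300))
})

test_that("fixed SNVs at depth >= 50 are recovered perfectly from simulation", {
  g <- generate_reference(1e5, 0.5, n_genes = 0, seed = 31)
  pos <- seq(500, 99500, length.out = 100)
  events <- purrr::map_dfr(pos, ~ planted_event("snv", .x, alt = "T"))
  s <- plant_events(g, events)
  cfg <- read_sim_config(base_error_rate = 0.01)
  pu <- simulate_pileups(s, cfg, coverage = 50, seed = 32)
  calls <- call_point_mutations(pu, caller_config(error_rate = 0.01))
  expect_setequal(calls$position, s$truth$position) # recall and precision 1
  expect_equal(calls$alt, s$truth$alt[match(calls$position,
                                            s$truth$position)])
})
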