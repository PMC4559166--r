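test_that("pair quality filtering is inclusive at the printed bounds", {
  pr <- manual_pairs(c(100, 200, 300, 400), 1200)
  pr$mapq <- c(9L, 10L, 60L, 60L)
  pr$min_baseq <- c(37L, 30L, 29L, 37L)
  kept <- filter_pairs(pr)
  expect_equal(kept$left_pos, c(200L, 400L)) # mapq 9 and baseq 29 removed
})

test_that("global distance statistics use the closed-form mean and n-1 SD", {
  st <- global_distance_stats(manual_pairs(c(1, 2, 3), c(1100, 1200, 1300)))
  expect_equal(st$mean_distance, 1200)
  expect_equal(st$sd_distance, 100)
  expect_equal(st$n_pairs, 3L)
  expect_error(global_distance_stats(manual_pairs(1, 1200)),
               class = "evotrace_insufficient_data")
  # counterpart pairs are excluded from the library baseline
  pr <- dplyr::bind_rows(manual_pairs(c(1, 2, 3), c(1100, 1200, 1300)),
                         manual_pairs(10, 90000, counterpart = "IS5"))
  expect_equal(global_distance_stats(pr)$mean_distance, 1200)
})

test_that("large simulated libraries recover their distance parameters", {
  g <- tiny_genome(5e5, seed = 41)
  s <- plant_events(g, planted_event("snv", 100, alt = "T"))
  pr <- simulate_mate_pairs(s, read_sim_config(insert_mean = 1200,
                                               insert_sd = 100),
                            n_pairs = 1e5, seed = 42)
  st <- global_distance_stats(pr)
  expect_lt(abs(st$mean_distance - 1200), 1)
  expect_lt(abs(st$sd_distance - 100), 1)
})

test_that("a degenerate distance spread aborts the scan", {
  pr <- manual_pairs(1:30, rep(1200, 30))
  st <- global_distance_stats(pr)
  expect_equal(st$sd_distance, 0)
  expect_error(scan_distance_deviation(pr, st, window_size = 1200),
               class = "evotrace_degenerate_spread")
})

test_that("event-free genomes yield no flagged windows", {
  g <- tiny_genome(5e5, seed = 43)
  s <- plant_events(g, planted_event("snv", 100, alt = "T"))
  pr <- filter_pairs(simulate_mate_pairs(s, read_sim_config(), n_pairs = 5e4,
                                         seed = 44))
  sc <- scan_distance_deviation(pr, global_distance_stats(pr),
                                window_size = 1200, min_pairs = 20)
  expect_equal(sum(sc$windows$flagged), 0L)
  expect_equal(nrow(sc$regions), 0L)
})

test_that("a planted 6775 bp deletion is flagged and sized by the scan", {
  g <- tiny_genome(2e5, seed = 45)
  s <- plant_events(g, planted_event("large_deletion", 100000, 6775))
  pr <- filter_pairs(simulate_mate_pairs(s, read_sim_config(), seed = 46))
  st <- global_distance_stats(pr)
  sc <- scan_distance_deviation(pr, st, window_size = 1200)
  expect_gte(nrow(sc$regions), 1L)
  cl <- classify_regions(sc, pr, is_catalog = g$is_catalog)
  del <- cl[cl$kind == "deletion", ]
  expect_gte(nrow(del), 1L)
  # m_w - mu_d recovers the deleted length within a few percent
  expect_lt(abs(del$size_estimate[1] - 6775) / 6775, 0.02)
  expect_false(del$censored[1])
})

test_that("an 88 bp deletion stays below the 3 SD radar", {
  g <- tiny_genome(2e5, seed = 47)
  s <- plant_events(g, planted_event("small_deletion", 100000, 88))
  pr <- filter_pairs(simulate_mate_pairs(
    s, read_sim_config(insert_mean = 1200, insert_sd = 100), seed = 48))
  sc <- scan_distance_deviation(pr, global_distance_stats(pr),
                                window_size = 1200)
  # 88 bp is 0.88 SD at sigma = 100: the scan must not flag it (the
  # small-indel caller owns it)
  expect_equal(nrow(sc$regions), 0L)
})

test_that("an uncensored IS insertion is sized and classified by counterparts", {
  g <- tiny_genome(2e5, seed = 49)
  s <- plant_events(g, planted_event("large_insertion", 100000, 1199,
                                     alt = "IS5"))
  cfg <- read_sim_config(insert_mean = 5000, insert_sd = 50,
                         pair_coverage = 50)
  pr <- filter_pairs(simulate_mate_pairs(s, cfg, seed = 50))
  st <- global_distance_stats(pr)
  sc <- scan_distance_deviation(pr, st, window_size = 5000)
  cl <- classify_regions(sc, pr, is_catalog = g$is_catalog,
                         read_length = 50, insert_sd = 50)
  ins <- cl[cl$kind == "insertion", ]
  expect_equal(nrow(ins), 1L)
  expect_lt(abs(ins$size_estimate - 1199) / 1199, 0.1)
  expect_equal(ins$is_element, "IS5")
  expect_false(ins$censored)
  # insert_mean 5000 >= 1199 + 100 + 3 * 50: the censoring law holds
})

test_that("a censored IS insertion is still detected, flagged as censored", {
  g <- tiny_genome(2e5, seed = 51)
  s <- plant_events(g, planted_event("large_insertion", 100000, 1199,
                                     alt = "IS5"))
  pr <- filter_pairs(simulate_mate_pairs(
    s, read_sim_config(insert_mean = 1200, insert_sd = 100), seed = 52))
  sc <- scan_distance_deviation(pr, global_distance_stats(pr),
                                window_size = 1200)
  cl <- classify_regions(sc, pr, is_catalog = g$is_catalog)
  ins <- cl[cl$kind == "insertion", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$is_element, "IS5")
  expect_true(ins$censored)
  expect_lt(abs(ins$position - 100000), 2400)
})

test_that("deletion sign law and insertion sign law hold across seeds", {
  g <- tiny_genome(1.5e5, seed = 53)
  for (seed in 1:5) {
    s <- plant_events(g, planted_event("large_deletion", 70000, 3000))
    pr <- filter_pairs(simulate_mate_pairs(s, read_sim_config(), seed = seed))
    st <- global_distance_stats(pr)
    sc <- scan_distance_deviation(pr, st, window_size = 1200)
    expect_true(all(sc$regions$median_distance > st$mean_distance))
  }
})

test_that("coverage profiles are flat under uniformity and double under dups", {
  g <- tiny_genome(2e5, seed = 55)
  s <- plant_events(g, planted_event("snv", 100, alt = "T"))
  pr <- simulate_mate_pairs(s, read_sim_config(pair_coverage = 50), seed = 56)
  prof <- coverage_profile(pr, window_size = 5000, read_length = 50,
                           genome_length = 2e5)
  # interior windows only: fragments cannot start within one insert of the
  # genome end, so the terminal windows are depleted by construction
  counts <- prof$n_starts[2:(nrow(prof) - 1)]
  expect_true(all(abs(counts - mean(counts)) <
                    4 * sqrt(mean(counts)) + 0.05 * mean(counts)))
  # empty input: an all-zero profile
  empty <- coverage_profile(pr[0, ], window_size = 5000, genome_length = 2e4)
  expect_true(all(empty$coverage == 0))
})

test_that("duplication detection reports maximal runs, unmerged", {
  flat <- tibble::tibble(start = seq(1, by = 5000, length.out = 100),
                         end = seq(5000, by = 5000, length.out = 100),
                         n_starts = 100L, coverage = 50)
  expect_equal(nrow(detect_duplication(flat)), 0L)
  two <- flat
  two$coverage[11:25] <- 100
  two$coverage[61:75] <- 100
  calls <- detect_duplication(two, ratio_threshold = 1.5,
                              min_consecutive_windows = 10)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$n_windows, c(15L, 15L))
  expect_equal(calls$mean_ratio, c(2, 2))
  # a run shorter than min_consecutive_windows is not called
  short <- flat
  short$coverage[11:15] <- 100
  expect_equal(nrow(detect_duplication(short, min_consecutive_windows = 10)),
               0L)
  zero <- flat
  zero$coverage <- 0
  expect_error(detect_duplication(zero),
               class = "evotrace_insufficient_data")
})

test_that("a simulated 200 kb duplication is recovered from read depth", {
  g <- generate_reference(1e6, 0.508, n_genes = 0, seed = 57)
  s <- plant_events(g, planted_event("duplication", 400000, 200000))
  pr <- filter_pairs(simulate_mate_pairs(
    s, read_sim_config(pair_coverage = 20), seed = 58))
  prof <- coverage_profile(pr, window_size = 5000, read_length = 50,
                           genome_length = 1e6)
  calls <- detect_duplication(prof, 1.5, 10)
  expect_equal(nrow(calls), 1L)
  expect_lt(abs(calls$length_bp - 200000), 5000 + 1)
  expect_lt(abs(calls$mean_ratio - 2), 0.15)
})
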