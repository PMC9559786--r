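small_model <- chromosome_model(c("chrA", "chrB"), c(1e6, 3e6))

test_that("mean region length floors the arithmetic mean", {
  expect_equal(mean_region_length(jia_haplotypes()), 86676)
  expect_equal(mean_region_length(100), 100)
  expect_equal(mean_region_length(c(10, 20, 31)), 20)
  expect_error(mean_region_length(numeric(0)), "zero regions")
})

test_that("random regions are length-matched, contained, and seeded", {
  cfg <- null_config(n_regions = 50, region_length = 1000, seed = 4)
  r1 <- draw_random_regions(small_model, cfg, seed = 99)
  r2 <- draw_random_regions(small_model, cfg, seed = 99)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(r1$end - r1$start == 1000))
  validate_intervals(r1, chrom_sizes = small_model)

  # forced placement: region as long as the only chromosome
  m1 <- chromosome_model("chr1", 5000)
  r <- draw_random_regions(m1, null_config(n_regions = 3,
                                           region_length = 5000), seed = 1)
  expect_true(all(r$start == 0 & r$end == 5000))
  expect_error(
    draw_random_regions(m1, null_config(region_length = 6000), seed = 1),
    "no chromosome")
})

test_that("chromosome choice is proportional to valid start positions", {
  m <- chromosome_model(c("c1", "c2"), c(100, 300))
  cfg <- null_config(n_regions = 1e5, region_length = 1, seed = 1)
  r <- draw_random_regions(m, cfg, seed = 8)
  frac_c2 <- mean(r$chrom == "c2")
  se <- sqrt(0.75 * 0.25 / 1e5)
  expect_lt(abs(frac_c2 - 0.75), 3 * se)
})

test_that("exclusion mask keeps random regions out of masked intervals", {
  mask <- genomic_intervals("chrB", 0, 2.9e6)  # most of chrB
  cfg <- null_config(n_regions = 200, region_length = 500, seed = 2,
                     exclusion_mask = mask)
  r <- draw_random_regions(small_model, cfg, seed = 5)
  expect_equal(count_overlap_events(r, mask), 0L)
})

test_that("null distribution moments match the replicate counts", {
  set.seed(101)
  peaks <- peak_set(random_intervals(300, chroms = c("chrA", "chrB"),
                                     max_pos = 9e5))
  cfg <- null_config(n_regions = 10, region_length = 5e4,
                     n_replicates = 50, seed = 12)
  null <- build_null(peaks, small_model, cfg)
  expect_length(null$replicate_counts, 50)
  expect_equal(null$mu_hat, mean(null$replicate_counts))
  expect_equal(null$sigma_hat, sd(null$replicate_counts))
  expect_false(null$degenerate)
  expect_gte(null$mu_hat, min(null$replicate_counts))
  expect_lte(null$mu_hat, max(null$replicate_counts))

  # empty peaks -> all-zero replicates, degenerate
  empty <- peak_set(genomic_intervals(character(), numeric(), numeric()))
  null0 <- build_null(empty, small_model, cfg)
  expect_true(null0$degenerate)
  expect_true(all(null0$replicate_counts == 0))

  # saturating peaks under regions_hit -> every count = n_regions
  cover <- peak_set(genomic_intervals(names(small_model), 0, small_model))
  cfgrh <- null_config(n_regions = 10, region_length = 5e4,
                       n_replicates = 20, seed = 3,
                       overlap_unit = "regions_hit")
  nullS <- build_null(cover, small_model, cfgrh)
  expect_true(all(nullS$replicate_counts == 10))
  expect_true(nullS$degenerate)
  expect_error(enrichment_p(genomic_intervals("chrA", 0, 100), cover,
                            small_model, cfgrh), "degenerate")
})

test_that("z and p are consistent and monotone in the observed count", {
  set.seed(55)
  haps <- random_intervals(20, chroms = c("chrA", "chrB"), max_pos = 9e5,
                           max_len = 5e4)
  peaks <- peak_set(random_intervals(400, chroms = c("chrA", "chrB"),
                                     max_pos = 9e5))
  cfg <- null_config(n_regions = 20, region_length = 3e4,
                     n_replicates = 200, seed = 21)
  res <- enrichment_p(haps, peaks, small_model, cfg)
  expect_equal(res$p_value, pnorm(res$z, lower.tail = FALSE))
  expect_equal(res$z, (res$k_obs - res$mu_hat) / res$sigma_hat)
  expect_gt(res$p_value, 0)
  expect_lt(res$p_value, 1)
  # k_obs at the null mean -> p = 0.5; +1.645 sd -> p ~ 0.05
  expect_equal(pnorm(0, lower.tail = FALSE), 0.5)
  expect_equal(pnorm(1.645, lower.tail = FALSE), 0.05, tolerance = 1e-3)

  # identical inputs + seed give bit-identical results
  res2 <- enrichment_p(haps, peaks, small_model, cfg)
  expect_identical(res, res2)

  # shuffling input order changes nothing
  res3 <- enrichment_p(haps[sample.int(nrow(haps)), ],
                       peak_set(peaks[sample.int(nrow(peaks)), ]),
                       small_model, cfg)
  expect_equal(res3$k_obs, res$k_obs)
  expect_equal(res3$mu_hat, res$mu_hat)
  expect_equal(res3$p_value, res$p_value)
})

test_that("empirical p-value matches direct counting", {
  null <- structure(list(replicate_counts = c(1, 5, 5, 7, 10)),
                    class = "null_distribution")
  expect_equal(empirical_p(null, 11), 1 / 6)    # above all replicates
  expect_equal(empirical_p(null, 0), 1)         # below all replicates
  expect_equal(empirical_p(null, 5), (1 + 4) / 6)
  r <- c(3, 8, 2, 9, 9, 1, 4)
  nullr <- structure(list(replicate_counts = r), class = "null_distribution")
  expect_equal(empirical_p(nullr, 6), (1 + sum(r >= 6)) / (length(r) + 1))
})
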