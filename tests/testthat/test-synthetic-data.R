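test_that("haplotype simulation honours the length law and spacing", {
  cfg <- sim_config(n_haplotypes = 10, haplotype_length_law = "fixed",
                    haplotype_length = 20000, seed = 3)
  h <- simulate_haplotypes(cfg)
  expect_equal(nrow(h), 10L)
  expect_true(all(h$end - h$start == 20000))
  validate_intervals(h, chrom_sizes = cfg$chromosomes)
  # pairwise gaps respect min_gap (padded intervals must not overlap)
  pad <- genomic_intervals(h$chrom, pmax(0, h$start - cfg$min_gap / 2),
                           h$end + cfg$min_gap / 2)
  expect_equal(count_overlap_events(pad, pad), nrow(pad))  # self only

  cfg36 <- sim_config(seed = 4)
  h36 <- simulate_haplotypes(cfg36)
  expect_equal(sort(h36$length), sort(jia_haplotypes()$length))
  expect_equal(h36$locus, jia_haplotypes()$locus)
})

test_that("generators are deterministic per seed", {
  cfg <- sim_config(n_haplotypes = 8, enrichment_fraction = 0.4,
                    n_peaks = 300, seed = 77)
  h1 <- simulate_haplotypes(cfg); h2 <- simulate_haplotypes(cfg)
  expect_identical(h1, h2)
  p1 <- simulate_peaks(cfg, h1); p2 <- simulate_peaks(cfg, h2)
  expect_identical(p1, p2)
  t1 <- simulate_tads_and_ctcf(cfg, h1)
  t2 <- simulate_tads_and_ctcf(cfg, h1)
  expect_identical(t1, t2)
  g1 <- simulate_genes(cfg, t1$tads); g2 <- simulate_genes(cfg, t1$tads)
  expect_identical(g1, g2)
})

test_that("planted peak bookkeeping matches direct recount", {
  cfg <- sim_config(n_haplotypes = 12, n_peaks = 10000,
                    enrichment_fraction = 0.5, seed = 21)
  h <- simulate_haplotypes(cfg)
  sim <- simulate_peaks(cfg, h)
  expect_equal(sim$truth$n_planted, 5000)
  expect_equal(sum(sim$peaks$planted), 5000)
  # every planted peak overlaps a haplotype
  planted <- sim$peaks[sim$peaks$planted, ]
  expect_true(all(regions_with_hit(planted, h)$hit))
  # peaks overlapping haplotypes = planted + recorded background spillover
  n_in <- sum(regions_with_hit(sim$peaks, h)$hit)
  expect_equal(n_in, 5000 + sim$truth$background_in_haplotype)

  # null mode: nothing planted
  cfg0 <- sim_config(n_haplotypes = 12, n_peaks = 500,
                     enrichment_fraction = 0, seed = 22)
  sim0 <- simulate_peaks(cfg0, h)
  expect_equal(sim0$truth$n_planted, 0)
  expect_false(any(sim0$peaks$planted))

  # saturation: fraction 1 puts every peak in a haplotype
  cfg1 <- sim_config(n_haplotypes = 12, n_peaks = 500,
                     enrichment_fraction = 1, seed = 23)
  sim1 <- simulate_peaks(cfg1, h)
  expect_true(all(regions_with_hit(sim1$peaks, h)$hit))
})

test_that("anchor failures translate into exactly the named exclusions", {
  cfg <- sim_config(n_haplotypes = 29, anchor_fail_loci = "PTPN22",
                    seed = 9)
  h <- simulate_haplotypes(cfg)
  sim <- simulate_tads_and_ctcf(cfg, h)
  checked <- check_anchors(sim$tads, sim$ctcf)
  expect_equal(sum(checked$retained), 28L)
  expect_false(checked$retained[checked$locus == "PTPN22"])
  expect_false(checked$right_anchor_ok[checked$locus == "PTPN22"])

  cfg_none <- sim_config(n_haplotypes = 10, seed = 9)
  h10 <- simulate_haplotypes(cfg_none)
  sim_none <- simulate_tads_and_ctcf(cfg_none, h10)
  expect_true(all(check_anchors(sim_none$tads, sim_none$ctcf)$retained))

  cfg_all <- sim_config(n_haplotypes = 10, anchor_fail_loci = h10$locus,
                        seed = 9)
  sim_all <- simulate_tads_and_ctcf(cfg_all, h10)
  expect_false(any(check_anchors(sim_all$tads, sim_all$ctcf)$retained))

  expect_error(
    simulate_tads_and_ctcf(sim_config(n_haplotypes = 5,
                                      anchor_fail_loci = "NOPE", seed = 1),
                           simulate_haplotypes(sim_config(n_haplotypes = 5,
                                                          seed = 1))),
    "anchor_fail_loci")
})

test_that("gene truth matches the pipeline's filtered per-TAD counts", {
  cfg <- sim_config(n_haplotypes = 8, n_genes = 600, seed = 31)
  h <- simulate_haplotypes(cfg)
  tc <- simulate_tads_and_ctcf(cfg, h)
  sim <- simulate_genes(cfg, tc$tads)
  kept <- suppressMessages(filter_expressed(genes_in_tads(sim$genes,
                                                          tc$tads)))
  got <- summarize_targets(kept)
  exp_counts <- sim$truth$per_tad
  got_counts <- ifelse(names(exp_counts) %in% names(got$per_locus),
                       got$per_locus[names(exp_counts)], 0L)
  expect_equal(unname(got_counts), unname(exp_counts))
  expect_equal(got$n_genes, sim$truth$n_union)

  # expression dropout: no expressed genes -> empty after filter
  cfg0 <- sim_config(n_haplotypes = 8, n_genes = 200,
                     expressed_fraction = 0, seed = 32)
  sim0 <- simulate_genes(cfg0, tc$tads)
  expect_equal(nrow(filter_expressed(genes_in_tads(sim0$genes, tc$tads))),
               0L)
  expect_equal(unname(sim0$truth$per_tad), rep(0L, nrow(tc$tads)))
})
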