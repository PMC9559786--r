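toy_tads <- function() {
  tad_candidates(data.frame(locus = c("L1", "L2"), chrom = "chr1",
                            start = c(1000, 5000), end = c(3000, 8000)))
}

test_that("gene-TAD assignment uses any overlap on the half-open rule", {
  tads <- toy_tads()
  g <- gene_records(c("g1", "g2", "g3", "g4"), c("S1", "S2", "S3", "S4"),
                    "chr1",
                    start = c(1500, 3000, 2900, 100),
                    end   = c(1800, 4000, 5200, 900),
                    tpm = 5)
  a <- genes_in_tads(g, tads)
  expect_setequal(a$gene_id[a$locus == "L1"], c("g1", "g3"))
  # g2 abuts L1's boundary at 3000 in half-open space: not assigned
  expect_false("g2" %in% a$gene_id)
  # g3 spans into L2 as well -> appears under both TADs
  expect_setequal(a$locus[a$gene_id == "g3"], c("L1", "L2"))
  expect_false("g4" %in% a$gene_id)

  # TSS mode assigns by start position only
  atss <- genes_in_tads(g, tads, mode = "tss")
  expect_equal(atss$locus[atss$gene_id == "g3"], "L1")
})

test_that("assignment agrees with brute force on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    t <- random_intervals(10, max_pos = 5e4, max_len = 8000)
    t <- t[!duplicated(t[, c("chrom", "start")]), ]
    tads <- tad_candidates(data.frame(
      locus = sprintf("T%02d", seq_len(nrow(t))), t[, c("chrom", "start", "end")]))
    g <- random_intervals(100, max_pos = 6e4, max_len = 4000)
    genes <- gene_records(sprintf("g%03d", 1:100), sprintf("s%03d", 1:100),
                          g$chrom, g$start, g$end, tpm = 1)
    a <- genes_in_tads(genes, tads)
    for (i in seq_len(nrow(tads))) {
      expected <- genes$gene_id[brute_regions_hit(genes, tads[i, ])]
      expect_setequal(a$gene_id[a$locus == tads$locus[i]], expected)
    }
  }
})

test_that("expression filter keeps protein-coding genes with TPM >= 1", {
  g <- gene_records(paste0("g", 1:4), paste0("s", 1:4), "chr1",
                    c(0, 100, 200, 300), c(50, 150, 250, 350),
                    biotype = c("protein_coding", "protein_coding",
                                "pseudogene", "ncRNA"),
                    tpm = c(1.0, 0.99, 50, 50))
  kept <- filter_expressed(g)
  expect_equal(kept$gene_id, "g1")      # boundary TPM = 1 kept
  # missing TPM treated as 0, with a message
  g$tpm[1] <- NA
  expect_message(kept2 <- filter_expressed(g), "treating TPM as 0")
  expect_equal(nrow(kept2), 0)
})

test_that("biotype and TPM filters commute", {
  set.seed(5)
  g <- gene_records(paste0("g", 1:200), paste0("s", 1:200), "chr1",
                    seq(0, by = 100, length.out = 200),
                    seq(50, by = 100, length.out = 200),
                    biotype = sample(c("protein_coding", "pseudogene",
                                       "ncRNA", "other"), 200, TRUE),
                    tpm = round(runif(200, 0, 3), 2))
  by_biotype_first <- g[g$biotype == "protein_coding", ]
  by_biotype_first <- by_biotype_first[by_biotype_first$tpm >= 1, ]
  by_tpm_first <- g[g$tpm >= 1, ]
  by_tpm_first <- by_tpm_first[by_tpm_first$biotype == "protein_coding", ]
  expect_equal(filter_expressed(g), by_biotype_first)
  expect_equal(filter_expressed(g), by_tpm_first)
})

test_that("target summary deduplicates genes shared between TADs", {
  empty <- summarize_targets(genes_in_tads(
    gene_records(character(), character(), character(), numeric(),
                 numeric()), toy_tads()))
  expect_equal(empty$n_genes, 0L)

  g <- gene_records(c("g1", "g2"), c("S1", "S2"), "chr1",
                    c(2900, 1200), c(5200, 1300), tpm = 5)
  a <- genes_in_tads(g, toy_tads())
  s <- summarize_targets(a)
  expect_equal(s$n_genes, 2L)  # g1 spans both TADs but counts once
  expect_equal(sum(s$per_locus), 3L)
  expect_lte(s$n_genes, sum(s$per_locus))
  expect_equal(s$symbols, c("S1", "S2"))
})
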