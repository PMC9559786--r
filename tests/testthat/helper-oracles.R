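# Independent oracles used across tests: all-pairs brute force for overlap
# counting, and a small random-interval generator.

brute_overlap_events <- function(a, b) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  n <- 0L
  for (i in seq_len(nrow(a))) {
    n <- n + sum(b$chrom == a$chrom[i] &
                   b$start < a$end[i] & a$start[i] < b$end)
  }
  n
}

brute_regions_hit <- function(regions, peaks) {
  r <- as.data.frame(regions); p <- as.data.frame(peaks)
  vapply(seq_len(nrow(r)), function(i) {
    any(p$chrom == r$chrom[i] & p$start < r$end[i] & r$start[i] < p$end)
  }, logical(1))
}

random_intervals <- function(n, chroms = c("chr1", "chr2", "chr3"),
                             max_pos = 1e5, max_len = 5000) {
  s <- sample.int(max_pos, n, replace = TRUE) - 1L
  l <- sample.int(max_len, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), s, s + l)
}
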