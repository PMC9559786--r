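#' Synthetic-data generator
#'
#' Generates complete synthetic inputs for every pipeline stage: a small
#' genome, non-overlapping risk haplotypes, peak sets with a controllable
#' fraction of peaks planted inside haplotypes (enrichment signal) versus
#' placed uniformly (null), candidate TADs with controllable CTCF-anchor
#' failures, and gene/expression tables with expression dropout. Each
#' component records ground truth so pipeline output can be checked
#' exactly. All draws are reproducible from `cfg$seed`; sub-generators use
#' fixed offsets from it, so the same configuration always yields the same
#' dataset.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults emulate the risk-haplotype study geometry: 36 haplotypes with
#' the published length distribution, histone-ChIP-seq-scale peaks
#' (Normal(500, 150) bp, truncated at 50), on a 3 x 50 Mb genome that is
#' large enough to hold the haplotypes without crowding yet keeps tests in
#' the seconds range.
#'
#' @param chromosomes Named numeric vector of chromosome lengths.
#' @param n_haplotypes Number of haplotypes.
#' @param locus_names Optional character vector of locus names to simulate
#'   (overrides `n_haplotypes`); under the `"from_table1"` law each named
#'   locus keeps its published length.
#' @param haplotype_length_law `"from_table1"` (published lengths; default),
#'   `"fixed"`, or `"lognormal"`.
#' @param haplotype_length Length used by the `"fixed"` law (bp).
#' @param haplotype_meanlog,haplotype_sdlog Parameters of the `"lognormal"`
#'   law.
#' @param min_gap Minimum bp between placed haplotypes (default 500,000;
#'   wide enough that TAD margins plus anchor windows of neighbouring loci
#'   can never touch).
#' @param n_peaks Number of peaks.
#' @param peak_length_mean,peak_length_sd,peak_length_min Peak width law:
#'   Normal(mean, sd) truncated below at `peak_length_min`.
#' @param enrichment_fraction Fraction of peaks planted inside haplotypes,
#'   in `[0, 1]`; 0 is the null mode.
#' @param anchor_fail_loci Locus names whose simulated TAD gets one bare
#'   boundary (no CTCF peak).
#' @param tad_margin_min,tad_margin_max TAD extension beyond the haplotype,
#'   per side, uniform in bp.
#' @param n_genes Number of genes.
#' @param gene_in_tad_fraction Fraction of genes planted inside TADs.
#' @param expressed_fraction Fraction of genes given TPM >= 1.
#' @param tpm_meanlog,tpm_sdlog Lognormal law for expressed genes' TPM
#'   (shifted above 1).
#' @param biotype_probs Probabilities for protein_coding / pseudogene /
#'   ncRNA.
#' @param seed Integer master seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(chromosomes = c(chr1 = 5e7, chr2 = 5e7, chr3 = 5e7),
                       n_haplotypes = 36L,
                       locus_names = NULL,
                       haplotype_length_law = c("from_table1", "fixed",
                                                "lognormal"),
                       haplotype_length = 86676,
                       haplotype_meanlog = log(5e4), haplotype_sdlog = 1,
                       min_gap = 5e5,
                       n_peaks = 2000L,
                       peak_length_mean = 500, peak_length_sd = 150,
                       peak_length_min = 50,
                       enrichment_fraction = 0,
                       anchor_fail_loci = character(),
                       tad_margin_min = 5e4, tad_margin_max = 2e5,
                       n_genes = 400L,
                       gene_in_tad_fraction = 0.5,
                       expressed_fraction = 0.6,
                       tpm_meanlog = log(10), tpm_sdlog = 1,
                       biotype_probs = c(protein_coding = 0.7,
                                         pseudogene = 0.15, ncRNA = 0.15),
                       seed = 1L) {
  haplotype_length_law <- match.arg(haplotype_length_law)
  if (!is.null(locus_names)) {
    if (anyDuplicated(locus_names)) stop("duplicated locus_names")
    n_haplotypes <- length(locus_names)
  }
  stopifnot(enrichment_fraction >= 0, enrichment_fraction <= 1,
            n_haplotypes >= 0, n_peaks >= 0, n_genes >= 0,
            haplotype_length > 0, peak_length_min > 0,
            expressed_fraction >= 0, expressed_fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

sim_hap_lengths <- function(cfg) {
  n <- cfg$n_haplotypes
  switch(cfg$haplotype_length_law,
    fixed = rep(cfg$haplotype_length, n),
    lognormal = pmax(1000, round(stats::rlnorm(n, cfg$haplotype_meanlog,
                                               cfg$haplotype_sdlog))),
    from_table1 = {
      tab <- jia_haplotypes()
      if (!is.null(cfg$locus_names)) {
        m <- match(cfg$locus_names, tab$locus)
        ifelse(is.na(m), round(mean(tab$length)), tab$length[m])
      } else if (n <= nrow(tab)) {
        tab$length[seq_len(n)]
      } else {
        c(tab$length, sample(tab$length, n - nrow(tab), replace = TRUE))
      }
    })
}

#' Simulate non-overlapping risk haplotypes
#'
#' Haplotypes are placed by rejection sampling so that no two lie within
#' `cfg$min_gap` of each other, keeping downstream truth bookkeeping
#' unambiguous. Locus names reuse the published table's names (extras are
#' numbered).
#'
#' @param cfg A [sim_config()].
#' @return `data.frame` with `locus`, `chrom`, `start`, `end`, `length`.
#' @export
simulate_haplotypes <- function(cfg) {
  with_seed(cfg$seed, {
    lens <- sim_hap_lengths(cfg)
    model <- cfg$chromosomes
    nms <- if (!is.null(cfg$locus_names)) {
      cfg$locus_names
    } else {
      pub_names <- jia_haplotypes()$locus
      if (cfg$n_haplotypes <= length(pub_names)) {
        pub_names[seq_len(cfg$n_haplotypes)]
      } else {
        c(pub_names, sprintf("locus_%02d",
                             seq_len(cfg$n_haplotypes - length(pub_names))))
      }
    }
    placed <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
    for (i in seq_along(lens)) {
      for (try in 1:10000) {
        valid <- model - lens[i] + 1
        if (all(valid < 1)) stop("chromosomes too short for haplotypes")
        w <- pmax(valid, 0)
        ci <- sample.int(length(model), 1, prob = w)
        s <- floor(stats::runif(1) * valid[ci])
        cand <- data.frame(chrom = names(model)[ci],
                           start = s - cfg$min_gap, end = s + lens[i] +
                             cfg$min_gap)
        if (count_overlap_events(cand, placed) == 0L) {
          placed <- rbind(placed,
                          data.frame(chrom = names(model)[ci], start = s,
                                     end = s + lens[i]))
          break
        }
        if (try == 10000) stop("could not place haplotypes with min_gap; ",
                               "enlarge the genome or reduce min_gap")
      }
    }
    data.frame(locus = nms, placed, length = lens, stringsAsFactors = FALSE)
  })
}

#' Simulate a peak set with planted enrichment
#'
#' `round(n_peaks * enrichment_fraction)` peaks are planted uniformly
#' inside uniformly-chosen haplotypes (truncated to fit when a haplotype is
#' shorter than the drawn width, with a message); the remainder are placed
#' uniformly on the genome, independent of the haplotypes.
#'
#' @param cfg A [sim_config()].
#' @param haplotypes Output of [simulate_haplotypes()].
#' @return List: `peaks` (a [peak_set()] with logical `planted` carried as
#'   a column) and `truth` (`n_planted`, `n_background`,
#'   `background_in_haplotype` — background spillover counted directly).
#' @export
simulate_peaks <- function(cfg, haplotypes) {
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_peaks
    model <- cfg$chromosomes
    widths <- pmax(cfg$peak_length_min,
                   round(stats::rnorm(n, cfg$peak_length_mean,
                                      cfg$peak_length_sd)))
    n_in <- round(n * cfg$enrichment_fraction)
    if (n_in > 0 && !nrow(haplotypes)) stop("cannot plant peaks: no haplotypes")
    planted <- c(rep(TRUE, n_in), rep(FALSE, n - n_in))
    chrom <- character(n); start <- numeric(n); end <- numeric(n)
    if (n_in > 0) {
      hi <- sample.int(nrow(haplotypes), n_in, replace = TRUE)
      span <- haplotypes$end[hi] - haplotypes$start[hi]
      w <- pmin(widths[seq_len(n_in)], span)
      n_trunc <- sum(w < widths[seq_len(n_in)])
      if (n_trunc) message(n_trunc, " planted peak(s) truncated to fit ",
                           "their haplotype")
      s <- haplotypes$start[hi] + floor(stats::runif(n_in) * (span - w + 1))
      chrom[seq_len(n_in)] <- haplotypes$chrom[hi]
      start[seq_len(n_in)] <- s
      end[seq_len(n_in)] <- s + w
    }
    if (n - n_in > 0) {
      i <- seq.int(n_in + 1, n)
      valid <- outer(model, widths[i], function(L, w) pmax(L - w + 1, 0))
      ci <- vapply(seq_along(i), function(j) {
        sample.int(length(model), 1, prob = valid[, j])
      }, integer(1))
      s <- floor(stats::runif(length(i)) *
                   valid[cbind(ci, seq_along(i))])
      chrom[i] <- names(model)[ci]
      start[i] <- s
      end[i] <- s + widths[i]
    }
    x <- genomic_intervals(chrom, start, end,
                           name = sprintf("peak_%05d", seq_len(n)))
    x$planted <- planted
    bg <- x[!x$planted, , drop = FALSE]
    truth <- list(
      n_planted = n_in,
      n_background = n - n_in,
      background_in_haplotype =
        if (nrow(bg)) sum(regions_with_hit(bg, haplotypes)$hit) else 0L
    )
    list(peaks = peak_set(x, label = "simulated_peaks"), truth = truth)
  })
}

#' Simulate candidate TADs and CTCF anchors
#'
#' One TAD per haplotype, extending it by independent uniform margins on
#' each side (clamped to the chromosome). A 400 bp CTCF peak is centred on
#' each boundary, except that loci listed in `cfg$anchor_fail_loci` get no
#' peak at their right boundary.
#'
#' @param cfg A [sim_config()].
#' @param haplotypes Output of [simulate_haplotypes()] (or any table with
#'   `locus`, `chrom`, `start`, `end`).
#' @return List: `tads` (a [tad_candidates()] table) and `ctcf` (a
#'   [peak_set()]).
#' @export
simulate_tads_and_ctcf <- function(cfg, haplotypes) {
  with_seed(cfg$seed + 2L, {
    h <- as.data.frame(haplotypes)
    model <- cfg$chromosomes
    n <- nrow(h)
    ml <- floor(stats::runif(n, cfg$tad_margin_min, cfg$tad_margin_max + 1))
    mr <- floor(stats::runif(n, cfg$tad_margin_min, cfg$tad_margin_max + 1))
    L <- model[h$chrom]
    dom <- data.frame(locus = h$locus, chrom = h$chrom,
                      start = pmax(0, h$start - ml),
                      end = pmin(L, h$end + mr), stringsAsFactors = FALSE)
    tads <- tad_candidates(dom, haplotypes = h)
    fail <- dom$locus %in% cfg$anchor_fail_loci
    unknown <- setdiff(cfg$anchor_fail_loci, dom$locus)
    if (length(unknown)) {
      stop("anchor_fail_loci not among simulated loci: ",
           paste(unknown, collapse = ", "))
    }
    anchor <- function(pos, side, keep) {
      k <- which(keep)
      data.frame(chrom = dom$chrom[k],
                 start = pmax(0, pos[k] - 200),
                 end = unname(pmin(L[k], pos[k] + 200)),
                 name = sprintf("ctcf_%s_%s", side, dom$locus[k]),
                 stringsAsFactors = FALSE)
    }
    ctcf <- rbind(anchor(dom$start, "L", rep(TRUE, n)),
                  anchor(dom$end, "R", !fail))
    list(tads = tads, ctcf = peak_set(ctcf, label = "simulated_CTCF"))
  })
}

# Generator-side bookkeeping: per-TAD and union counts of genes surviving
# the protein-coding + TPM >= 1 filter, by direct per-TAD comparison
# (independent of the overlap engine's indexed path).
gene_truth_counts <- function(genes, tads) {
  t <- as.data.frame(tads)
  keep <- genes$biotype == "protein_coding" & genes$tpm >= 1
  hits <- lapply(seq_len(nrow(t)), function(i) {
    which(keep & genes$chrom == t$chrom[i] &
            genes$start < t$end[i] & genes$end > t$start[i])
  })
  list(
    per_tad = stats::setNames(vapply(hits, length, integer(1)), t$locus),
    n_union = length(unique(unlist(hits)))
  )
}

#' Simulate gene and expression tables
#'
#' A fraction of genes is planted with its start inside a uniformly-chosen
#' TAD (guaranteeing overlap); the rest are scattered uniformly. Biotypes
#' are drawn from `cfg$biotype_probs`; expressed genes receive
#' TPM = 1 + lognormal, the rest TPM uniform in (0, 1) so the TPM >= 1
#' filter separates them exactly.
#'
#' @param cfg A [sim_config()].
#' @param tads TAD table (e.g. `simulate_tads_and_ctcf(...)$tads`); rows
#'   with `retained == FALSE` are still used for placement (placement does
#'   not look at anchors).
#' @return List: `genes` (gene record `data.frame`) and `truth` — the
#'   generator's own per-TAD count of genes that survive the
#'   protein-coding + TPM filter, computed by direct comparison.
#' @export
simulate_genes <- function(cfg, tads) {
  with_seed(cfg$seed + 3L, {
    t <- as.data.frame(tads)
    n <- cfg$n_genes
    model <- cfg$chromosomes
    widths <- pmax(500, round(stats::rlnorm(n, log(2e4), 0.8)))
    in_tad <- stats::runif(n) < cfg$gene_in_tad_fraction & nrow(t) > 0
    chrom <- character(n); start <- numeric(n)
    if (any(in_tad)) {
      ti <- sample.int(nrow(t), sum(in_tad), replace = TRUE)
      chrom[in_tad] <- t$chrom[ti]
      start[in_tad] <- t$start[ti] +
        floor(stats::runif(sum(in_tad)) * (t$end[ti] - t$start[ti]))
    }
    if (any(!in_tad)) {
      k <- sum(!in_tad)
      ci <- sample.int(length(model), k, replace = TRUE, prob = model)
      chrom[!in_tad] <- names(model)[ci]
      start[!in_tad] <- floor(stats::runif(k) *
                                pmax(1, model[ci] - widths[!in_tad]))
    }
    end <- pmin(start + widths, model[chrom])
    biotype <- sample(names(cfg$biotype_probs), n, replace = TRUE,
                      prob = cfg$biotype_probs)
    expressed <- stats::runif(n) < cfg$expressed_fraction
    tpm <- ifelse(expressed,
                  1 + stats::rlnorm(n, cfg$tpm_meanlog, cfg$tpm_sdlog),
                  stats::runif(n, 0, 0.999))
    genes <- gene_records(sprintf("G%05d", seq_len(n)),
                          sprintf("GENE%05d", seq_len(n)),
                          chrom, start, end, biotype, tpm)
    truth <- gene_truth_counts(genes, t)
    list(genes = genes, truth = truth)
  })
}

#' Simulate a full input bundle on disk
#'
#' Writes chrom.sizes, haplotype TSV, peak BED, TAD BED4, CTCF BED, gene
#' TSV, expression TSV and a truth JSON into `dir`, ready for
#' [run_pipeline()].
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths plus the in-memory components,
#'   invisibly.
#' @export
simulate_bundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  haps <- simulate_haplotypes(cfg)
  pk <- simulate_peaks(cfg, haps)
  tc <- simulate_tads_and_ctcf(cfg, haps)
  gn <- simulate_genes(cfg, tc$tads)
  paths <- list(
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    haplotypes = file.path(dir, "haplotypes.tsv"),
    peaks = file.path(dir, "peaks.bed"),
    tads = file.path(dir, "tads.bed"),
    ctcf = file.path(dir, "ctcf.bed"),
    genes = file.path(dir, "genes.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_chrom_sizes(cfg$chromosomes, paths$chrom_sizes)
  utils::write.table(haps, paths$haplotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed(pk$peaks, paths$peaks)
  td <- as.data.frame(tc$tads)
  write_bed(genomic_intervals(td$chrom, td$start, td$end, td$locus),
            paths$tads)
  write_bed(tc$ctcf, paths$ctcf)
  utils::write.table(gn$genes[, c("gene_id", "symbol", "chrom", "start",
                                  "end", "biotype")],
                     paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gn$genes[, c("gene_id", "tpm")], paths$expression,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  retained_tads <- tc$tads[!tc$tads$locus %in% cfg$anchor_fail_loci, ,
                           drop = FALSE]
  truth <- list(
    seed = cfg$seed,
    n_haplotypes = nrow(haps),
    peaks = pk$truth,
    anchor_fail_loci = cfg$anchor_fail_loci,
    n_tads_retained_expected =
      nrow(haps) - length(cfg$anchor_fail_loci),
    genes = gn$truth,
    genes_retained = gene_truth_counts(gn$genes, retained_tads)
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(haplotypes_df = haps, peaks_df = pk$peaks,
                          tads_df = tc$tads, ctcf_df = tc$ctcf,
                          genes_df = gn$genes, truth_record = truth)))
}
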