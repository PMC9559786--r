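#' Pipeline orchestration
#'
#' One call runs the full analysis in order: peak enrichment over the risk
#' haplotypes, per-haplotype presence/absence annotation, selection of
#' qualified loci, CTCF-anchor validation of candidate TADs, and expressed
#' target-gene extraction — writing per-stage TSVs and a reproducibility
#' manifest.
#'
#' @name cli_and_reporting
NULL

#' Pipeline configuration
#'
#' @param chrom_sizes Path to a UCSC chrom.sizes file.
#' @param haplotypes Path to a haplotype TSV (header: `locus`, `chrom`,
#'   `start`, `end`, optional `length` with printed lengths).
#' @param peaks Named character vector of BED paths, one per peak set; the
#'   names label the peak sets (e.g. `c(H3K4me1 = "...", H3K27ac = "...")`).
#' @param tads Path to a BED4 of candidate TADs (name column = locus);
#'   `NULL` skips the TAD and gene stages.
#' @param ctcf Path to a CTCF peak BED; required when `tads` is given.
#' @param genes,expression Paths to the gene table and two-column
#'   expression TSV; `NULL` skips the gene stage.
#' @param out_dir Output directory.
#' @param n_regions,n_replicates,overlap_unit Forwarded to [null_config()].
#' @param region_length `"auto"` (mean haplotype length via
#'   [mean_region_length()]) or an integer bp value.
#' @param qualify_on Label(s) of the peak set(s) whose presence qualifies a
#'   locus for TAD analysis (default: the first peak set).
#' @param anchor_window Boundary window for [check_anchors()], bp.
#' @param min_tpm Expression threshold for [filter_expressed()].
#' @param alpha Significance level.
#' @param seed Integer seed for the null draws.
#' @return List of class `pipeline_config` (validated: all paths exist).
#' @export
pipeline_config <- function(chrom_sizes, haplotypes, peaks,
                            tads = NULL, ctcf = NULL,
                            genes = NULL, expression = NULL,
                            out_dir = "haplotad_out",
                            n_regions = NULL, region_length = "auto",
                            n_replicates = 1000L,
                            overlap_unit = c("events", "regions_hit"),
                            qualify_on = NULL,
                            anchor_window = 25000, min_tpm = 1,
                            alpha = 0.05, seed = 1L) {
  overlap_unit <- match.arg(overlap_unit)
  if (is.null(names(peaks)) || any(!nzchar(names(peaks)))) {
    stop("'peaks' must be a named vector of BED paths")
  }
  paths <- c(chrom_sizes, haplotypes, peaks, tads, ctcf, genes, expression)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(tads) && is.null(ctcf)) {
    stop("TAD validation requires a CTCF peak file")
  }
  structure(
    list(chrom_sizes = chrom_sizes, haplotypes = haplotypes,
         peaks = peaks, tads = tads, ctcf = ctcf, genes = genes,
         expression = expression, out_dir = out_dir,
         n_regions = n_regions, region_length = region_length,
         n_replicates = as.integer(n_replicates),
         overlap_unit = overlap_unit,
         qualify_on = qualify_on %||% names(peaks)[1],
         anchor_window = anchor_window, min_tpm = min_tpm,
         alpha = alpha, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

pipeline_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Stage order: enrich (one test per peak set) -> annotate (per-haplotype
#' presence table) -> qualify loci -> validate TADs -> extract genes ->
#' report. Outputs written under `cfg$out_dir`: `enrichment.tsv`,
#' `annotation.tsv`, `tads.tsv`, `genes_per_tad.tsv`,
#' `target_symbols.txt`, `config.json` and `manifest.json` (config hash,
#' seed, package version, md5 of every output). A stage failure aborts
#' with the stage name; outputs written so far are kept alongside a
#' `FAILED` marker file.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Log one line per stage (default `TRUE`).
#' @return List with `enrichment`, `annotation`, `qualified_loci`, `tads`,
#'   `targets`, `manifest`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  on.exit({
    file.create(file.path(cfg$out_dir, "FAILED"))
    message("pipeline failed at stage: ", stage)
  })

  model <- read_chrom_sizes(cfg$chrom_sizes)
  haps <- utils::read.table(cfg$haplotypes, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "")
  validate_intervals(haps, chrom_sizes = model)
  if (!"length" %in% names(haps)) haps$length <- haps$end - haps$start
  peak_sets <- lapply(names(cfg$peaks), function(lb) {
    read_bed(cfg$peaks[[lb]], label = lb)
  })
  names(peak_sets) <- names(cfg$peaks)

  stage <- "enrich"
  region_length <- if (identical(cfg$region_length, "auto")) {
    mean_region_length(haps)
  } else as.numeric(cfg$region_length)
  ncfg <- null_config(
    n_regions = cfg$n_regions %||% nrow(haps),
    region_length = region_length,
    n_replicates = cfg$n_replicates,
    seed = cfg$seed, overlap_unit = cfg$overlap_unit
  )
  enr <- lapply(peak_sets, function(ps) {
    enrichment_p(haps, ps, model, ncfg, alpha = cfg$alpha)
  })
  enrichment <- do.call(rbind, lapply(enr, function(e) {
    data.frame(label = e$label, k_obs = e$k_obs, mu_hat = e$mu_hat,
               sigma_hat = e$sigma_hat, z = e$z, p_value = e$p_value,
               significant = e$significant, stringsAsFactors = FALSE)
  }))
  rownames(enrichment) <- NULL
  for (e in enr) {
    pipeline_log(verbose, stage, "%s: k_obs=%d, p=%.3g", e$label, e$k_obs,
                 e$p_value)
  }

  stage <- "annotate"
  annotation <- haps[, c("locus", "chrom", "start", "end")]
  for (lb in names(peak_sets)) {
    annotation[[lb]] <- regions_with_hit(haps, peak_sets[[lb]])$hit
  }
  pipeline_log(verbose, stage, "annotated %d haplotypes with %d peak set(s)",
               nrow(annotation), length(peak_sets))

  stage <- "qualify"
  missing_q <- setdiff(cfg$qualify_on, names(peak_sets))
  if (length(missing_q)) {
    stop("qualify_on label(s) not among peak sets: ",
         paste(missing_q, collapse = ", "))
  }
  qual <- Reduce(`|`, lapply(cfg$qualify_on, function(lb) annotation[[lb]]))
  qualified <- annotation$locus[qual]
  pipeline_log(verbose, stage, "%d/%d loci qualified on %s",
               length(qualified), nrow(annotation),
               paste(cfg$qualify_on, collapse = "|"))

  tad_out <- NULL
  targets <- NULL
  if (!is.null(cfg$tads)) {
    stage <- "tads"
    tad_bed <- read_bed(cfg$tads)
    tads <- tad_candidates(as.data.frame(tad_bed), haplotypes = NULL)
    tads <- tads[tads$locus %in% qualified, , drop = FALSE]
    ctcf <- read_bed(cfg$ctcf)
    tad_out <- check_anchors(tads, ctcf, window = cfg$anchor_window)
    pipeline_log(verbose, stage, "%d/%d candidate TADs retained",
                 sum(tad_out$retained), nrow(tad_out))

    if (!is.null(cfg$genes)) {
      stage <- "genes"
      genes <- read_gene_table(cfg$genes, cfg$expression)
      assigned <- genes_in_tads(genes, tad_out)
      kept <- suppressMessages(filter_expressed(assigned,
                                                min_tpm = cfg$min_tpm))
      targets <- summarize_targets(kept)
      targets$per_tad_table <- kept
      pipeline_log(verbose, stage, "%d expressed target gene(s)",
                   targets$n_genes)
    }
  }

  stage <- "report"
  wr <- function(x, f) {
    p <- file.path(cfg$out_dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  out_files <- c(
    wr(enrichment, "enrichment.tsv"),
    wr(annotation, "annotation.tsv")
  )
  if (!is.null(tad_out)) {
    out_files <- c(out_files, wr(as.data.frame(tad_out), "tads.tsv"))
  }
  if (!is.null(targets)) {
    out_files <- c(
      out_files,
      wr(targets$per_tad_table, "genes_per_tad.tsv"),
      {
        p <- file.path(cfg$out_dir, "target_symbols.txt")
        writeLines(targets$symbols, p)
        p
      }
    )
  }
  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  # hash the analysis-defining part of the config: the destination
  # directory must not change the hash
  cfg_for_hash <- unclass(cfg)
  cfg_for_hash$out_dir <- NULL
  hash_file <- tempfile()
  jsonlite::write_json(cfg_for_hash, hash_file, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("haplotad")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(hash_file)),
    outputs = as.list(stats::setNames(unname(tools::md5sum(out_files)),
                                      basename(out_files)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(verbose, stage, "wrote %d output file(s) to %s",
               length(out_files) + 2, cfg$out_dir)

  on.exit()  # success: cancel the FAILED marker
  list(enrichment = enrichment, annotation = annotation,
       qualified_loci = qualified, tads = tad_out, targets = targets,
       manifest = manifest)
}

#' Reproduce the published fixture tallies
#'
#' Pure function of the packaged tables — no peak files, no randomness:
#' mean haplotype length, histone-mark class counts, GRO-seq counts,
#' qualified-locus count, MPRA/GRO-seq overlap counts and eQTL counts.
#'
#' @return Named list of tallies.
#' @export
fixture_summary <- function() {
  haps <- jia_haplotypes()
  marks <- jia_marks()
  mk <- count_mark_classes(marks)
  resting <- count_mpra_overlaps(jia_mpra("resting_K562"))
  ifng <- count_mpra_overlaps(jia_mpra("K562_IFNG"))
  eq <- count_eqtl(jia_eqtl())
  list(
    n_haplotypes = nrow(haps),
    mean_haplotype_length = mean_region_length(haps),
    marks = mk,
    n_qualified_loci = length(select_enriched_loci(marks)),
    mpra_resting_k562 = resting,
    mpra_k562_ifng = ifng,
    eqtl = eq
  )
}
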