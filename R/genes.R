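#' Candidate target genes within retained TADs
#'
#' Enhancers predominantly regulate genes inside their own TAD, so the
#' candidate target set of a risk haplotype is the genes whose bodies
#' overlap its retained TAD, restricted to protein-coding genes expressed
#' in the cell type of interest (TPM >= 1).
#'
#' @name target_genes
NULL

#' Construct a gene record table
#'
#' @param gene_id Stable identifiers (unique).
#' @param symbol Display symbols.
#' @param chrom,start,end Gene-body coordinates (0-based half-open).
#' @param biotype One of `"protein_coding"`, `"pseudogene"`, `"ncRNA"`,
#'   `"other"`.
#' @param tpm Non-negative expression values; `NA` is treated as 0 by
#'   [filter_expressed()].
#' @return `data.frame` of gene records.
#' @export
gene_records <- function(gene_id, symbol, chrom, start, end,
                         biotype = "protein_coding", tpm = NA_real_) {
  n <- length(gene_id)
  biotype <- rep_len(as.character(biotype), n)
  tpm <- rep_len(as.numeric(tpm), n)
  x <- data.frame(gene_id = as.character(gene_id),
                  symbol = as.character(symbol),
                  chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end),
                  biotype = as.character(biotype), tpm = as.numeric(tpm),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  if (anyDuplicated(x$gene_id)) stop("duplicated gene_id")
  bad_bt <- setdiff(unique(x$biotype),
                    c("protein_coding", "pseudogene", "ncRNA", "other"))
  if (length(bad_bt)) stop("unknown biotype: ", paste(bad_bt, collapse = ", "))
  if (any(x$tpm < 0, na.rm = TRUE)) stop("tpm must be >= 0")
  x
}

#' Read a gene table and attach expression
#'
#' Genes come as a TSV with header columns `gene_id`, `symbol`, `chrom`,
#' `start`, `end`, `biotype`; expression as a two-column TSV
#' (`gene_id`, `tpm`). Genes missing from the expression table get
#' `tpm = NA` (treated as 0 at filtering, with a message).
#'
#' @param gene_path Gene table path.
#' @param expression_path Optional expression table path.
#' @return Gene record `data.frame`.
#' @export
read_gene_table <- function(gene_path, expression_path = NULL) {
  g <- utils::read.table(gene_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  tpm <- rep(NA_real_, nrow(g))
  if (!is.null(expression_path)) {
    e <- utils::read.table(expression_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
    tpm <- e$tpm[match(g$gene_id, e$gene_id)]
  }
  gene_records(g$gene_id, g$symbol, g$chrom, g$start, g$end, g$biotype, tpm)
}

#' Assign genes to TADs
#'
#' A gene belongs to a TAD when its body overlaps the domain (half-open
#' convention; any amount of overlap). A gene may appear under several
#' TADs; deduplication happens in [summarize_targets()]. A stricter
#' TSS-only mode assigns by the gene's start position instead.
#'
#' @param genes Gene record `data.frame`.
#' @param tads A [tad_candidates()] table; rows with a `retained` column set
#'   to `FALSE` are dropped first.
#' @param mode `"any_overlap"` (default) or `"tss"`.
#' @return Long `data.frame`: one row per (locus, gene) assignment, carrying
#'   the gene columns.
#' @export
genes_in_tads <- function(genes, tads, mode = c("any_overlap", "tss")) {
  mode <- match.arg(mode)
  g <- as.data.frame(genes)
  t <- as.data.frame(tads)
  if ("retained" %in% names(t)) t <- t[t$retained, , drop = FALSE]
  pieces <- lapply(seq_len(nrow(t)), function(i) {
    same <- g$chrom == t$chrom[i]
    hit <- if (mode == "any_overlap") {
      same & g$start < t$end[i] & g$end > t$start[i]
    } else {
      same & g$start >= t$start[i] & g$start < t$end[i]
    }
    if (!any(hit)) return(NULL)
    cbind(locus = t$locus[i], g[hit, , drop = FALSE])
  })
  out <- do.call(rbind, c(pieces, list(
    cbind(locus = character(), g[0, , drop = FALSE]))))
  rownames(out) <- NULL
  out
}

#' Expression and biotype filter
#'
#' Keeps protein-coding genes with TPM >= `min_tpm`; pseudogenes and
#' non-coding RNA are removed regardless of expression. The boundary is
#' inclusive: the exclusion rule is "TPM < 1", so TPM = 1 survives. The
#' two filters commute. Missing TPM is treated as 0 (not expressed), with
#' a message.
#'
#' @param genes Gene record `data.frame` (possibly the output of
#'   [genes_in_tads()]).
#' @param min_tpm Expression threshold in TPM (default 1).
#' @return Filtered `data.frame`.
#' @export
filter_expressed <- function(genes, min_tpm = 1) {
  x <- as.data.frame(genes)
  if (!"tpm" %in% names(x)) stop("genes need a 'tpm' column")
  n_na <- sum(is.na(x$tpm))
  if (n_na) {
    message(n_na, " gene(s) without expression values; treating TPM as 0")
    x$tpm[is.na(x$tpm)] <- 0
  }
  x[x$biotype == "protein_coding" & x$tpm >= min_tpm, , drop = FALSE]
}

#' Summarize candidate target genes
#'
#' @param assigned Output of [genes_in_tads()] (usually after
#'   [filter_expressed()]).
#' @return List with `n_genes` (unique `gene_id` count across all TADs),
#'   `per_locus` (named integer vector of per-TAD counts) and `symbols`
#'   (sorted unique symbols, ready for external ontology tools).
#' @export
summarize_targets <- function(assigned) {
  x <- as.data.frame(assigned)
  if (!nrow(x)) {
    return(list(n_genes = 0L, per_locus = integer(0), symbols = character(0)))
  }
  per_locus <- vapply(split(x$gene_id, x$locus),
                      function(g) length(unique(g)), integer(1))
  list(n_genes = length(unique(x$gene_id)),
       per_locus = per_locus,
       symbols = sort(unique(x$symbol)))
}

#' Write the flat gene-symbol list for ontology tools
#' @param summary Output of [summarize_targets()].
#' @param path Output path (one symbol per line).
#' @return `path`, invisibly.
#' @export
write_symbol_list <- function(summary, path) {
  writeLines(summary$symbols, path)
  invisible(path)
}
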