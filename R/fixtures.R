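#' Packaged risk-haplotype tables
#'
#' The package ships, as plain TSV under `extdata/`, the published tables
#' describing 36 juvenile idiopathic arthritis (JIA) risk haplotypes
#' (hg38 LD blocks at r^2 = 0.80), their histone-mark/GRO-seq annotation,
#' the MPRA-identified enhancer regions with their GRO-seq overlap status,
#' and the eQTL records for MPRA SNPs inside monocyte GRO-seq peaks.
#' Tables are transcribed verbatim, including printed symbol typos (e.g.
#' "TIMMCD1", "ZFPl36F1"); see [locus_symbol_map()] for canonical symbols.
#'
#' @name fixtures
NULL

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "haplotad")
  if (p == "") stop("missing packaged fixture: ", name)
  p
}

read_fixture_tsv <- function(name) {
  utils::read.table(fixture_path(name), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "",
                    colClasses = "character", fileEncoding = "UTF-8")
}

# Printed tables use "+" for presence and either ASCII hyphen or en-dash
# for absence.
parse_mark_symbol <- function(x) {
  out <- rep(NA, length(x))
  out[x == "+"] <- TRUE
  out[x %in% c("-", "–", "−")] <- FALSE
  if (anyNA(out)) {
    stop("unrecognized presence/absence symbol: ",
         paste(unique(x[is.na(out)]), collapse = " "), call. = FALSE)
  }
  out
}

#' Risk-haplotype table (36 LD blocks, hg38)
#'
#' @return `data.frame` with columns `locus`, `snp` (tag SNP rsID),
#'   `region` (printed coordinate string), `chrom`, `start`, `end`
#'   (0-based half-open) and `length` — the printed length, kept verbatim.
#'   The printed length equals `B - A` of the printed 1-based inclusive
#'   coordinates, i.e. one less than the half-open span; this convention is
#'   asserted at load time and never recomputed.
#' @export
jia_haplotypes <- function() {
  x <- read_fixture_tsv("risk_haplotypes.tsv")
  iv <- parse_region_string(x$ld_block)
  out <- data.frame(locus = x$locus, snp = x$snp, region = x$ld_block,
                    chrom = iv$chrom, start = iv$start, end = iv$end,
                    length = as.numeric(x$length), stringsAsFactors = FALSE)
  stopifnot(nrow(out) == 36L,
            all(out$length == (out$end - out$start) - 1))
  out
}

#' Histone-mark / GRO-seq annotation of the risk haplotypes
#'
#' @return `data.frame` with `locus`, `snp`, `region`, `chrom`, `start`,
#'   `end` and logical columns `h3k27ac`, `h3k4me1`, `gro_resting`,
#'   `gro_activated`.
#' @export
jia_marks <- function() {
  x <- read_fixture_tsv("mark_annotation.tsv")
  iv <- parse_region_string(x$haplotype)
  data.frame(locus = x$locus, snp = x$snp, region = x$haplotype,
             chrom = iv$chrom, start = iv$start, end = iv$end,
             h3k27ac = parse_mark_symbol(x$h3k27ac),
             h3k4me1 = parse_mark_symbol(x$h3k4me1),
             gro_resting = parse_mark_symbol(x$gro_resting),
             gro_activated = parse_mark_symbol(x$gro_activated),
             stringsAsFactors = FALSE)
}

#' MPRA-identified enhancer regions with GRO-seq overlap status
#'
#' @param condition `"resting_K562"` (18 regions) or `"K562_IFNG"`
#'   (19 regions); `NULL` returns both, stacked, with a `condition` column.
#' @return `data.frame` with `locus`, `context` (intronic/intergenic),
#'   `region`, `chrom`, `start`, `end`, logical `gro_resting` and
#'   `gro_activated`, and `condition`.
#' @export
jia_mpra <- function(condition = NULL) {
  load1 <- function(file, cond) {
    x <- read_fixture_tsv(file)
    iv <- parse_region_string(x$region)
    data.frame(locus = x$locus, context = x$context, region = x$region,
               chrom = iv$chrom, start = iv$start, end = iv$end,
               gro_resting = parse_mark_symbol(x$gro_resting),
               gro_activated = parse_mark_symbol(x$gro_activated),
               condition = cond, stringsAsFactors = FALSE)
  }
  both <- rbind(load1("mpra_resting_k562.tsv", "resting_K562"),
                load1("mpra_k562_ifng.tsv", "K562_IFNG"))
  if (is.null(condition)) return(both)
  condition <- match.arg(condition, c("resting_K562", "K562_IFNG"))
  both[both$condition == condition, , drop = FALSE]
}

#' eQTL records for MPRA SNPs within monocyte GRO-seq peaks
#'
#' @return `data.frame` with `snp`, `locus`, `gene`, numeric `p_value` and
#'   `p_threshold` (the gene-specific multiple-testing threshold reported
#'   by the eQTL service).
#' @export
jia_eqtl <- function() {
  x <- read_fixture_tsv("eqtl_records.tsv")
  x$p_value <- as.numeric(x$p_value)
  x$p_threshold <- as.numeric(x$p_threshold)
  stopifnot(all(x$p_value > 0), all(x$p_threshold > 0))
  x
}

#' Map from printed locus/gene symbols to canonical symbols
#'
#' Some printed symbols are garbled ("TIMMCD1", "ZFPl36F1", ...). The
#' fixtures keep them verbatim; this map is shipped separately and is never
#' applied unless the user calls [normalize_locus_symbols()] explicitly.
#'
#' @return `data.frame` with `verbatim`, `canonical`, `note`.
#' @export
locus_symbol_map <- function() {
  read_fixture_tsv("locus_symbol_map.tsv")
}

#' Apply the symbol normalization map
#' @param x Character vector of symbols as printed.
#' @param map A map `data.frame` (default [locus_symbol_map()]).
#' @return Character vector with mapped symbols replaced; others untouched.
#' @export
normalize_locus_symbols <- function(x, map = locus_symbol_map()) {
  m <- match(x, map$verbatim)
  ifelse(is.na(m), x, map$canonical[m])
}

#' Tally mark classes over the haplotype annotation
#'
#' @param annotations Output of [jia_marks()] (or any table with the same
#'   logical columns).
#' @return Named list: `both` (H3K27ac and H3K4me1), `k4me1_only`,
#'   `neither`, `gro_resting`, `gro_activated` (column sums) and
#'   `gained_on_activation` (GRO-seq peak appearing only after
#'   activation). On the packaged table: 22 / 7 / 7 / 11 / 16 / 5.
#' @export
count_mark_classes <- function(annotations) {
  a <- as.data.frame(annotations)
  need <- c("h3k27ac", "h3k4me1", "gro_resting", "gro_activated")
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  list(
    both = sum(a$h3k27ac & a$h3k4me1),
    k4me1_only = sum(a$h3k4me1 & !a$h3k27ac),
    neither = sum(!a$h3k27ac & !a$h3k4me1),
    gro_resting = sum(a$gro_resting),
    gro_activated = sum(a$gro_activated),
    gained_on_activation = sum(!a$gro_resting & a$gro_activated)
  )
}

#' Tally MPRA-region GRO-seq overlaps
#'
#' @param regions Output of [jia_mpra()].
#' @param condition Optional condition filter (`"resting_K562"` or
#'   `"K562_IFNG"`).
#' @return Named list: `resting_hits`, `activated_hits` (regions whose
#'   MPRA SNPs fall in a GRO-seq peak of resting / activated macrophages).
#' @export
count_mpra_overlaps <- function(regions, condition = NULL) {
  x <- as.data.frame(regions)
  if (!is.null(condition)) {
    condition <- match.arg(condition, c("resting_K562", "K562_IFNG"))
    x <- x[x$condition == condition, , drop = FALSE]
  }
  list(resting_hits = sum(x$gro_resting),
       activated_hits = sum(x$gro_activated))
}

#' Tally eQTL records
#'
#' @param records Output of [jia_eqtl()].
#' @return Named list: `snps` (distinct rsIDs), `loci` (distinct locus
#'   names), `all_significant` (every record's p-value below its
#'   gene-specific threshold).
#' @export
count_eqtl <- function(records) {
  x <- as.data.frame(records)
  list(snps = length(unique(x$snp)),
       loci = length(unique(x$locus)),
       all_significant = nrow(x) == 0 || all(x$p_value < x$p_threshold))
}

#' Export the packaged fixtures to a directory
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
export_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c("risk_haplotypes.tsv", "mark_annotation.tsv",
             "mpra_resting_k562.tsv", "mpra_k562_ifng.tsv",
             "eqtl_records.tsv", "locus_symbol_map.tsv")
  out <- file.path(dir, files)
  ok <- file.copy(vapply(files, fixture_path, ""), out, overwrite = TRUE)
  if (!all(ok)) stop("failed to export fixtures")
  invisible(out)
}
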