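#' Candidate TADs around risk haplotypes
#'
#' Candidate topologically associating domains arrive as plain intervals
#' (called externally from Hi-C contact maps); this module validates them
#' against CTCF ChIP-seq: a domain is retained only when both of its
#' boundaries carry a CTCF anchor, since genuine TAD loops are anchored by
#' CTCF/cohesin complexes at each end.
#'
#' @name tad_architecture
NULL

#' Construct candidate TADs
#'
#' @param domains Interval `data.frame` with a `locus` column (or BED4-style
#'   `name` column, taken as the locus) giving the haplotype each domain
#'   encompasses.
#' @param haplotypes Optional interval `data.frame` with a `locus` column;
#'   when given, each domain must fully contain its haplotype (checked here,
#'   at construction).
#' @return `data.frame` of class `tad_candidates` with columns `locus`,
#'   `chrom`, `start`, `end`.
#' @export
tad_candidates <- function(domains, haplotypes = NULL) {
  x <- as.data.frame(domains)
  if (!"locus" %in% names(x)) {
    if (!"name" %in% names(x)) stop("domains need a 'locus' (or 'name') column")
    x$locus <- x$name
  }
  x <- x[, c("locus", "chrom", "start", "end")]
  validate_intervals(x)
  if (anyDuplicated(x$locus)) stop("duplicated TAD locus names")
  if (!is.null(haplotypes)) {
    h <- as.data.frame(haplotypes)
    m <- match(x$locus, h$locus)
    if (anyNA(m)) {
      stop("TAD locus without a matching haplotype: ",
           paste(x$locus[is.na(m)], collapse = ", "), call. = FALSE)
    }
    contained <- x$chrom == h$chrom[m] & x$start <= h$start[m] &
      x$end >= h$end[m]
    if (any(!contained)) {
      stop("TAD domain does not contain its haplotype: ",
           paste(x$locus[!contained], collapse = ", "), call. = FALSE)
    }
  }
  rownames(x) <- NULL
  class(x) <- c("tad_candidates", "data.frame")
  x
}

#' CTCF-anchor check for candidate TADs
#'
#' A boundary anchor is "clear" when at least one CTCF peak overlaps the
#' half-open window `[boundary - window, boundary + window)` (clamped at
#' position 0). A domain is retained iff both boundaries pass; failing
#' domains are excluded from all downstream analysis.
#'
#' @param tads A [tad_candidates()] table.
#' @param ctcf_peaks A [peak_set()] of CTCF ChIP-seq peaks.
#' @param window Half-width in bp of the boundary window (default 25,000,
#'   on the order of Hi-C loop-anchor resolution).
#' @param min_signal Optional minimum value of the peaks' `signal` column
#'   (narrowPeak signalValue); default no strength threshold.
#' @return `tads` with added logical columns `left_anchor_ok`,
#'   `right_anchor_ok`, `retained`.
#' @export
check_anchors <- function(tads, ctcf_peaks, window = 25000, min_signal = NULL) {
  stopifnot(window >= 0)
  p <- as.data.frame(ctcf_peaks)
  if (!is.null(min_signal)) {
    if (!"signal" %in% names(p))
      stop("min_signal given but peaks carry no 'signal' column")
    p <- p[!is.na(p$signal) & p$signal >= min_signal, , drop = FALSE]
  }
  idx <- overlap_index(p)
  x <- as.data.frame(tads)
  boundary_hit <- function(pos) {
    w <- data.frame(chrom = x$chrom,
                    start = pmax(0, pos - window),
                    end = pos + window + (window == 0))
    count_vs_index(w, idx) > 0L
  }
  # window = 0 degenerates to the single base at the boundary
  x$left_anchor_ok <- boundary_hit(x$start)
  x$right_anchor_ok <- boundary_hit(x$end)
  x$retained <- x$left_anchor_ok & x$right_anchor_ok
  class(x) <- c("tad_candidates", "data.frame")
  x
}

#' Select enrichment-qualified loci from a mark annotation
#'
#' Keeps loci whose LD block shows the H3K4me1 mark, with or without
#' H3K27ac — the qualification rule for TAD analysis ("both marks, or
#' H3K4me1 alone"). H3K27ac without H3K4me1 does not qualify.
#'
#' @param annotation `data.frame` with `locus` and logical `h3k4me1` (and
#'   typically `h3k27ac`) columns, e.g. [jia_marks()].
#' @return Character vector of locus names.
#' @export
select_enriched_loci <- function(annotation) {
  x <- as.data.frame(annotation)
  if (!all(c("locus", "h3k4me1") %in% names(x))) {
    stop("annotation needs 'locus' and 'h3k4me1' columns")
  }
  x$locus[as.logical(x$h3k4me1)]
}

#' Write a TAD anchor report
#' @param tads Output of [check_anchors()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tad_report <- function(tads, path) {
  utils::write.table(as.data.frame(tads), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
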