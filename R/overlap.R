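#' @name overlap
#' @title Interval overlap engine
#'
#' @description
#' Overlap is defined on the half-open convention: intervals `x` and `y` on
#' the same chromosome overlap iff `x.start < y.end && y.start < x.end`, so
#' abutting intervals sharing only a boundary point never overlap. Counting
#' uses a sort-and-sweep scheme: the query set is indexed once per
#' chromosome as sorted start and end vectors, and the number of peaks
#' overlapping a region `[s, e)` is obtained by binary search as
#' `#(start <= e - 1) - #(end <= s)`; total cost O((n + m) log m).
#' Strand is ignored throughout.
NULL

# Per-chromosome sorted index of an interval set (starts, ends ascending).
overlap_index <- function(x) {
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i) {
    list(starts = sort(x$start[i]), ends = sort(x$end[i]), n = length(i))
  })
}

# Integer vector: number of indexed intervals overlapping each region.
count_vs_index <- function(regions, idx) {
  out <- integer(nrow(regions))
  if (!nrow(regions)) return(out)
  for (ch in intersect(unique(regions$chrom), names(idx))) {
    ix <- idx[[ch]]
    r <- which(regions$chrom == ch)
    started_before_end <- findInterval(regions$end[r] - 1, ix$starts)
    ended_before_start <- findInterval(regions$start[r], ix$ends)
    out[r] <- started_before_end - ended_before_start
  }
  out
}

#' Count interval overlap events between two sets
#'
#' Counts ordered pairs (x in `a`, y in `b`) whose intervals overlap — the
#' event-level notion of "number of overlaps" used by the enrichment
#' statistic (a single haplotype overlapped by three peaks contributes
#' three events). The count is symmetric in its arguments.
#'
#' @param a,b Interval `data.frame`s (e.g. [peak_set()]s).
#' @return Non-negative integer.
#' @examples
#' a <- genomic_intervals("chr1", c(0, 50), c(10, 90))
#' b <- genomic_intervals("chr1", 5, 60)
#' count_overlap_events(a, b)  # 2
#' @export
count_overlap_events <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(0L)
  sum(count_vs_index(a, overlap_index(b)))
}

#' Annotate regions by peak presence
#'
#' For each region, records whether at least one peak overlaps it — the
#' region-level presence/absence reading used for per-haplotype "+"/"-"
#' mark tables.
#'
#' @param regions Interval `data.frame` of regions (e.g. risk haplotypes).
#' @param peaks A [peak_set()].
#' @return `regions` with two added columns: integer `n_peaks` and logical
#'   `hit`.
#' @export
regions_with_hit <- function(regions, peaks) {
  out <- as.data.frame(regions)
  out$n_peaks <- count_vs_index(out, overlap_index(as.data.frame(peaks)))
  out$hit <- out$n_peaks > 0L
  out
}

# Observed overlap statistic under a chosen unit.
overlap_statistic <- function(regions, idx, unit = c("events", "regions_hit")) {
  unit <- match.arg(unit)
  counts <- count_vs_index(regions, idx)
  if (unit == "events") sum(counts) else sum(counts > 0L)
}
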