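#' Construct a set of genomic intervals
#'
#' Intervals are stored 0-based half-open (BED convention): an interval
#' covers positions `start`, ..., `end - 1`. This is the universal unit for
#' peaks, risk haplotypes, TADs and gene bodies throughout the package.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer-valued vector of 0-based inclusive start positions.
#' @param end Integer-valued vector of exclusive end positions.
#' @param name Optional character vector of labels (recycled `NA` if absent).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   invariant-checked (`0 <= start < end`).
#' @examples
#' genomic_intervals("chr1", 100, 200, "peak1")
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL) {
  n <- length(chrom)
  if (is.null(name)) name <- rep(NA_character_, n)
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end   = as.numeric(end),
    name  = as.character(name),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

#' Validate interval invariants
#'
#' Checks `0 <= start < end` for every row and, when a chromosome model is
#' supplied, that every chromosome is known and every `end` lies within its
#' chromosome.
#'
#' @param x Interval `data.frame` (columns `chrom`, `start`, `end`).
#' @param chrom_sizes Optional named numeric vector of chromosome lengths.
#' @return `x`, invisibly. Errors describe the first offending row.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad)) {
    stop(sprintf(
      "invalid interval at row %d: %s:%s-%s (need 0 <= start < end)",
      bad[1], x$chrom[bad[1]], format(x$start[bad[1]], scientific = FALSE),
      format(x$end[bad[1]], scientific = FALSE)
    ), call. = FALSE)
  }
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(x$chrom), names(chrom_sizes))
    if (length(unknown)) {
      stop("interval chromosome(s) not in chromosome model: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    over <- which(x$end > chrom_sizes[x$chrom])
    if (length(over)) {
      stop(sprintf("interval at row %d extends past the end of %s",
                   over[1], x$chrom[over[1]]), call. = FALSE)
    }
  }
  invisible(x)
}

#' Build a chromosome model
#'
#' @param names Character vector of chromosome names.
#' @param lengths Positive lengths in bp.
#' @return Named numeric vector (name -> length), the package's chromosome
#'   model used for placing random regions and validating intervals.
#' @export
chromosome_model <- function(names, lengths) {
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths)) stop("names/lengths length mismatch")
  if (any(lengths <= 0)) stop("all chromosome lengths must be > 0")
  if (anyDuplicated(names)) stop("duplicated chromosome names")
  stats::setNames(lengths, as.character(names))
}

#' Normalize chromosome naming dialect
#'
#' Public BED files mix "chr1" and "1" styles; this maps a vector of names
#' to one style. Applied only on request, never silently.
#'
#' @param chrom Character vector of chromosome names.
#' @param style `"ucsc"` ("chr1") or `"ensembl"` ("1").
#' @return Renamed character vector.
#' @export
normalize_chrom_names <- function(chrom, style = c("ucsc", "ensembl")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", chrom)
  if (style == "ucsc") paste0("chr", bare) else bare
}

#' Parse a printed locus string into an interval
#'
#' Printed coordinates of the form `"chr1:113,761,186-113,834,946"` are
#' 1-based and inclusive; they are converted on ingest to the internal
#' 0-based half-open convention (`start = A - 1`, `end = B`). Thousands
#' separators are tolerated. Note that the source tables report a "length"
#' equal to `B - A`; that printed length is carried verbatim by the fixture
#' loaders and is one less than the half-open span `B - A + 1`.
#'
#' @param text Character vector of `"chrN:A-B"` strings.
#' @return Interval `data.frame` (one row per string) with the input string
#'   as `name`.
#' @examples
#' parse_region_string("chr1:113,761,186-113,834,946")
#' @export
parse_region_string <- function(text) {
  text <- as.character(text)
  m <- regmatches(text, regexec("^\\s*([A-Za-z0-9_.]+):([0-9,]+)-([0-9,]+)\\s*$", text))
  bad <- which(vapply(m, length, 1L) != 4L)
  if (length(bad)) {
    stop("malformed region string: '", text[bad[1]], "' (expected chrN:A-B)",
         call. = FALSE)
  }
  chrom <- vapply(m, `[`, "", 2L)
  a <- as.numeric(gsub(",", "", vapply(m, `[`, "", 3L)))
  b <- as.numeric(gsub(",", "", vapply(m, `[`, "", 4L)))
  deg <- which(b <= a)
  if (length(deg)) {
    stop("degenerate region string (end <= start): '", text[deg[1]], "'",
         call. = FALSE)
  }
  genomic_intervals(chrom, a - 1, b, name = text)
}

#' Assemble a peak set
#'
#' A peak set is an interval table sorted by (chrom, start, end) carrying a
#' source label (mark/assay/condition). Raw peak files may contain mutually
#' overlapping peaks; no merging is performed.
#'
#' @param x Interval `data.frame`.
#' @param label Source description string.
#' @return Sorted interval `data.frame` of class `peak_set` with attribute
#'   `label`.
#' @export
peak_set <- function(x, label = "peaks") {
  if (nrow(x)) validate_intervals(x)
  if (!"name" %in% names(x)) x$name <- rep(NA_character_, nrow(x))
  extra <- setdiff(names(x), c("chrom", "start", "end", "name"))
  x <- x[order(x$chrom, x$start, x$end),
         c("chrom", "start", "end", "name", extra), drop = FALSE]
  rownames(x) <- NULL
  attr(x, "label") <- label
  class(x) <- c("peak_set", "data.frame")
  x
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s: %d peaks on %d chromosome(s)\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

peak_label <- function(x) attr(x, "label") %||% "peaks"

`%||%` <- function(a, b) if (is.null(a)) b else a
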