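#' Read a BED or narrowPeak file as a peak set
#'
#' Supports headerless, tab-separated BED3+ (first three columns chrom,
#' start, end; a fourth column, when present, is taken as the name) and the
#' 10-column ENCODE narrowPeak dialect (columns beyond the interval and name
#' are ignored). Coordinates are kept exactly as stored in the file
#' (0-based half-open).
#'
#' @param path File path.
#' @param dialect `"bed3plus"` (default) or `"narrowPeak"`.
#' @param label Peak-set label; defaults to the file name.
#' @return A [peak_set()].
#' @export
read_bed <- function(path, dialect = c("bed3plus", "narrowPeak"),
                     label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(peak_set(genomic_intervals(character(), numeric(), numeric()),
                    label = label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  need <- if (dialect == "narrowPeak") 10L else 3L
  short <- which(nfield < need)
  if (length(short)) {
    stop(sprintf("malformed %s line %d in %s: %d column(s), need >= %d",
                 dialect, short[1], path, nfield[short[1]], need),
         call. = FALSE)
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  badnum <- which(is.na(start) | is.na(end))
  if (length(badnum)) {
    stop(sprintf("malformed line %d in %s: non-numeric coordinates",
                 badnum[1], path), call. = FALSE)
  }
  badspan <- which(start >= end | start < 0)
  if (length(badspan)) {
    stop(sprintf("invalid interval at line %d in %s: start %s, end %s",
                 badspan[1], path,
                 format(start[badspan[1]], scientific = FALSE),
                 format(end[badspan[1]], scientific = FALSE)), call. = FALSE)
  }
  name <- ifelse(nfield >= 4L, vapply(fields, function(f) f[4], ""),
                 NA_character_)
  name[name %in% c(".", "")] <- NA_character_
  x <- genomic_intervals(chrom, start, end, name)
  if (dialect == "narrowPeak") {
    # column 7 is signalValue in the ENCODE dialect; kept for the optional
    # minimum-signal anchor filter, otherwise ignored
    x$signal <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 7L)))
  }
  peak_set(x, label = label)
}

#' Write a peak set as BED
#'
#' Emits sorted, tab-separated BED3 (plus a 4th name column when any name is
#' set). `read_bed(write_bed(x))` reproduces `x`'s intervals exactly.
#'
#' @param peaks A [peak_set()] or interval `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  x <- as.data.frame(peaks)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  has_name <- "name" %in% names(x) && any(!is.na(x$name))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(x)) {
    out <- paste(x$chrom,
                 format(x$start, scientific = FALSE, trim = TRUE),
                 format(x$end, scientific = FALSE, trim = TRUE),
                 sep = "\t")
    if (has_name) {
      nm <- ifelse(is.na(x$name), ".", x$name)
      out <- paste(out, nm, sep = "\t")
    }
    writeLines(out, con)
  }
  invisible(path)
}

#' Read a UCSC chrom.sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path File path.
#' @return A [chromosome_model()] (named numeric vector).
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "numeric"),
                         col.names = c("chrom", "size"))
  chromosome_model(x$chrom, x$size)
}

#' Write a chromosome model as a chrom.sizes file
#' @param model Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(model, path) {
  writeLines(paste(names(model),
                   format(model, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}
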