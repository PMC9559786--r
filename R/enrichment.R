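#' Random-region enrichment test
#'
#' The test asks whether a peak set (histone ChIP-seq, GRO-seq enhancer
#' calls, ...) overlaps a set of risk regions more than expected from the
#' genome background. The null is built by dropping `n_regions` random
#' regions of fixed length (the mean risk-haplotype length) uniformly on
#' the genome, counting their overlap with the peaks, and repeating
#' `n_replicates` times; a normal distribution is fitted to the replicate
#' counts and the observed count is converted to a one-sided upper-tail
#' p-value.
#'
#' @name enrichment
NULL

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Null-model configuration
#'
#' Defaults mirror the risk-haplotype study design: 36 random regions of
#' 86,676 bp (the mean haplotype length), 1000 replicates. For
#' MPRA-region enrichment the same engine is reused with `n_regions = 18`
#' and `region_length = mean_region_length(<MPRA regions>)`.
#'
#' @param n_regions Random regions per replicate (>= 1).
#' @param region_length Region length in bp (>= 1); typically
#'   [mean_region_length()] of the query regions.
#' @param n_replicates Number of replicates (>= 2).
#' @param seed Integer seed recorded in every result; no global RNG state is
#'   consumed.
#' @param overlap_unit `"events"` (peak x region intersecting pairs; the
#'   default, matching the test statistic) or `"regions_hit"` (regions with
#'   >= 1 peak, the "+"/"-" table reading).
#' @param exclusion_mask Optional interval `data.frame`; random regions
#'   overlapping the mask are redrawn. Default empty (no gap/blacklist
#'   exclusion).
#' @return A list of class `null_config`.
#' @export
null_config <- function(n_regions = 36L, region_length = 86676L,
                        n_replicates = 1000L, seed = 1L,
                        overlap_unit = c("events", "regions_hit"),
                        exclusion_mask = NULL) {
  overlap_unit <- match.arg(overlap_unit)
  stopifnot(n_regions >= 1, region_length >= 1, n_replicates >= 2)
  structure(
    list(n_regions = as.integer(n_regions),
         region_length = as.numeric(region_length),
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed),
         overlap_unit = overlap_unit,
         exclusion_mask = exclusion_mask),
    class = "null_config"
  )
}

#' Mean region length
#'
#' Arithmetic mean of the supplied lengths, rounded down to an integer
#' number of bp — the length given to every random region. For the
#' packaged risk-haplotype table the printed (1-based, `B - A`) lengths
#' are used and yield 86,676 bp.
#'
#' @param x Numeric vector of lengths, or a `data.frame` with a `length`
#'   column (e.g. [jia_haplotypes()]).
#' @return Integer-valued mean length (floor).
#' @export
mean_region_length <- function(x) {
  if (is.data.frame(x)) {
    if (!"length" %in% names(x)) stop("data.frame input needs a 'length' column")
    x <- x$length
  }
  x <- as.numeric(x)
  if (!length(x)) stop("cannot take the mean region length of zero regions")
  floor(mean(x))
}

#' Draw one replicate of random regions
#'
#' Places `cfg$n_regions` intervals of exactly `cfg$region_length` bp, each
#' wholly inside one chromosome: the chromosome is chosen with probability
#' proportional to its number of valid start positions
#' (`length - region_length + 1`) and the start is uniform over those
#' positions. Regions may overlap one another and any real feature; if
#' `cfg$exclusion_mask` is set, regions intersecting the mask are redrawn.
#'
#' @param model A [chromosome_model()].
#' @param cfg A [null_config()].
#' @param seed Optional integer; if `NULL` the current RNG stream is used
#'   (as inside [build_null()]).
#' @return A [peak_set()] of random regions.
#' @export
draw_random_regions <- function(model, cfg, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, draw_random_regions(model, cfg)))
  len <- cfg$region_length
  valid <- model - len + 1
  ok <- valid >= 1
  if (!any(ok)) {
    stop("no chromosome can contain a region of length ",
         format(len, scientific = FALSE), call. = FALSE)
  }
  w <- ifelse(ok, valid, 0)
  draw <- function(n) {
    ci <- sample.int(length(model), n, replace = TRUE, prob = w)
    start <- floor(stats::runif(n) * valid[ci])
    data.frame(chrom = names(model)[ci], start = start, end = start + len,
               stringsAsFactors = FALSE)
  }
  regions <- draw(cfg$n_regions)
  if (!is.null(cfg$exclusion_mask) && nrow(cfg$exclusion_mask)) {
    midx <- overlap_index(as.data.frame(cfg$exclusion_mask))
    for (tries in 1:1000) {
      bad <- which(count_vs_index(regions, midx) > 0L)
      if (!length(bad)) break
      regions[bad, ] <- draw(length(bad))
    }
    if (length(which(count_vs_index(regions, midx) > 0L)))
      stop("could not place random regions outside the exclusion mask")
  }
  regions$name <- sprintf("rand_%03d", seq_len(nrow(regions)))
  peak_set(regions, label = "random_regions")
}

#' Build the null distribution of overlap counts
#'
#' Repeats the random-region draw `cfg$n_replicates` times and records, per
#' replicate, the overlap count (per `cfg$overlap_unit`) between the peaks
#' and that replicate's regions. The normal fit uses the sample mean and
#' the n-1 sample standard deviation; no continuity correction.
#'
#' @param peaks A [peak_set()].
#' @param model A [chromosome_model()].
#' @param cfg A [null_config()] (its `seed` drives the whole draw).
#' @return A list of class `null_distribution` with `replicate_counts`,
#'   `mu_hat`, `sigma_hat`, `degenerate` (`sigma_hat == 0`) and `cfg`.
#' @export
build_null <- function(peaks, model, cfg) {
  validate_intervals(as.data.frame(peaks), chrom_sizes = model)
  idx <- overlap_index(as.data.frame(peaks))
  counts <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_replicates), function(i) {
      r <- draw_random_regions(model, cfg)
      overlap_statistic(r, idx, cfg$overlap_unit)
    }, numeric(1))
  })
  structure(
    list(replicate_counts = counts,
         mu_hat = mean(counts),
         sigma_hat = stats::sd(counts),
         degenerate = stats::sd(counts) == 0,
         cfg = cfg),
    class = "null_distribution"
  )
}

#' Normal-approximation enrichment p-value
#'
#' Computes the observed overlap `k_obs` between the risk regions and the
#' peaks (same unit as the null), fits the null via [build_null()], and
#' reports `z = (k_obs - mu_hat) / sigma_hat` with the one-sided
#' upper-tail normal p-value (enrichment only; depletion is not tested).
#' The p-value is floored at 1e-300 to avoid underflow.
#'
#' @param haplotypes Interval `data.frame` of risk regions.
#' @param peaks A [peak_set()].
#' @param model A [chromosome_model()].
#' @param cfg A [null_config()].
#' @param alpha Significance level (default 0.05).
#' @return A list of class `enrichment_result`: `label`, `k_obs`, `mu_hat`,
#'   `sigma_hat`, `z`, `p_value`, `significant`, `null`, `cfg`.
#' @export
enrichment_p <- function(haplotypes, peaks, model, cfg = null_config(),
                         alpha = 0.05) {
  null <- build_null(peaks, model, cfg)
  if (null$degenerate) {
    stop("degenerate null (sigma_hat == 0): the normal approximation is ",
         "undefined; use empirical_p() on the replicate counts instead",
         call. = FALSE)
  }
  k_obs <- overlap_statistic(as.data.frame(haplotypes),
                             overlap_index(as.data.frame(peaks)),
                             cfg$overlap_unit)
  z <- (k_obs - null$mu_hat) / null$sigma_hat
  p <- max(stats::pnorm(z, lower.tail = FALSE), 1e-300)
  structure(
    list(label = peak_label(peaks), k_obs = k_obs,
         mu_hat = null$mu_hat, sigma_hat = null$sigma_hat,
         z = z, p_value = p, alpha = alpha, significant = p < alpha,
         null = null, cfg = cfg),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %s\n  k_obs = %s, null mean = %.2f, sd = %.2f\n  z = %.3f, one-sided p = %.3g%s\n",
    x$label, format(x$k_obs, scientific = FALSE), x$mu_hat, x$sigma_hat,
    x$z, x$p_value,
    if (x$significant) sprintf(" (significant at alpha = %g)", x$alpha) else ""
  ))
  invisible(x)
}

#' Empirical permutation p-value
#'
#' Rank-based fallback when the normal approximation is poor or the null is
#' degenerate: `(1 + #\{replicates >= k_obs\}) / (n_replicates + 1)`.
#'
#' @param null A `null_distribution` (or an `enrichment_result`, whose null
#'   is used).
#' @param k_obs Observed overlap count; defaults to the result's `k_obs`
#'   when an `enrichment_result` is given.
#' @return p-value in (0, 1].
#' @export
empirical_p <- function(null, k_obs = NULL) {
  if (inherits(null, "enrichment_result")) {
    if (is.null(k_obs)) k_obs <- null$k_obs
    null <- null$null
  }
  if (is.null(k_obs)) stop("k_obs is required")
  r <- null$replicate_counts
  if (!length(r)) stop("empty replicate counts")
  (1 + sum(r >= k_obs)) / (length(r) + 1)
}
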