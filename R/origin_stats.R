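#' Inter-origin distances from a peak set
#'
#' Distances are successive differences of peak midpoints within each
#' chromosome (center-to-center); chromosomes with fewer than two peaks
#' contribute none. The global summary pools the distances of all
#' chromosomes rather than averaging per-chromosome medians.
#'
#' @param peaks Peak data frame with columns `chrom` and `midpoint` (or
#'   `start`/`end` from which midpoints are derived).
#'
#' @return List with `per_chrom` (named list of distance vectors in bp),
#'   `distances` (pooled vector) and `summary` (a [distance_summary()] row).
#' @export
inter_origin_distances <- function(peaks) {
  if (is.null(peaks$midpoint)) {
    peaks$midpoint <- floor((peaks$start + peaks$end) / 2)
  }
  per_chrom <- lapply(split(peaks$midpoint, peaks$chrom), function(m) {
    if (length(m) < 2L) numeric(0) else diff(sort(m))
  })
  per_chrom <- per_chrom[order(names(per_chrom))]
  pooled <- unlist(per_chrom, use.names = FALSE) %||% numeric(0)
  list(per_chrom = per_chrom, distances = pooled,
       summary = distance_summary(pooled))
}

#' Five-number summary for a distance distribution
#'
#' Median, quartiles and Tukey whiskers (most extreme observations within
#' 1.5 IQR of the quartiles), as drawn in a box-and-whiskers plot.
#'
#' @param x Numeric vector.
#' @return One-row data frame with `n`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`.
#' @export
distance_summary <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(data.frame(n = 0L, median = NA_real_, q1 = NA_real_,
                      q3 = NA_real_, whisker_low = NA_real_,
                      whisker_high = NA_real_))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  data.frame(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
             whisker_low = min(x[x >= q[1] - 1.5 * iqr]),
             whisker_high = max(x[x <= q[3] + 1.5 * iqr]))
}

#' Overlap between two peak sets
#'
#' A peak in one set overlaps the other if it shares at least one bp with
#' any peak there (half-open intervals). Both directions are reported,
#' because the two denominators differ even though the count of overlapping
#' pairs is symmetric.
#'
#' @param a,b Peak data frames (`chrom`, `start`, `end`).
#' @return List with `n_a`, `n_a_in_b`, `frac_a_in_b` and the mirrored
#'   `n_b`, `n_b_in_a`, `frac_b_in_a`.
#' @export
overlap_fraction <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(list(n_a = nrow(a), n_a_in_b = 0L, frac_a_in_b = NaN,
                n_b = nrow(b), n_b_in_a = 0L, frac_b_in_a = NaN))
  }
  lv <- union(unique(a$chrom), unique(b$chrom))
  ga <- as_granges(a, seqlevels = lv)
  gb <- as_granges(b, seqlevels = lv)
  a_hit <- GenomicRanges::countOverlaps(ga, gb) > 0
  b_hit <- GenomicRanges::countOverlaps(gb, ga) > 0
  list(n_a = nrow(a), n_a_in_b = sum(a_hit), frac_a_in_b = mean(a_hit),
       n_b = nrow(b), n_b_in_a = sum(b_hit), frac_b_in_a = mean(b_hit))
}

#' Default mirrored log-spaced bins for TSS-distance histograms
#'
#' Ten log-spaced magnitude bins from 1 kb to 1 Mb mirrored about zero,
#' with open outer bins. Purely presentational.
#'
#' @return Numeric vector of bin edges.
#' @export
tss_distance_breaks <- function() {
  mags <- 10^seq(3, 6, length.out = 10)
  c(-Inf, -rev(mags), 0, mags, Inf)
}

#' Distribution of peak distances to the nearest TSS
#'
#' For each peak, the signed distance from its midpoint to the nearest TSS
#' on the same chromosome: positive downstream (3') of the TSS relative to
#' the TSS strand, negative upstream. Equidistant ties resolve to the
#' lower-coordinate TSS. Peaks on chromosomes without any TSS are excluded
#' and counted.
#'
#' @param peaks Peak data frame (`chrom`, `midpoint` or `start`/`end`).
#' @param tss TSS data frame (`chrom`, `pos`, `strand`).
#' @param breaks Histogram bin edges for the signed distances.
#'
#' @return List with `distances` (signed bp, one per usable peak),
#'   `counts` (named bin counts), `breaks` and `n_excluded`.
#' @export
tss_distance_distribution <- function(peaks, tss,
                                      breaks = tss_distance_breaks()) {
  if (is.null(tss) || nrow(tss) == 0L) {
    stop("the TSS set is empty", call. = FALSE)
  }
  if (is.null(peaks$midpoint)) {
    peaks$midpoint <- floor((peaks$start + peaks$end) / 2)
  }
  dist_all <- numeric(0)
  n_excluded <- 0L
  for (cm in unique(peaks$chrom)) {
    mids <- peaks$midpoint[peaks$chrom == cm]
    t_cm <- tss[tss$chrom == cm, , drop = FALSE]
    if (nrow(t_cm) == 0L) {
      n_excluded <- n_excluded + length(mids)
      next
    }
    o <- order(t_cm$pos)
    tpos <- t_cm$pos[o]
    tstr <- t_cm$strand[o]
    j <- findInterval(mids, tpos)
    left <- pmax(j, 1L)
    right <- pmin(j + 1L, length(tpos))
    d_left <- abs(mids - tpos[left])
    d_right <- abs(mids - tpos[right])
    use_left <- j >= 1L & (j >= length(tpos) | d_left <= d_right)
    k <- ifelse(use_left, left, right)
    signed <- mids - tpos[k]
    signed <- ifelse(tstr[k] == "-", -signed, signed)
    dist_all <- c(dist_all, signed)
  }
  counts <- table(cut(dist_all, breaks = breaks, right = FALSE))
  list(distances = dist_all, counts = counts, breaks = breaks,
       n_excluded = n_excluded)
}

#' Compare two inter-origin-distance distributions
#'
#' Summarises both distance samples (n, median, quartiles, whiskers) and
#' tests for a location difference with a two-sided Wilcoxon rank-sum test,
#' the appropriate test for these right-skewed distributions.
#'
#' @param a,b Numeric distance vectors (non-empty).
#' @param labels Length-2 condition labels used in the summary table.
#' @param mode Passed to [wilcoxon_rank_sum()].
#'
#' @return List with `summary` (two-row data frame), `median_diff`
#'   (median(b) - median(a)) and `test` (the Wilcoxon result).
#' @export
compare_conditions <- function(a, b, labels = c("A", "B"), mode = "auto") {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both distance lists must be non-empty", call. = FALSE)
  }
  sm <- rbind(distance_summary(a), distance_summary(b))
  sm <- cbind(condition = labels, sm)
  test <- wilcoxon_rank_sum(a, b, mode = mode)
  list(summary = sm,
       median_diff = stats::median(b) - stats::median(a),
       test = test)
}
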