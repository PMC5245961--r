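#' Call origin peaks from windowed BrIP-seq counts
#'
#' The fixed-window origin caller. In order:
#' \enumerate{
#'   \item \strong{Enrichment filter}: windows whose sample count is at
#'     least `fold` times the (library-scaled) control count form the
#'     enriched set E. Windows with a raw control count of zero use
#'     `control_pseudocount` in place of the scaled control so the ratio is
#'     defined everywhere.
#'   \item \strong{Threshold}: the mean and (population) SD of the sample
#'     counts over E give the significance threshold
#'     mean + `sd_mult` * SD.
#'   \item \strong{Significant windows}: members of the threshold domain
#'     (by default E itself) whose sample count is `>=` the threshold.
#'   \item \strong{Merging}: runs of adjacent significant windows become one
#'     origin peak whose midpoint is `floor((start + end) / 2)`.
#' }
#' An empty enriched set yields an empty peak list with a warning.
#'
#' @param sample,control [window_counts()] objects on the same grid.
#' @param cfg A [peak_call_config()].
#'
#' @return Data frame of class `origin_peaks` with columns `chrom`,
#'   `start`, `end`, `midpoint`, `n_windows`, `sample_count`,
#'   `scaled_control`, sorted by coordinate. The attribute `"report"`
#'   (see [peak_report()]) records library totals, the enriched-set size,
#'   mean, SD, threshold and peak count.
#' @export
call_peaks <- function(sample, control, cfg = peak_call_config()) {
  stopifnot(inherits(sample, "window_counts"),
            inherits(control, "window_counts"),
            inherits(cfg, "peak_call_config"))
  check_same_grid(sample, control)
  if (sample$window_size != cfg$window_size) {
    stop("'cfg$window_size' does not match the window grid", call. = FALSE)
  }
  sc <- scale_control(sample, control, cfg$library_scale)
  chroms <- names(sample$counts)
  s_all <- unlist(sample$counts, use.names = FALSE)
  c_raw <- unlist(control$counts, use.names = FALSE)
  c_scl <- unlist(sc$counts, use.names = FALSE)
  denom <- ifelse(c_raw == 0, cfg$control_pseudocount, c_scl)
  enriched <- s_all >= cfg$fold * denom
  report <- list(
    window_size = sample$window_size, n_windows = length(s_all),
    total_sample = sample$total_assigned,
    total_control = control$total_assigned,
    scale_factor = sc$scale_factor, n_enriched = sum(enriched),
    mu = NA_real_, sigma = NA_real_, threshold = NA_real_,
    n_significant = 0L, n_peaks = 0L)
  empty <- empty_peaks()
  if (!any(enriched)) {
    warning("no windows pass the enrichment filter; returning no peaks",
            call. = FALSE)
    attr(empty, "report") <- report
    return(empty)
  }
  e_vals <- s_all[enriched]
  mu <- mean(e_vals)
  sigma <- if (cfg$sd_type == "population") {
    sqrt(mean((e_vals - mu)^2))
  } else {
    stats::sd(e_vals)
  }
  if (is.na(sigma)) sigma <- 0   # single enriched window, sample SD
  threshold <- mu + cfg$sd_mult * sigma
  eligible <- if (cfg$threshold_domain == "enriched_only") {
    enriched
  } else {
    rep(TRUE, length(s_all))
  }
  significant <- eligible & s_all >= threshold
  report$mu <- mu
  report$sigma <- sigma
  report$threshold <- threshold
  report$n_significant <- sum(significant)
  ## split the flat mask back per chromosome and merge adjacent windows
  offsets <- c(0L, cumsum(lengths(sample$counts)))
  peaks <- list()
  for (k in seq_along(chroms)) {
    cm <- chroms[k]
    idx <- which(significant[(offsets[k] + 1L):offsets[k + 1L]])
    if (!length(idx)) next
    grp <- if (cfg$merge) cumsum(c(1L, diff(idx) != 1L)) else seq_along(idx)
    w <- sample$window_size
    sz <- sample$chrom_sizes[[cm]]
    sv <- sample$counts[[cm]]
    cv <- sc$counts[[cm]]
    for (g in split(idx, grp)) {
      start <- (min(g) - 1L) * w
      end <- min(max(g) * w, sz)
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = cm, start = as.integer(start), end = as.integer(end),
        midpoint = as.integer(floor((start + end) / 2)),
        n_windows = length(g), sample_count = sum(sv[g]),
        scaled_control = sum(cv[g]), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(peaks)) do.call(rbind, peaks) else empty
  rownames(out) <- NULL
  class(out) <- c("origin_peaks", "data.frame")
  report$n_peaks <- nrow(out)
  attr(out, "report") <- report
  out
}

empty_peaks <- function() {
  out <- data.frame(chrom = character(), start = integer(),
                    end = integer(), midpoint = integer(),
                    n_windows = integer(), sample_count = numeric(),
                    scaled_control = numeric(), stringsAsFactors = FALSE)
  class(out) <- c("origin_peaks", "data.frame")
  out
}

#' Run report of a peak call
#'
#' @param peaks An `origin_peaks` object from [call_peaks()].
#' @return Named list with library totals, scale factor, enriched-set size,
#'   mean, SD, threshold, and counts of significant windows and peaks.
#' @export
peak_report <- function(peaks) {
  attr(peaks, "report")
}

#' Write / read origin peaks as BED
#'
#' BED6 with the peak's summed sample read count in the score column; a
#' leading `#` header line documents the columns. Reading reconstructs the
#' midpoint from the interval; the scaled control column is not representable
#' in BED6 and comes back as `NA`.
#'
#' @param peaks An `origin_peaks` data frame.
#' @param path File path.
#' @return `read_peaks` returns an `origin_peaks` data frame.
#' @export
write_peaks <- function(peaks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore(sample_count)\tstrand", con)
  if (nrow(peaks)) {
    df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                     sprintf("peak_%05d", seq_len(nrow(peaks))),
                     peaks$sample_count, ".", stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  df <- load_reads_bed(path)
  out <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    midpoint = as.integer(floor((df$start + df$end) / 2)),
    n_windows = rep(NA_integer_, nrow(df)), sample_count = df$score,
    scaled_control = rep(NA_real_, nrow(df)), stringsAsFactors = FALSE)
  class(out) <- c("origin_peaks", "data.frame")
  out
}
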