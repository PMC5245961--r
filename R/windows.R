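#' Construct a per-chromosome window-count object
#'
#' Container for fixed-window read tallies on a genome grid. Mostly produced
#' by [count_windows()]; the constructor is exported so count vectors can be
#' assembled programmatically (e.g. for small worked examples).
#'
#' @param counts Named list of numeric count vectors, one per chromosome;
#'   vector `i` covers `[(i-1) * window_size, i * window_size)`.
#' @param window_size Window size in bp.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#'
#' @return An object of class `window_counts` with elements `window_size`,
#'   `counts`, `chrom_sizes` and `total_assigned`.
#' @export
window_counts <- function(counts, window_size, chrom_sizes) {
  check_num(window_size, "window_size", lower = 1)
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  if (!is.list(counts) || !setequal(names(counts), names(chrom_sizes))) {
    stop("'counts' must be a list named by the chromosomes in 'chrom_sizes'",
         call. = FALSE)
  }
  counts <- counts[names(chrom_sizes)]
  for (cm in names(chrom_sizes)) {
    nb <- ceiling(chrom_sizes[[cm]] / window_size)
    if (length(counts[[cm]]) != nb) {
      stop(sprintf("'%s' needs %d windows, got %d", cm, nb,
                   length(counts[[cm]])), call. = FALSE)
    }
    if (any(counts[[cm]] < 0)) {
      stop("window counts must be non-negative", call. = FALSE)
    }
  }
  structure(
    list(window_size = as.integer(window_size), counts = counts,
         chrom_sizes = chrom_sizes,
         total_assigned = sum(vapply(counts, sum, numeric(1)))),
    class = "window_counts"
  )
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("window_counts: %d bp windows on %d chromosome(s), %s reads\n",
              x$window_size, length(x$counts),
              format(x$total_assigned, big.mark = ",")))
  invisible(x)
}

#' Tally reads into fixed genome windows
#'
#' Divides every chromosome into `window_size` bp windows and assigns each
#' read to exactly one window by its 5' position (the start for
#' plus-strand reads, the last base for minus-strand reads; unstranded
#' reads count by their start). Totals are conserved.
#'
#' @param reads Reads data frame (`chrom`, `start`, `end`, `strand`),
#'   0-based half-open, within chromosome bounds.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param window_size Window size in bp.
#'
#' @return A [window_counts()] object.
#' @export
count_windows <- function(reads, chrom_sizes, window_size = 1000) {
  if (!is.numeric(window_size) || length(window_size) != 1L ||
      is.na(window_size) || window_size <= 0) {
    stop("'window_size' must be a positive number", call. = FALSE)
  }
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  if (nrow(reads)) {
    if (!all(reads$chrom %in% names(chrom_sizes))) {
      stop("reads on chromosomes absent from 'chrom_sizes'", call. = FALSE)
    }
    if (any(reads$start < 0) ||
        any(reads$end > chrom_sizes[reads$chrom])) {
      stop("reads must lie within chromosome bounds", call. = FALSE)
    }
  }
  pos5 <- ifelse(reads$strand == "-", reads$end - 1L, reads$start)
  counts <- lapply(names(chrom_sizes), function(cm) {
    nb <- ceiling(chrom_sizes[[cm]] / window_size)
    p <- pos5[reads$chrom == cm]
    tabulate(p %/% window_size + 1L, nbins = nb)
  })
  names(counts) <- names(chrom_sizes)
  window_counts(counts, window_size, chrom_sizes)
}

#' Scale control counts to the sample library size
#'
#' Multiplies every control window count by
#' `total_assigned(sample) / total_assigned(control)` so that the fold
#' comparison is made at equal sequencing depth. With
#' `library_scale = FALSE` the control is returned unchanged (raw-count
#' comparison).
#'
#' @param sample,control [window_counts()] objects on the same grid.
#' @param library_scale Apply the depth scaling.
#'
#' @return A `window_counts`-shaped object whose counts may be fractional,
#'   with an extra element `scale_factor`.
#' @export
scale_control <- function(sample, control, library_scale = TRUE) {
  check_same_grid(sample, control)
  if (control$total_assigned == 0) {
    stop("control library has zero assigned reads; cannot scale",
         call. = FALSE)
  }
  f <- if (isTRUE(library_scale)) {
    sample$total_assigned / control$total_assigned
  } else {
    1
  }
  out <- control
  out$counts <- lapply(control$counts, function(v) v * f)
  out$total_assigned <- control$total_assigned * f
  out$scale_factor <- f
  out
}

check_same_grid <- function(a, b) {
  if (a$window_size != b$window_size ||
      !identical(names(a$counts), names(b$counts)) ||
      !isTRUE(all.equal(unname(a$chrom_sizes), unname(b$chrom_sizes)))) {
    stop("sample and control window counts are not on the same grid",
         call. = FALSE)
  }
  invisible(TRUE)
}
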