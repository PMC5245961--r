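`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## scalar numeric check with range; `name` is used in the error message
check_num <- function(x, name, lower = -Inf, upper = Inf,
                      allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (!is.na(x) && (x < lower || x > upper)) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

check_chrom_sizes <- function(chrom_sizes) {
  if (is.list(chrom_sizes)) chrom_sizes <- unlist(chrom_sizes)
  if (length(chrom_sizes) == 0L || is.null(names(chrom_sizes)) ||
      any(!nzchar(names(chrom_sizes))) || anyDuplicated(names(chrom_sizes))) {
    stop("'chrom_sizes' must be a named vector with unique chromosome names",
         call. = FALSE)
  }
  if (!is.numeric(chrom_sizes) || any(is.na(chrom_sizes)) ||
      any(chrom_sizes <= 0)) {
    stop("all chromosome sizes must be positive numbers", call. = FALSE)
  }
  chrom_sizes
}

## a minimal reads data frame used throughout (0-based, half-open)
new_reads <- function(chrom, start, end, strand, origin = NA_integer_,
                      prefix = "read") {
  n <- length(chrom)
  origin <- rep(as.integer(origin), length.out = n)
  data.frame(
    chrom = as.character(chrom),
    start = as.integer(round(start)),
    end = as.integer(round(end)),
    name = if (n) sprintf("%s_%06d", prefix, seq_len(n)) else character(),
    score = integer(n),
    strand = as.character(strand),
    origin = origin,
    stringsAsFactors = FALSE
  )
}

sort_reads <- function(reads, chrom_order = NULL) {
  if (nrow(reads) == 0L) return(reads)
  chrom_fac <- if (is.null(chrom_order)) {
    factor(reads$chrom)
  } else {
    factor(reads$chrom, levels = chrom_order)
  }
  reads <- reads[order(chrom_fac, reads$start, reads$end), , drop = FALSE]
  rownames(reads) <- NULL
  reads
}

## GRanges helpers (1-based closed <-> 0-based half-open bed-style frames)
as_granges <- function(df, width1 = FALSE, seqlevels = NULL) {
  lv <- seqlevels %||% unique(df$chrom)
  if (width1) {
    rng <- IRanges::IRanges(start = df$pos + 1L, width = 1L)
  } else {
    rng <- IRanges::IRanges(start = df$start + 1L, end = df$end)
  }
  GenomicRanges::GRanges(factor(df$chrom, levels = lv), rng)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
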