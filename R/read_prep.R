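validate_fastq <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("id", "sequence", "quality") %in% names(records))) {
    stop("FASTQ records must be a data frame with columns ",
         "'id', 'sequence', 'quality'", call. = FALSE)
  }
  bad <- which(nchar(records$sequence) != nchar(records$quality))
  if (length(bad)) {
    stop(sprintf("sequence/quality length mismatch in record %d ('%s')",
                 bad[1], records$id[bad[1]]), call. = FALSE)
  }
  invisible(records)
}

#' Trim 3' poly-T tails from reads
#'
#' Removes the maximal run of trailing T bases from each sequence and
#' truncates the quality string in lockstep. Reads shorter than
#' `min_len_after` after trimming are flagged as discarded (not removed, so
#' callers can account for them). The operation is idempotent and never
#' lengthens a read. An N is not part of a T-run: a trailing N stops
#' trimming.
#'
#' @param records FASTQ data frame (`id`, `sequence`, `quality`).
#' @param min_len_after Minimum post-trim length below which a read is
#'   flagged as discarded.
#' @param verbose Emit a one-line summary message.
#'
#' @return The records with trimmed `sequence`/`quality` plus columns
#'   `bases_trimmed` and `discarded`.
#' @export
trim_polyt <- function(records, min_len_after = 20, verbose = FALSE) {
  validate_fastq(records)
  check_num(min_len_after, "min_len_after", lower = 0)
  out <- records
  out$sequence <- sub("T*$", "", records$sequence)
  keep_len <- nchar(out$sequence)
  out$quality <- substr(records$quality, 1L, keep_len)
  out$bases_trimmed <- nchar(records$sequence) - keep_len
  out$discarded <- keep_len < min_len_after
  if (verbose) {
    message(sprintf(
      "trim_polyt: %d reads in, %d bases trimmed, %d discarded (< %d bp)",
      nrow(out), sum(out$bases_trimmed), sum(out$discarded),
      as.integer(min_len_after)))
  }
  out
}

#' Read / write FASTQ files
#'
#' Thin wrappers around Biostrings FASTQ I/O exchanging the package's plain
#' `id`/`sequence`/`quality` record frame.
#'
#' @param path File path.
#' @param records FASTQ data frame (`id`, `sequence`, `quality`).
#' @return `read_fastq` returns a FASTQ record data frame.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(records, path) {
  validate_fastq(records)
  s <- Biostrings::DNAStringSet(records$sequence)
  names(s) <- records$id
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                records$quality))
  invisible(path)
}

#' Load aligned single-end reads from a BED file
#'
#' Parses BED3-6 (whitespace-delimited, 0-based half-open; `#`, `track` and
#' `browser` lines are skipped). Malformed lines raise an error naming the
#' line number. When a chromosome-sizes table is supplied, records on
#' unknown chromosomes or extending beyond a chromosome end are rejected and
#' tallied rather than raising.
#'
#' @param path BED file path.
#' @param chrom_sizes Optional named numeric vector of chromosome lengths.
#' @param verbose Emit a summary message with read / rejected counts.
#'
#' @return Reads data frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`) with attribute `n_rejected`.
#' @export
load_reads_bed <- function(path, chrom_sizes = NULL, verbose = FALSE) {
  lines <- readLines(path)
  ln <- seq_along(lines)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  ln <- ln[keep]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) {
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1]
    stop(sprintf("malformed BED line %d: expected at least 3 fields, got %d",
                 ln[i], nf[i]), call. = FALSE)
  }
  f <- function(k, default) {
    vapply(fields, function(x) if (length(x) >= k) x[k] else default,
           character(1))
  }
  start <- suppressWarnings(as.integer(f(2, NA)))
  end <- suppressWarnings(as.integer(f(3, NA)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf(
      "malformed BED line %d: start/end must be integers with 0 <= start < end",
      ln[bad[1]]), call. = FALSE)
  }
  strand <- f(6, ".")
  bad_strand <- which(!strand %in% c("+", "-", "."))
  if (length(bad_strand)) {
    stop(sprintf("malformed BED line %d: strand must be '+', '-' or '.'",
                 ln[bad_strand[1]]), call. = FALSE)
  }
  out <- data.frame(
    chrom = f(1, NA), start = start, end = end, name = f(4, "."),
    score = suppressWarnings(as.numeric(f(5, "0"))), strand = strand,
    stringsAsFactors = FALSE)
  out$score[is.na(out$score)] <- 0
  n_rejected <- 0L
  if (!is.null(chrom_sizes)) {
    chrom_sizes <- check_chrom_sizes(chrom_sizes)
    known <- out$chrom %in% names(chrom_sizes)
    inb <- known
    inb[known] <- out$end[known] <= chrom_sizes[out$chrom[known]]
    n_rejected <- sum(!inb)
    out <- out[inb, , drop = FALSE]
    rownames(out) <- NULL
  }
  if (verbose) {
    message(sprintf("load_reads_bed: %d reads loaded, %d rejected",
                    nrow(out), n_rejected))
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write reads to a BED6 file
#'
#' @param reads Reads data frame (`chrom`, `start`, `end`, and optionally
#'   `name`, `score`, `strand`).
#' @param path File path.
#' @export
write_reads_bed <- function(reads, path) {
  df <- data.frame(chrom = reads$chrom, start = reads$start,
                   end = reads$end, name = reads$name %||% ".",
                   score = reads$score %||% 0,
                   strand = reads$strand %||% ".",
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a chromosome-sizes table
#'
#' Two-column `chrom<TAB>length` text format.
#'
#' @param chrom_sizes Named numeric vector.
#' @param path File path.
#' @return `read_chrom_sizes` returns a named numeric vector.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  writeLines(sprintf("%s\t%d", names(chrom_sizes),
                     as.integer(chrom_sizes)), path)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  check_chrom_sizes(stats::setNames(df$length, df$chrom))
}
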