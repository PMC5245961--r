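#' Simulate a TSS annotation
#'
#' Places transcription start sites uniformly over the genome with random
#' strands. Used as the annotation against which origin/TSS distances are
#' computed and as the anchor set for TSS-biased origin placement.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param n_tss Number of TSS records.
#' @param seed Integer seed.
#'
#' @return Data frame with columns `chrom`, `pos` (0-based bp), `strand`,
#'   sorted by chromosome and position.
#' @export
simulate_tss <- function(chrom_sizes, n_tss, seed = 1L) {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  check_num(n_tss, "n_tss", lower = 0)
  withr::with_seed(seed, {
    if (n_tss == 0) {
      return(data.frame(chrom = character(), pos = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    }
    chrom <- sample(names(chrom_sizes), n_tss, replace = TRUE,
                    prob = chrom_sizes)
    pos <- floor(stats::runif(n_tss) * chrom_sizes[chrom])
    strand <- sample(c("+", "-"), n_tss, replace = TRUE)
    out <- data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
                      stringsAsFactors = FALSE)
    out <- out[order(factor(out$chrom, levels = names(chrom_sizes)),
                     out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

## rejection placement of n positions on one chromosome, at least
## `min_spacing` bp from each other and from `existing` positions
place_on_chrom <- function(chrom, size, n, min_spacing, existing = numeric()) {
  accepted <- sort(existing)
  placed <- numeric(0)
  max_tries <- 1000L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- floor(stats::runif(1) * size)
      if (length(accepted) == 0L ||
          min(abs(accepted - cand)) >= min_spacing) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf(paste0("cannot place %d origins on chromosome '%s' ",
                          "(%g bp) at minimum spacing %d bp"),
                   n, chrom, size, min_spacing), call. = FALSE)
    }
    accepted <- sort(c(accepted, cand))
    placed <- c(placed, cand)
  }
  placed
}

#' Plant replication origins on a synthetic genome
#'
#' Draws origin positions under the constraints of a [genome_spec()]:
#' in-bounds, at least `min_spacing` apart on each chromosome, and with a
#' stated fraction placed within `tss_window` of a TSS (each origin is
#' TSS-biased independently with probability `origin_tss_bias`, so the
#' realised fraction is binomial). With a fixed seed the output is
#' reproducible bit for bit.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed.
#'
#' @return Data frame with columns `origin_id`, `chrom`, `pos` (0-based bp),
#'   `efficiency`, `near_tss`, sorted by chromosome and position.
#' @export
simulate_origins <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  empty <- data.frame(origin_id = integer(), chrom = character(),
                      pos = integer(), efficiency = numeric(),
                      near_tss = logical(), stringsAsFactors = FALSE)
  if (spec$n_origins == 0L) return(empty)
  sizes <- spec$chrom_sizes
  withr::with_seed(seed, {
    n <- spec$n_origins
    biased <- stats::rbinom(n, 1L, spec$origin_tss_bias) == 1L
    chrom <- character(n)
    pos <- rep(NA_real_, n)
    ## TSS-anchored origins first: a TSS plus a uniform offset in the window
    if (any(biased)) {
      nb <- sum(biased)
      idx <- sample.int(nrow(spec$tss), nb, replace = TRUE)
      off <- sample(seq(-spec$tss_window, spec$tss_window), nb,
                    replace = TRUE)
      chrom[biased] <- spec$tss$chrom[idx]
      pos[biased] <- clamp(spec$tss$pos[idx] + off, 0,
                           sizes[chrom[biased]] - 1)
    }
    chrom[!biased] <- sample(names(sizes), sum(!biased), replace = TRUE,
                             prob = sizes)
    ## enforce spacing chromosome by chromosome; biased positions are kept
    ## (re-drawn near a random TSS on the same chromosome on collision)
    for (cm in unique(chrom)) {
      here <- which(chrom == cm)
      b_here <- here[biased[here]]
      accepted <- numeric(0)
      for (i in b_here) {
        ok <- length(accepted) == 0L ||
          min(abs(accepted - pos[i])) >= spec$min_spacing
        tries <- 0L
        while (!ok && tries < 1000L) {
          tss_cm <- spec$tss[spec$tss$chrom == cm, , drop = FALSE]
          j <- sample.int(nrow(tss_cm), 1L)
          cand <- clamp(tss_cm$pos[j] +
                          sample(seq(-spec$tss_window, spec$tss_window), 1L),
                        0, sizes[[cm]] - 1)
          if (length(accepted) == 0L ||
              min(abs(accepted - cand)) >= spec$min_spacing) {
            pos[i] <- cand
            ok <- TRUE
          }
          tries <- tries + 1L
        }
        if (!ok) {
          stop(sprintf(paste0("cannot place %d origins on chromosome '%s' ",
                              "at minimum spacing %d bp"),
                       length(here), cm, spec$min_spacing), call. = FALSE)
        }
        accepted <- c(accepted, pos[i])
      }
      u_here <- here[!biased[here]]
      if (length(u_here)) {
        pos[u_here] <- place_on_chrom(cm, sizes[[cm]], length(u_here),
                                      spec$min_spacing, existing = accepted)
      }
    }
    eff <- if (length(spec$efficiency) == 1L) {
      rep(spec$efficiency, n)
    } else {
      stats::runif(n, spec$efficiency[1], spec$efficiency[2])
    }
    out <- data.frame(chrom = chrom, pos = as.integer(pos), efficiency = eff,
                      near_tss = biased, stringsAsFactors = FALSE)
    out <- out[order(factor(out$chrom, levels = names(sizes)),
                     out$pos), , drop = FALSE]
    out <- cbind(origin_id = seq_len(n), out)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a BrIP-seq experiment
#'
#' Generates the sample library (origin-centred nascent-strand reads plus a
#' uniform background) and the matched genomic-control library (uniform over
#' the genome, no size selection). Each origin contributes a Poisson number
#' of reads with mean `reads_per_origin * efficiency`; each read comes from
#' a fragment of uniform length in `nascent_len_range` centred on the
#' origin, with the read 5' start uniform within the fragment.
#'
#' @param origins Data frame from [simulate_origins()].
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param spec A [brip_sim_spec()].
#' @param seed Integer seed.
#'
#' @return List with elements `sample` and `control`, each a reads data
#'   frame (`chrom`, `start`, `end`, `name`, `score`, `strand`, `origin`)
#'   sorted by chromosome and start; 0-based half-open coordinates.
#' @export
simulate_bripseq <- function(origins, chrom_sizes, spec = brip_sim_spec(),
                             seed = 1L) {
  stopifnot(inherits(spec, "brip_sim_spec"))
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  if (any(chrom_sizes < spec$read_len)) {
    stop("every chromosome must be at least one read long", call. = FALSE)
  }
  if (nrow(origins) &&
      (!all(origins$chrom %in% names(chrom_sizes)) ||
       any(origins$pos < 0 | origins$pos >= chrom_sizes[origins$chrom]))) {
    stop("origins must lie within the supplied chromosome bounds",
         call. = FALSE)
  }
  rl <- spec$read_len
  withr::with_seed(seed, {
    ## origin-centred nascent-strand reads
    if (nrow(origins)) {
      lam <- spec$reads_per_origin * origins$efficiency
      n_i <- stats::rpois(nrow(origins), lam)
      idx <- rep.int(seq_len(nrow(origins)), n_i)
    } else {
      idx <- integer(0)
    }
    if (length(idx)) {
      frag_len <- stats::runif(length(idx), spec$nascent_len_range[1],
                               spec$nascent_len_range[2])
      frag_start <- origins$pos[idx] - frag_len / 2
      start <- floor(frag_start + stats::runif(length(idx)) *
                       (frag_len - rl + 1))
      sz <- chrom_sizes[origins$chrom[idx]]
      start <- clamp(start, 0, sz - rl)
      sig <- new_reads(origins$chrom[idx], start, start + rl,
                       sample(c("+", "-"), length(idx), replace = TRUE),
                       origin = origins$origin_id[idx])
    } else {
      sig <- new_reads(character(), integer(), integer(), character())
    }
    ## uniform background in the sample library
    bg <- uniform_reads(chrom_sizes, spec$background_rate, rl,
                        prefix = "bg")
    smp <- sort_reads(rbind(sig, bg), names(chrom_sizes))
    if (nrow(smp)) smp$name <- sprintf("samp_%06d", seq_len(nrow(smp)))
    ## genomic control: uniform; depth either stated or matched to sample
    if (is.null(spec$control_rate)) {
      ctl <- uniform_reads_n(chrom_sizes, nrow(smp), rl, prefix = "ctl")
    } else {
      ctl <- uniform_reads(chrom_sizes, spec$control_rate, rl,
                           prefix = "ctl")
    }
    ctl <- sort_reads(ctl, names(chrom_sizes))
    if (nrow(ctl)) ctl$name <- sprintf("ctl_%06d", seq_len(nrow(ctl)))
    list(sample = smp, control = ctl)
  })
}

## Poisson(rate_per_kb * chrom_kb) uniform reads per chromosome
uniform_reads <- function(chrom_sizes, rate_per_kb, read_len, prefix) {
  n_c <- stats::rpois(length(chrom_sizes), rate_per_kb * chrom_sizes / 1000)
  uniform_reads_counts(chrom_sizes, n_c, read_len, prefix)
}

## exactly n uniform reads, allocated to chromosomes by length
uniform_reads_n <- function(chrom_sizes, n, read_len, prefix) {
  n_c <- if (n > 0) {
    as.vector(stats::rmultinom(1, n, prob = chrom_sizes))
  } else {
    integer(length(chrom_sizes))
  }
  uniform_reads_counts(chrom_sizes, n_c, read_len, prefix)
}

uniform_reads_counts <- function(chrom_sizes, n_c, read_len, prefix) {
  chrom <- rep(names(chrom_sizes), n_c)
  n <- length(chrom)
  if (n == 0L) {
    return(new_reads(character(), integer(), integer(), character(),
                     prefix = prefix))
  }
  start <- floor(stats::runif(n) * (chrom_sizes[chrom] - read_len + 1))
  new_reads(chrom, start, start + read_len,
            sample(c("+", "-"), n, replace = TRUE), prefix = prefix)
}

#' Build FASTQ records for simulated reads
#'
#' Draws a random base sequence for each aligned read (the simulator does
#' not use a reference sequence, so base identity is arbitrary) at constant
#' Sanger quality. With `no_trailing_t = TRUE` the final base is drawn from
#' A/C/G so that a subsequently appended poly-T tail remains exactly
#' identifiable by the trimmer.
#'
#' @param reads Reads data frame (`chrom`, `start`, `end`, `name`).
#' @param seed Integer seed.
#' @param no_trailing_t Force the last template base to not be T.
#' @param quality_char Single quality character applied to every base.
#'
#' @return Data frame with columns `id`, `sequence`, `quality`.
#' @export
fastq_from_reads <- function(reads, seed = 1L, no_trailing_t = FALSE,
                             quality_char = "I") {
  lens <- reads$end - reads$start
  withr::with_seed(seed, {
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    if (no_trailing_t && length(seqs)) {
      last <- sample(c("A", "C", "G"), length(seqs), replace = TRUE)
      seqs <- paste0(substr(seqs, 1L, pmax(lens - 1L, 0L)),
                     ifelse(lens > 0L, last, ""))
    }
    data.frame(id = as.character(reads$name), sequence = seqs,
               quality = strrep(quality_char, lens),
               stringsAsFactors = FALSE)
  })
}

#' Append 3' poly-T tails to FASTQ records
#'
#' Emulates the template-derived T-runs at the 3' end of nascent-strand
#' reads that the trimming stage removes. Tail lengths are drawn uniformly
#' from the inclusive integer range; qualities are extended in lockstep.
#'
#' @param records FASTQ data frame (`id`, `sequence`, `quality`).
#' @param polyT_tail_len_range Length-2 non-negative integer range.
#' @param seed Integer seed.
#' @param quality_char Quality character used for appended tail bases.
#'
#' @return The records with tails appended, plus a `tail_len` column.
#' @export
emit_fastq <- function(records, polyT_tail_len_range = c(0, 15), seed = 1L,
                       quality_char = "I") {
  validate_fastq(records)
  r <- as.integer(polyT_tail_len_range)
  if (length(r) != 2L || any(is.na(r)) || any(r < 0) || r[1] > r[2]) {
    stop("'polyT_tail_len_range' must be a non-negative length-2 range",
         call. = FALSE)
  }
  if (any(nchar(records$sequence) == 0L)) {
    stop("read sequences must be non-empty", call. = FALSE)
  }
  withr::with_seed(seed, {
    k <- r[1] + sample.int(r[2] - r[1] + 1L, nrow(records),
                           replace = TRUE) - 1L
    out <- records
    out$sequence <- paste0(records$sequence, strrep("T", k))
    out$quality <- paste0(records$quality, strrep(quality_char, k))
    out$tail_len <- k
    out
  })
}

#' Evaluate peak calls against planted origins
#'
#' @param peaks Origin-peak data frame (`chrom`, `start`, `end`).
#' @param origins Planted-origin data frame (`chrom`, `pos`).
#'
#' @return List with `recovery` (fraction of origins inside a peak),
#'   `precision` (fraction of peaks containing an origin), `n_peaks` and
#'   `n_origins`.
#' @export
peak_recovery <- function(peaks, origins) {
  if (nrow(peaks) == 0L || nrow(origins) == 0L) {
    return(list(recovery = 0, precision = 0, n_peaks = nrow(peaks),
                n_origins = nrow(origins)))
  }
  lv <- union(unique(peaks$chrom), unique(origins$chrom))
  grp <- as_granges(peaks, seqlevels = lv)
  gro <- as_granges(origins, width1 = TRUE, seqlevels = lv)
  list(recovery = mean(GenomicRanges::countOverlaps(gro, grp) > 0),
       precision = mean(GenomicRanges::countOverlaps(grp, gro) > 0),
       n_peaks = nrow(peaks), n_origins = nrow(origins))
}
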