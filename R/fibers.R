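#' Simulate dual-pulse molecular-combing fibers
#'
#' Each fiber carries origins spaced by draws from the inter-origin-distance
#' distribution. Every origin fires at the start of the first (CldU) pulse
#' and launches two forks whose rates are drawn independently; each fork
#' lays CldU label during pulse 1 and IdU label during pulse 2, so an
#' isolated origin appears as a central CldU track flanked by two IdU tracks
#' of length rate x pulse2. Converging forks from neighbouring origins
#' terminate where they meet, which merges their IdU tracks into a single
#' internal segment; tracks are clipped at the fiber ends and flagged as
#' truncated.
#'
#' @param spec A [combing_sim_spec()].
#' @param seed Integer seed.
#'
#' @return List with `fibers` (long-format segment table: `fiber_id`,
#'   `fiber_len_um`, `label`, `start_um`, `end_um`, `truncated`) and `truth`
#'   (list with per-origin positions, fork rates and spacings, and the
#'   generating spec).
#' @export
simulate_fibers <- function(spec = combing_sim_spec(), seed = 1L) {
  stopifnot(inherits(spec, "combing_sim_spec"))
  withr::with_seed(seed, {
    parts <- lapply(seq_len(spec$n_fibers), function(f) sim_fiber(f, spec))
    fibers <- do.call(rbind, lapply(parts, `[[`, "segments"))
    truth_origins <- do.call(rbind, lapply(parts, `[[`, "origins"))
    rownames(fibers) <- rownames(truth_origins) <- NULL
    list(fibers = fibers,
         truth = list(origins = truth_origins, spec = spec))
  })
}

empty_segments <- function() {
  data.frame(fiber_id = integer(), fiber_len_um = numeric(),
             label = character(), start_um = numeric(), end_um = numeric(),
             truncated = logical(), stringsAsFactors = FALSE)
}

sim_fiber <- function(fiber_id, spec) {
  k2u <- spec$kb_per_um
  p1 <- spec$pulse1_min
  p2 <- spec$pulse2_min
  L <- max(stats::rnorm(1, spec$fiber_len_um[["mean"]],
                        spec$fiber_len_um[["sd"]]), 20)
  iod_mean_um <- spec$iod_kb[["mean"]] / k2u
  ## origin centres along the fiber
  pos <- numeric(0)
  spacing_kb <- numeric(0)
  p <- stats::runif(1, 0, iod_mean_um)
  while (p <= L) {
    pos <- c(pos, p)
    d <- max(stats::rnorm(1, spec$iod_kb[["mean"]], spec$iod_kb[["sd"]]), 2)
    spacing_kb <- c(spacing_kb, d)
    p <- p + d / k2u
  }
  n <- length(pos)
  empty_truth <- data.frame(
    fiber_id = integer(), origin_id = integer(), pos_um = numeric(),
    rate_left_kb_min = numeric(), rate_right_kb_min = numeric(),
    spacing_to_next_kb = numeric(), stringsAsFactors = FALSE)
  if (n == 0L) return(list(segments = empty_segments(),
                           origins = empty_truth))
  rl <- pmax(stats::rnorm(n, spec$fork_rate_kb_min[["mean"]],
                          spec$fork_rate_kb_min[["sd"]]), 0.05)
  rr <- pmax(stats::rnorm(n, spec$fork_rate_kb_min[["mean"]],
                          spec$fork_rate_kb_min[["sd"]]), 0.05)
  ## converging forks stop when they meet
  t_total <- p1 + p2
  tstop_l <- rep(t_total, n)
  tstop_r <- rep(t_total, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      d_kb <- (pos[i + 1L] - pos[i]) * k2u
      tm <- d_kb / (rr[i] + rl[i + 1L])
      tstop_r[i] <- min(tstop_r[i], tm)
      tstop_l[i + 1L] <- min(tstop_l[i + 1L], tm)
    }
  }
  cld_l <- rl * pmin(tstop_l, p1) / k2u   # um
  cld_r <- rr * pmin(tstop_r, p1) / k2u
  idu_l <- rl * pmax(tstop_l - p1, 0) / k2u
  idu_r <- rr * pmax(tstop_r - p1, 0) / k2u
  seg <- data.frame(
    label = rep(c("IdU", "CldU", "IdU"), n),
    start_um = as.vector(rbind(pos - cld_l - idu_l, pos - cld_l,
                               pos + cld_r)),
    end_um = as.vector(rbind(pos - cld_l, pos + cld_r,
                             pos + cld_r + idu_r)),
    stringsAsFactors = FALSE)
  seg <- seg[seg$end_um - seg$start_um > 1e-9, , drop = FALSE]
  seg <- seg[order(seg$start_um), , drop = FALSE]
  ## merge abutting same-label segments (left+right CldU of one origin,
  ## IdU tracks of converged forks)
  if (nrow(seg) > 1L) {
    keep <- rep(TRUE, nrow(seg))
    for (k in 2:nrow(seg)) {
      prev <- max(which(keep[1:(k - 1L)]))
      if (seg$label[k] == seg$label[prev] &&
          seg$start_um[k] - seg$end_um[prev] < 1e-9) {
        seg$end_um[prev] <- max(seg$end_um[prev], seg$end_um[k])
        keep[k] <- FALSE
      }
    }
    seg <- seg[keep, , drop = FALSE]
  }
  ## clip at the fiber ends, flag what got cut
  truncated <- seg$start_um < -1e-9 | seg$end_um > L + 1e-9
  seg$start_um <- pmax(seg$start_um, 0)
  seg$end_um <- pmin(seg$end_um, L)
  ok <- seg$end_um - seg$start_um > 1e-9
  seg <- seg[ok, , drop = FALSE]
  truncated <- truncated[ok]
  segments <- data.frame(fiber_id = fiber_id, fiber_len_um = L,
                         label = seg$label, start_um = seg$start_um,
                         end_um = seg$end_um, truncated = truncated,
                         stringsAsFactors = FALSE)
  origins <- data.frame(
    fiber_id = fiber_id, origin_id = seq_len(n), pos_um = pos,
    rate_left_kb_min = rl, rate_right_kb_min = rr,
    spacing_to_next_kb = c(if (n > 1L) spacing_kb[seq_len(n - 1L)], NA_real_),
    stringsAsFactors = FALSE)
  list(segments = segments, origins = origins)
}

#' Write / read a fiber segment table
#'
#' Plain TSV with one labelled segment per row (`fiber_id`, `fiber_len_um`,
#' `label`, `start_um`, `end_um`, `truncated`).
#'
#' @param fibers Fiber segment data frame.
#' @param path File path.
#' @return `read_fibers` returns the segment data frame.
#' @export
write_fibers <- function(fibers, path) {
  write_tsv(fibers, path)
}

#' @rdname write_fibers
#' @export
read_fibers <- function(path) {
  df <- read_tsv(path)
  need <- c("fiber_id", "fiber_len_um", "label", "start_um", "end_um")
  if (!all(need %in% names(df))) {
    stop("fiber table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$truncated)) df$truncated <- FALSE
  df
}
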