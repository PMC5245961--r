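## per-fiber segment bookkeeping shared by the two estimators:
## for every segment, which neighbours are contiguous (gap <= max_gap_um)
## and whether the segment touches a fiber end
fiber_neighbours <- function(seg, cfg) {
  n <- nrow(seg)
  eps <- 1e-6
  gap_prev <- c(Inf, seg$start_um[-1] - seg$end_um[-n])
  gap_next <- c(seg$start_um[-1] - seg$end_um[-n], Inf)
  prev_lab <- c(NA_character_, seg$label[-n])
  next_lab <- c(seg$label[-1], NA_character_)
  prev_lab[gap_prev > cfg$max_gap_um] <- NA_character_
  next_lab[gap_next > cfg$max_gap_um] <- NA_character_
  touches <- seg$start_um <= eps | seg$end_um >= seg$fiber_len_um - eps
  if (!is.null(seg$truncated)) touches <- touches | seg$truncated
  data.frame(prev_lab = prev_lab, next_lab = next_lab, touches_end = touches,
             stringsAsFactors = FALSE)
}

#' Fork progression rates from labelled fibers
#'
#' With the default CldU-based convention, every complete origin pattern
#' (a CldU segment flanked by IdU on both sides, away from the fiber ends)
#' measures the mean rate of its two forks:
#' rate = CldU length x `kb_per_um` / (2 x `pulse1_min`). With the
#' IdU-based convention, every IdU segment contiguous with exactly one CldU
#' segment measures one fork: rate = IdU length x `kb_per_um` /
#' `pulse2_min`; segments touching a fiber end are censored (their true
#' length is unknown) and, by default, segments flanked by CldU on both
#' sides are excluded as converged-fork pairs whose length reflects origin
#' spacing rather than speed. See [combing_config()] for why the CldU
#' convention is the default.
#'
#' @param fibers Fiber segment data frame (see [simulate_fibers()] /
#'   [read_fibers()]).
#' @param cfg A [combing_config()].
#'
#' @return Data frame with one measured fork per row: `fiber_id`,
#'   `rate_kb_min`.
#' @export
fork_rates <- function(fibers, cfg = combing_config()) {
  stopifnot(inherits(cfg, "combing_config"))
  out <- lapply(split(fibers, fibers$fiber_id), function(seg) {
    seg <- seg[order(seg$start_um), , drop = FALSE]
    nb <- fiber_neighbours(seg, cfg)
    if (cfg$measure == "IdU") {
      is_target <- seg$label == "IdU"
      n_cldu <- (!is.na(nb$prev_lab) & nb$prev_lab == "CldU") +
        (!is.na(nb$next_lab) & nb$next_lab == "CldU")
      ok <- is_target & !nb$touches_end & n_cldu >= 1L
      if (cfg$exclude_converged) ok <- ok & n_cldu == 1L
      rate <- (seg$end_um - seg$start_um) * cfg$kb_per_um / cfg$pulse2_min
    } else {
      n_idu <- (!is.na(nb$prev_lab) & nb$prev_lab == "IdU") +
        (!is.na(nb$next_lab) & nb$next_lab == "IdU")
      ok <- seg$label == "CldU" & !nb$touches_end & n_idu == 2L
      rate <- (seg$end_um - seg$start_um) * cfg$kb_per_um /
        (2 * cfg$pulse1_min)
    }
    data.frame(fiber_id = seg$fiber_id[ok], rate_kb_min = rate[ok],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out) %||%
    data.frame(fiber_id = integer(), rate_kb_min = numeric())
  rownames(out) <- NULL
  out
}

#' Single-molecule inter-origin distances from labelled fibers
#'
#' An origin event is a CldU segment flanked by IdU on both sides
#' (bidirectional firing during the first pulse); its centre is the CldU
#' segment midpoint. Distances are successive centre differences converted
#' to kb; fibers with fewer than two events contribute none.
#'
#' @param fibers Fiber segment data frame.
#' @param cfg A [combing_config()].
#'
#' @return Data frame with columns `fiber_id`, `iod_kb`.
#' @export
fiber_iods <- function(fibers, cfg = combing_config()) {
  stopifnot(inherits(cfg, "combing_config"))
  out <- lapply(split(fibers, fibers$fiber_id), function(seg) {
    seg <- seg[order(seg$start_um), , drop = FALSE]
    nb <- fiber_neighbours(seg, cfg)
    is_origin <- seg$label == "CldU" &
      !is.na(nb$prev_lab) & nb$prev_lab == "IdU" &
      !is.na(nb$next_lab) & nb$next_lab == "IdU"
    centers <- (seg$start_um[is_origin] + seg$end_um[is_origin]) / 2
    if (length(centers) < 2L) {
      return(data.frame(fiber_id = integer(), iod_kb = numeric()))
    }
    data.frame(fiber_id = seg$fiber_id[1],
               iod_kb = diff(sort(centers)) * cfg$kb_per_um,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out) %||%
    data.frame(fiber_id = integer(), iod_kb = numeric())
  rownames(out) <- NULL
  out
}

#' Compare two combing conditions
#'
#' Computes fork rates and inter-origin distances for both fiber sets and
#' reports, per metric and condition, the number of measured tracks and the
#' box-whisker summary, plus a two-sided Wilcoxon rank-sum p-value per
#' metric. N is the number of measurements entering each comparison, not
#' the number of fibers.
#'
#' @param fibers_a,fibers_b Fiber segment data frames.
#' @param cfg A [combing_config()].
#' @param labels Length-2 condition labels.
#'
#' @return List with `summary` (one row per metric x condition) and
#'   `p_values` (named: `fork_rate`, `iod`).
#' @export
combing_report <- function(fibers_a, fibers_b, cfg = combing_config(),
                           labels = c("A", "B")) {
  rates <- list(fork_rates(fibers_a, cfg)$rate_kb_min,
                fork_rates(fibers_b, cfg)$rate_kb_min)
  iods <- list(fiber_iods(fibers_a, cfg)$iod_kb,
               fiber_iods(fibers_b, cfg)$iod_kb)
  for (i in 1:2) {
    if (length(rates[[i]]) == 0L) {
      stop(sprintf("no fork-rate measurements in condition '%s'",
                   labels[i]), call. = FALSE)
    }
    if (length(iods[[i]]) == 0L) {
      stop(sprintf("no inter-origin distances in condition '%s'",
                   labels[i]), call. = FALSE)
    }
  }
  row <- function(metric, label, x) {
    cbind(data.frame(metric = metric, condition = label),
          distance_summary(x))
  }
  summary <- rbind(
    row("fork_rate_kb_min", labels[1], rates[[1]]),
    row("fork_rate_kb_min", labels[2], rates[[2]]),
    row("iod_kb", labels[1], iods[[1]]),
    row("iod_kb", labels[2], iods[[2]]))
  p_values <- c(
    fork_rate = wilcoxon_rank_sum(rates[[1]], rates[[2]])$p.value,
    iod = wilcoxon_rank_sum(iods[[1]], iods[[2]])$p.value)
  list(summary = summary, p_values = p_values)
}

#' Box-and-whiskers plot of a combing comparison
#'
#' Convenience ggplot of the per-condition fork-rate and inter-origin
#' distance distributions. Requires the ggplot2 package.
#'
#' @param fibers_a,fibers_b Fiber segment data frames.
#' @param cfg A [combing_config()].
#' @param labels Length-2 condition labels.
#' @return A ggplot object.
#' @export
combing_boxplot <- function(fibers_a, fibers_b, cfg = combing_config(),
                            labels = c("A", "B")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("combing_boxplot requires the 'ggplot2' package", call. = FALSE)
  }
  df <- rbind(
    data.frame(metric = "fork rate (kb/min)", condition = labels[1],
               value = fork_rates(fibers_a, cfg)$rate_kb_min),
    data.frame(metric = "fork rate (kb/min)", condition = labels[2],
               value = fork_rates(fibers_b, cfg)$rate_kb_min),
    data.frame(metric = "inter-origin distance (kb)", condition = labels[1],
               value = fiber_iods(fibers_a, cfg)$iod_kb),
    data.frame(metric = "inter-origin distance (kb)", condition = labels[2],
               value = fiber_iods(fibers_b, cfg)$iod_kb))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
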