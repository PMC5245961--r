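#' Synthetic genome specification
#'
#' Describes the toy genome on which origins are planted: chromosome sizes,
#' the number of origins, optional TSS annotation and the fraction of origins
#' drawn close to a TSS (origins cluster near transcription start sites in
#' gene-rich domains, and the generator can emulate that bias).
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param n_origins Number of origins to plant across the genome.
#' @param tss Optional data frame with columns `chrom`, `pos` (0-based bp)
#'   and `strand`; required when `origin_tss_bias > 0`.
#' @param origin_tss_bias Fraction of origins placed within `tss_window` of a
#'   TSS. Each origin is biased independently with this probability.
#' @param tss_window Half-width in bp of the window around a TSS used for
#'   biased placement.
#' @param min_spacing Minimum distance in bp between two planted origins on
#'   the same chromosome. The default keeps origins resolvable on a 1 kb
#'   window grid.
#' @param efficiency Per-origin firing efficiency; either a single value in
#'   (0, 1] applied to all origins or a length-2 range to draw uniformly.
#'
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_sizes, n_origins, tss = NULL,
                        origin_tss_bias = 0, tss_window = 1000,
                        min_spacing = 5000, efficiency = 1) {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  check_num(n_origins, "n_origins", lower = 0)
  check_num(origin_tss_bias, "origin_tss_bias", lower = 0, upper = 1)
  check_num(tss_window, "tss_window", lower = 1)
  check_num(min_spacing, "min_spacing", lower = 0)
  if (origin_tss_bias > 0 && (is.null(tss) || nrow(tss) == 0L)) {
    stop("'tss' must be provided when 'origin_tss_bias' > 0", call. = FALSE)
  }
  if (!length(efficiency) %in% c(1L, 2L) || any(efficiency <= 0) ||
      any(efficiency > 1)) {
    stop("'efficiency' must be one value or a range within (0, 1]",
         call. = FALSE)
  }
  structure(
    list(chrom_sizes = chrom_sizes, n_origins = as.integer(n_origins),
         tss = tss, origin_tss_bias = origin_tss_bias,
         tss_window = as.integer(tss_window),
         min_spacing = as.integer(min_spacing), efficiency = efficiency),
    class = "genome_spec"
  )
}

#' BrIP-seq simulation specification
#'
#' Parameters of the synthetic nascent-strand sequencing experiment. Nascent
#' strands are 0.5-3.0 kb fragments centred on origins (emulating the sucrose
#' gradient size selection of the assay), sequenced as single-end 75 bp
#' reads, over a uniform genomic background. The control library is uniform
#' over the genome because no size selection is applied to it.
#'
#' @param nascent_len_range Length-2 vector, nascent-fragment length range in
#'   bp (low < high).
#' @param read_len Read length in bp.
#' @param reads_per_origin Mean number of reads per planted origin at
#'   efficiency 1 (Poisson-distributed per origin, scaled by the origin's
#'   firing efficiency).
#' @param background_rate Uniform background read density in the sample
#'   library, reads per kb of genome.
#' @param control_rate Read density of the genomic control in reads per kb,
#'   or `NULL` to match the control library size to the sample library size
#'   (equal sequencing depth).
#' @param polyT_tail_len_range Length-2 integer range of 3' poly-T tail
#'   lengths appended in FASTQ mode.
#'
#' @return An object of class `brip_sim_spec`.
#' @export
brip_sim_spec <- function(nascent_len_range = c(500, 3000), read_len = 75,
                          reads_per_origin = 30, background_rate = 0.5,
                          control_rate = NULL,
                          polyT_tail_len_range = c(0, 15)) {
  if (length(nascent_len_range) != 2L ||
      nascent_len_range[1] >= nascent_len_range[2]) {
    stop("'nascent_len_range' must be an increasing length-2 range",
         call. = FALSE)
  }
  check_num(read_len, "read_len", lower = 1)
  if (read_len > nascent_len_range[1]) {
    stop("'read_len' must not exceed the minimum nascent-strand length",
         call. = FALSE)
  }
  check_num(reads_per_origin, "reads_per_origin", lower = 0)
  check_num(background_rate, "background_rate", lower = 0)
  if (!is.null(control_rate)) check_num(control_rate, "control_rate",
                                        lower = 0)
  if (length(polyT_tail_len_range) != 2L || any(polyT_tail_len_range < 0) ||
      polyT_tail_len_range[1] > polyT_tail_len_range[2]) {
    stop("'polyT_tail_len_range' must be a non-negative length-2 range",
         call. = FALSE)
  }
  structure(
    list(nascent_len_range = as.numeric(nascent_len_range),
         read_len = as.integer(read_len),
         reads_per_origin = reads_per_origin,
         background_rate = background_rate, control_rate = control_rate,
         polyT_tail_len_range = as.integer(polyT_tail_len_range)),
    class = "brip_sim_spec"
  )
}

#' Molecular-combing simulation specification
#'
#' Parameters of the synthetic dual-pulse combing experiment: fibers of
#' normally distributed length carry origins spaced by draws from the
#' inter-origin-distance distribution; every origin fires at the start of the
#' first pulse and sends out two forks whose rates are drawn per fork.
#' Converging forks from neighbouring origins terminate where they meet.
#'
#' @param n_fibers Number of fibers to simulate.
#' @param fiber_len_um Named vector `c(mean=, sd=)`, fiber length in um.
#' @param fork_rate_kb_min Named vector `c(mean=, sd=)`, per-fork rate in
#'   kb/min.
#' @param iod_kb Named vector `c(mean=, sd=)`, inter-origin distance in kb.
#' @param pulse1_min,pulse2_min Durations of the CldU and IdU pulses in
#'   minutes.
#' @param kb_per_um Stretching constant converting um of combed fiber to kb
#'   of DNA. The conventional constant for silanised-coverslip combing is
#'   2 kb/um.
#'
#' @return An object of class `combing_sim_spec`.
#' @export
combing_sim_spec <- function(n_fibers = 500,
                             fiber_len_um = c(mean = 150, sd = 30),
                             fork_rate_kb_min = c(mean = 1.2, sd = 0.2),
                             iod_kb = c(mean = 96, sd = 10),
                             pulse1_min = 30, pulse2_min = 30,
                             kb_per_um = 2) {
  check_num(n_fibers, "n_fibers", lower = 1)
  for (nm in c("fiber_len_um", "fork_rate_kb_min", "iod_kb")) {
    v <- get(nm)
    if (length(v) != 2L || is.null(names(v)) ||
        !all(c("mean", "sd") %in% names(v))) {
      stop(sprintf("'%s' must be a named c(mean=, sd=) vector", nm),
           call. = FALSE)
    }
    if (v[["mean"]] <= 0 || v[["sd"]] < 0) {
      stop(sprintf("'%s' must have positive mean and non-negative sd", nm),
           call. = FALSE)
    }
  }
  check_num(pulse1_min, "pulse1_min", lower = 1e-9)
  check_num(pulse2_min, "pulse2_min", lower = 1e-9)
  check_num(kb_per_um, "kb_per_um", lower = 1e-9)
  structure(
    list(n_fibers = as.integer(n_fibers), fiber_len_um = fiber_len_um,
         fork_rate_kb_min = fork_rate_kb_min, iod_kb = iod_kb,
         pulse1_min = pulse1_min, pulse2_min = pulse2_min,
         kb_per_um = kb_per_um),
    class = "combing_sim_spec"
  )
}

#' Peak-calling configuration
#'
#' Tuning parameters of the fixed-window origin caller. Windows with at
#' least `fold` times the (optionally library-scaled) control count form the
#' enriched set; the mean and SD of the sample counts over that set define
#' the significance threshold mean + `sd_mult` * SD (the comparison is
#' inclusive, `>=`).
#'
#' @param window_size Window size in bp.
#' @param fold Minimum sample/control fold ratio for the enrichment filter.
#' @param sd_mult SD multiplier of the significance threshold.
#' @param library_scale Scale control counts by the sample/control library
#'   size ratio before the fold comparison.
#' @param control_pseudocount Pseudocount applied to windows whose raw
#'   control count is zero, so the fold filter is defined everywhere.
#' @param threshold_domain Which windows are eligible to become peaks:
#'   `"enriched_only"` (a peak must pass both the fold filter and the
#'   threshold) or `"all_windows"` (the threshold alone decides, its mean
#'   and SD still computed over the enriched set).
#' @param sd_type `"population"` (divide by n) or `"sample"` (divide by
#'   n - 1) standard deviation.
#' @param merge Merge adjacent significant windows into a single origin
#'   peak. Disable for sensitivity analyses on unmerged windows.
#'
#' @return An object of class `peak_call_config`.
#' @export
peak_call_config <- function(window_size = 1000, fold = 2, sd_mult = 3,
                             library_scale = TRUE, control_pseudocount = 1,
                             threshold_domain = c("enriched_only",
                                                  "all_windows"),
                             sd_type = c("population", "sample"),
                             merge = TRUE) {
  check_num(window_size, "window_size", lower = 1)
  check_num(fold, "fold", lower = 1)
  check_num(sd_mult, "sd_mult", lower = 0)
  check_num(control_pseudocount, "control_pseudocount", lower = 0)
  structure(
    list(window_size = as.integer(window_size), fold = fold,
         sd_mult = sd_mult, library_scale = isTRUE(library_scale),
         control_pseudocount = control_pseudocount,
         threshold_domain = match.arg(threshold_domain),
         sd_type = match.arg(sd_type), merge = isTRUE(merge)),
    class = "peak_call_config"
  )
}

#' Combing measurement configuration
#'
#' Conventions used when measuring fork rates and inter-origin distances on
#' labelled fibers.
#'
#' @param pulse1_min,pulse2_min Pulse durations in minutes (CldU then IdU).
#' @param kb_per_um Stretching constant, kb of DNA per um of fiber.
#' @param max_gap_um Maximum gap in um across which two segments are still
#'   considered contiguous (joins tracks split by staining gaps).
#' @param measure Label used for the fork-rate estimate. The default
#'   `"CldU"` measures the first-pulse bidirectional track length /
#'   (2 * pulse1) on complete origin patterns (CldU flanked by IdU on both
#'   sides); because converging forks of neighbouring origins typically
#'   meet only after the label switch, these tracks are rarely shortened
#'   and the estimate is nearly free of censoring bias. `"IdU"` measures
#'   second-pulse track length / pulse2 on single forks; at realistic
#'   origin densities many full-length IdU tracks are destroyed by fork
#'   convergence or fiber ends, which preferentially censors fast forks
#'   and biases the IdU-based median downward.
#' @param exclude_converged Exclude IdU segments flanked by CldU on both
#'   sides from the rate estimate. Such segments arise when forks from
#'   neighbouring origins converge and terminate between the origins, so
#'   their length reflects origin spacing, not fork speed.
#'
#' @return An object of class `combing_config`.
#' @export
combing_config <- function(pulse1_min = 30, pulse2_min = 30, kb_per_um = 2,
                           max_gap_um = 1, measure = c("CldU", "IdU"),
                           exclude_converged = TRUE) {
  check_num(pulse1_min, "pulse1_min", lower = 1e-9)
  check_num(pulse2_min, "pulse2_min", lower = 1e-9)
  check_num(kb_per_um, "kb_per_um", lower = 1e-9)
  check_num(max_gap_um, "max_gap_um", lower = 0)
  structure(
    list(pulse1_min = pulse1_min, pulse2_min = pulse2_min,
         kb_per_um = kb_per_um, max_gap_um = max_gap_um,
         measure = match.arg(measure),
         exclude_converged = isTRUE(exclude_converged)),
    class = "combing_config"
  )
}
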