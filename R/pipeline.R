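#' Default pipeline configuration
#'
#' The demo configuration simulates a wild-type-like and a knockout-like
#' condition on a 10 Mb two-chromosome toy genome, with the knockout
#' sharing a fraction of the wild-type origin set (emulating partial
#' origin-usage overlap between conditions), calls peaks per condition
#' against a matched genomic control, and runs the full downstream report
#' set.
#'
#' @return Nested named list of defaults, amendable via [validate_config()].
#' @export
oriseq_defaults <- function() {
  list(
    seed = 1L,
    genome = list(
      chrom_sizes = c(chr1 = 6e6, chr2 = 4e6),
      n_tss = 500, origin_tss_bias = 0.3, tss_window = 1000,
      min_spacing = 5000),
    conditions = list(
      wt = list(n_origins = 400, reads_per_origin = 30,
                fork_rate = c(mean = 1.2, sd = 0.2),
                iod_kb = c(mean = 96, sd = 10)),
      ko = list(n_origins = 260, reads_per_origin = 30,
                shared_with_wt = 0.4,
                fork_rate = c(mean = 1.4, sd = 0.2),
                iod_kb = c(mean = 115.5, sd = 12))),
    bripseq = list(
      nascent_len_range = c(500, 3000), read_len = 75,
      background_rate = 0.5, control_rate = NULL,
      polyT_tail_len_range = c(0, 15)),
    trim = list(min_len_after = 20, n_demo_reads = 2000),
    peaks = list(
      window_size = 1000, fold = 2, sd_mult = 3, library_scale = TRUE,
      control_pseudocount = 1, threshold_domain = "enriched_only",
      sd_type = "population", merge = TRUE),
    combing = list(
      n_fibers = 300, fiber_len_um = c(mean = 150, sd = 30),
      pulse1_min = 30, pulse2_min = 30, kb_per_um = 2, max_gap_um = 1),
    quant = list(
      band_mass_ng = 2.54, molar_mass_kDa = 100, cells_loaded = 1e5,
      detection_fraction = 0.01, genome_bp = 6e9, median_iod_bp = 115500,
      n_unique_peaks = 13000, ploidy = 2, unique_mappable_fraction = 0.5,
      territory_bp = 3.5e6, spacing_bp = 1e5)
  )
}

## recursive merge of user settings over defaults; unknown keys collected
merge_config <- function(defaults, user, path = "", errors = NULL) {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      errors <- c(errors, sprintf("unknown configuration key '%s'", full))
      next
    }
    d <- defaults[[key]]
    u <- user[[key]]
    if (is.list(d) && !is.null(names(d)) && !key %in%
          c("chrom_sizes", "fork_rate", "iod_kb", "fiber_len_um")) {
      res <- merge_config(d, as.list(u), full, errors)
      defaults[[key]] <- res$config
      errors <- res$errors
    } else {
      if (key %in% c("chrom_sizes", "fork_rate", "iod_kb",
                     "fiber_len_um") && is.list(u)) {
        u <- unlist(u)
      }
      defaults[[key]] <- u
    }
  }
  list(config = defaults, errors = errors)
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML or JSON file path or a nested list, fills every
#' unspecified field from [oriseq_defaults()], rejects unknown keys and
#' checks value ranges. All problems found are reported together in a
#' single error.
#'
#' @param config File path (`.yaml`/`.yml`/`.json`) or nested list; `NULL`
#'   or an empty list yields the all-defaults configuration.
#'
#' @return The normalised configuration (class `oriseq_config`).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop(sprintf("configuration file '%s' does not exist", config),
           call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  config <- config %||% list()
  if (!is.list(config)) {
    stop("'config' must be a file path or a named list", call. = FALSE)
  }
  res <- merge_config(oriseq_defaults(), config)
  cfg <- res$config
  errors <- res$errors
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  sizes <- tryCatch(check_chrom_sizes(cfg$genome$chrom_sizes),
                    error = function(e) {
                      errors <<- c(errors, conditionMessage(e))
                      NULL
                    })
  if (!is.null(sizes)) cfg$genome$chrom_sizes <- sizes
  chk(cfg$peaks$window_size > 0, "peaks.window_size must be positive")
  chk(cfg$peaks$fold >= 1, "peaks.fold must be >= 1")
  chk(cfg$peaks$sd_mult >= 0, "peaks.sd_mult must be >= 0")
  chk(cfg$peaks$threshold_domain %in% c("enriched_only", "all_windows"),
      "peaks.threshold_domain must be 'enriched_only' or 'all_windows'")
  chk(cfg$peaks$sd_type %in% c("population", "sample"),
      "peaks.sd_type must be 'population' or 'sample'")
  chk(cfg$genome$origin_tss_bias >= 0 && cfg$genome$origin_tss_bias <= 1,
      "genome.origin_tss_bias must be in [0, 1]")
  chk(cfg$genome$min_spacing >= 0, "genome.min_spacing must be >= 0")
  chk(cfg$bripseq$background_rate >= 0,
      "bripseq.background_rate must be >= 0")
  chk(length(cfg$bripseq$nascent_len_range) == 2 &&
        cfg$bripseq$nascent_len_range[1] < cfg$bripseq$nascent_len_range[2],
      "bripseq.nascent_len_range must be an increasing length-2 range")
  chk(cfg$bripseq$read_len >= 1, "bripseq.read_len must be >= 1")
  chk(cfg$trim$min_len_after >= 0, "trim.min_len_after must be >= 0")
  chk(cfg$combing$pulse1_min > 0 && cfg$combing$pulse2_min > 0,
      "combing pulse durations must be positive")
  chk(cfg$combing$kb_per_um > 0, "combing.kb_per_um must be positive")
  chk(cfg$combing$n_fibers >= 1, "combing.n_fibers must be >= 1")
  chk(cfg$quant$detection_fraction > 0 &&
        cfg$quant$detection_fraction <= 1,
      "quant.detection_fraction must be in (0, 1]")
  chk(cfg$quant$unique_mappable_fraction > 0 &&
        cfg$quant$unique_mappable_fraction <= 1,
      "quant.unique_mappable_fraction must be in (0, 1]")
  for (cond in names(cfg$conditions)) {
    chk(cfg$conditions[[cond]]$n_origins >= 0,
        sprintf("conditions.%s.n_origins must be >= 0", cond))
    chk(cfg$conditions[[cond]]$reads_per_origin >= 0,
        sprintf("conditions.%s.reads_per_origin must be >= 0", cond))
  }
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && !is.na(cfg$seed),
      "seed must be a single integer")
  if (length(errors)) {
    stop(paste0("invalid configuration:\n  - ",
                paste(errors, collapse = "\n  - ")), call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "oriseq_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate, trim, peak calling (per condition), origin-landscape
#' statistics, combing and quantification in dependency order, writing
#' every output under `out_dir` and finishing with a JSON manifest that
#' records the configuration, seed, package version and an MD5 checksum of
#' every file. Re-running with the same configuration and seed reproduces
#' every output byte for byte; no timestamps are written.
#'
#' @param config A configuration accepted by [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Emit per-stage progress messages.
#'
#' @return Invisibly, a list with the key result objects (`peaks`,
#'   `stats`, `combing`, `quant`, `manifest_path`).
#' @export
run_pipeline <- function(config = NULL, out_dir, verbose = FALSE) {
  cfg <- if (inherits(config, "oriseq_config")) config else
    validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("genome", "reads", "trim", "peaks", "stats", "combing",
              "quant")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- cfg$seed
  sizes <- cfg$genome$chrom_sizes
  files <- character(0)
  put <- function(rel) {
    files <<- c(files, rel)
    file.path(out_dir, rel)
  }

  ## --- simulate: genome, TSS, origins shared between conditions ---------
  say("stage simulate")
  sim <- run_stage("simulate", {
    tss <- simulate_tss(sizes, cfg$genome$n_tss, seed = seed + 7L)
    n_wt <- cfg$conditions$wt$n_origins
    n_ko <- cfg$conditions$ko$n_origins
    shared <- round(cfg$conditions$ko$shared_with_wt * n_ko)
    n_cand <- n_wt + (n_ko - shared)
    cand_spec <- genome_spec(
      sizes, n_cand, tss = tss,
      origin_tss_bias = cfg$genome$origin_tss_bias,
      tss_window = cfg$genome$tss_window,
      min_spacing = cfg$genome$min_spacing)
    cand <- simulate_origins(cand_spec, seed = seed + 11L)
    pick <- withr::with_seed(seed + 13L, {
      wt_rows <- sort(sample.int(n_cand, n_wt))
      shared_rows <- sort(sample(wt_rows, shared))
      list(wt = wt_rows,
           ko = sort(c(shared_rows, setdiff(seq_len(n_cand), wt_rows))))
    })
    wt <- cand[pick$wt, , drop = FALSE]
    ko <- cand[pick$ko, , drop = FALSE]
    wt$origin_id <- seq_len(nrow(wt))
    ko$origin_id <- seq_len(nrow(ko))
    rownames(wt) <- rownames(ko) <- NULL
    write_chrom_sizes(sizes, put("genome/chrom.sizes"))
    write_tsv(tss, put("genome/tss.tsv"))
    write_tsv(wt, put("genome/origins_wt.tsv"))
    write_tsv(ko, put("genome/origins_ko.tsv"))
    list(tss = tss, origins = list(wt = wt, ko = ko))
  })

  ## --- simulate + write reads per condition ----------------------------
  brip <- run_stage("simulate", {
    spec <- do.call(brip_sim_spec, cfg$bripseq)
    out <- list()
    for (i in seq_along(sim$origins)) {
      cond <- names(sim$origins)[i]
      sp <- spec
      sp$reads_per_origin <- cfg$conditions[[cond]]$reads_per_origin
      rs <- simulate_bripseq(sim$origins[[cond]], sizes, sp,
                             seed = seed + 20L + i)
      write_reads_bed(rs$sample, put(sprintf("reads/%s_sample.bed", cond)))
      write_reads_bed(rs$control,
                      put(sprintf("reads/%s_control.bed", cond)))
      out[[cond]] <- rs
    }
    out
  })

  ## --- trim: FASTQ round trip on a slice of the WT sample ---------------
  say("stage trim")
  run_stage("trim", {
    n_demo <- min(cfg$trim$n_demo_reads, nrow(brip$wt$sample))
    demo_reads <- brip$wt$sample[seq_len(n_demo), , drop = FALSE]
    rec <- fastq_from_reads(demo_reads, seed = seed + 31L)
    tailed <- emit_fastq(rec, cfg$bripseq$polyT_tail_len_range,
                         seed = seed + 32L)
    write_fastq(tailed[c("id", "sequence", "quality")],
                put("trim/demo_tailed.fastq"))
    trimmed <- trim_polyt(tailed, min_len_after = cfg$trim$min_len_after)
    keep <- !trimmed$discarded
    write_fastq(trimmed[keep, c("id", "sequence", "quality")],
                put("trim/demo_trimmed.fastq"))
    write_tsv(data.frame(
      reads_in = nrow(trimmed), bases_trimmed = sum(trimmed$bases_trimmed),
      discarded = sum(trimmed$discarded)), put("trim/trim_report.tsv"))
  })

  ## --- peak calling per condition ---------------------------------------
  say("stage callpeaks")
  pk_cfg <- do.call(peak_call_config, cfg$peaks)
  peaks <- run_stage("callpeaks", {
    out <- list()
    for (cond in names(brip)) {
      s_wc <- count_windows(brip[[cond]]$sample, sizes,
                            cfg$peaks$window_size)
      c_wc <- count_windows(brip[[cond]]$control, sizes,
                            cfg$peaks$window_size)
      pk <- call_peaks(s_wc, c_wc, pk_cfg)
      write_peaks(pk, put(sprintf("peaks/%s_peaks.bed", cond)))
      rep <- peak_report(pk)
      write_tsv(data.frame(stat = names(rep),
                           value = vapply(rep, format, character(1))),
                put(sprintf("peaks/%s_report.tsv", cond)))
      out[[cond]] <- pk
    }
    out
  })

  ## --- origin-landscape statistics --------------------------------------
  say("stage stats")
  stats_out <- run_stage("stats", {
    iod <- lapply(peaks, inter_origin_distances)
    for (cond in names(iod)) {
      pc <- iod[[cond]]$per_chrom
      write_tsv(data.frame(
        chrom = rep(names(pc), lengths(pc)),
        distance_bp = unlist(pc, use.names = FALSE) %||% numeric(0)),
        put(sprintf("stats/%s_iod_per_chrom.tsv", cond)))
    }
    cmp <- if (length(iod$wt$distances) && length(iod$ko$distances)) {
      compare_conditions(iod$wt$distances, iod$ko$distances,
                         labels = c("wt", "ko"))
    } else {
      NULL
    }
    if (!is.null(cmp)) {
      tab <- cmp$summary
      tab$wilcoxon_p <- cmp$test$p.value
      write_tsv(tab, put("stats/iod_compare.tsv"))
    }
    ov <- overlap_fraction(peaks$wt, peaks$ko)
    write_tsv(as.data.frame(ov), put("stats/overlap.tsv"))
    th <- tss_distance_distribution(peaks$wt, sim$tss)
    write_tsv(data.frame(bin = names(th$counts),
                         count = as.integer(th$counts)),
              put("stats/wt_tss_hist.tsv"))
    list(iod = iod, compare = cmp, overlap = ov, tss_hist = th)
  })

  ## --- combing -----------------------------------------------------------
  say("stage combing")
  combing_out <- run_stage("combing", {
    mk_spec <- function(cond) combing_sim_spec(
      n_fibers = cfg$combing$n_fibers,
      fiber_len_um = cfg$combing$fiber_len_um,
      fork_rate_kb_min = cfg$conditions[[cond]]$fork_rate,
      iod_kb = cfg$conditions[[cond]]$iod_kb,
      pulse1_min = cfg$combing$pulse1_min,
      pulse2_min = cfg$combing$pulse2_min,
      kb_per_um = cfg$combing$kb_per_um)
    fib <- list(wt = simulate_fibers(mk_spec("wt"), seed = seed + 41L),
                ko = simulate_fibers(mk_spec("ko"), seed = seed + 42L))
    for (cond in names(fib)) {
      write_fibers(fib[[cond]]$fibers,
                   put(sprintf("combing/%s_fibers.tsv", cond)))
    }
    ccfg <- combing_config(
      pulse1_min = cfg$combing$pulse1_min,
      pulse2_min = cfg$combing$pulse2_min,
      kb_per_um = cfg$combing$kb_per_um,
      max_gap_um = cfg$combing$max_gap_um)
    rep <- combing_report(fib$wt$fibers, fib$ko$fibers, ccfg,
                          labels = c("wt", "ko"))
    tab <- rep$summary
    tab$wilcoxon_p <- rep$p_values[
      ifelse(tab$metric == "fork_rate_kb_min", "fork_rate", "iod")]
    write_tsv(tab, put("combing/combing_report.tsv"))
    list(fibers = fib, report = rep)
  })

  ## --- quantification ----------------------------------------------------
  say("stage quant")
  quant_out <- run_stage("quant", {
    qr <- do.call(quant_report, cfg$quant)
    write_tsv(qr, put("quant/quant_report.tsv"))
    jsonlite::write_json(
      stats::setNames(as.list(qr$reported), qr$quantity),
      put("quant/quant_report.json"), auto_unbox = TRUE, digits = NA)
    qr
  })

  ## --- manifest -----------------------------------------------------------
  manifest <- list(
    package = "oriseq",
    version = as.character(utils::packageVersion("oriseq")),
    seed = seed,
    config = unclass(cfg),
    files = data.frame(
      path = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files))),
      stringsAsFactors = FALSE))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("pipeline complete: %d files", length(files) + 1L)
  invisible(list(peaks = peaks, stats = stats_out, combing = combing_out,
                 quant = quant_out, manifest_path = manifest_path))
}

#' Run the end-to-end demo pipeline
#'
#' Simulates a wild-type-like and a knockout-like dataset on a 10 Mb toy
#' genome and produces the full report set under `out_dir`. Two runs with
#' the same seed produce byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param config Optional overrides merged over [oriseq_defaults()].
#' @param verbose Emit progress messages.
#'
#' @return Invisibly, the [run_pipeline()] result list.
#' @export
oriseq_demo <- function(out_dir, seed = 1L, config = list(),
                        verbose = FALSE) {
  config$seed <- seed
  run_pipeline(config, out_dir, verbose = verbose)
}
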