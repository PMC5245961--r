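# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately re-derive results with naive loops so the
# vectorised implementations are checked against a second route.

# literal re-computation of the peak-calling steps: enrichment filter,
# mean/population-SD threshold over the enriched set, merge of adjacent
# significant windows
naive_call_peaks <- function(sample_counts, control_counts, window_size,
                             chrom_sizes, fold = 2, sd_mult = 3,
                             library_scale = TRUE, pseudocount = 1,
                             threshold_domain = "enriched_only") {
  tot_s <- sum(unlist(sample_counts))
  tot_c <- sum(unlist(control_counts))
  f <- if (library_scale) tot_s / tot_c else 1
  enriched <- list()
  vals <- numeric(0)
  for (cm in names(sample_counts)) {
    s <- sample_counts[[cm]]
    c0 <- control_counts[[cm]]
    e <- logical(length(s))
    for (i in seq_along(s)) {
      denom <- if (c0[i] == 0) pseudocount else c0[i] * f
      e[i] <- s[i] >= fold * denom
    }
    enriched[[cm]] <- e
    vals <- c(vals, s[e])
  }
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), sample_count = numeric())
  if (!length(vals)) return(empty)
  mu <- mean(vals)
  sig <- sqrt(sum((vals - mu)^2) / length(vals))
  thr <- mu + sd_mult * sig
  rows <- list()
  for (cm in names(sample_counts)) {
    s <- sample_counts[[cm]]
    elig <- if (threshold_domain == "enriched_only") {
      enriched[[cm]]
    } else {
      rep(TRUE, length(s))
    }
    sig_w <- which(elig & s >= thr)
    while (length(sig_w)) {
      k <- 1L
      while (k < length(sig_w) && sig_w[k + 1L] == sig_w[k] + 1L) {
        k <- k + 1L
      }
      g <- sig_w[seq_len(k)]
      sig_w <- sig_w[-seq_len(k)]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cm, start = (min(g) - 1L) * window_size,
        end = min(max(g) * window_size, chrom_sizes[[cm]]),
        sample_count = sum(s[g]))
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# exact two-sided rank-sum p by enumeration of all rank assignments
# (tie-free samples only)
enum_wilcoxon <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  us <- apply(sets, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(statistic = u_obs, p.value = p)
}

# random window grid (<= 1000 windows) with background + sprinkled spikes
random_grid <- function(seed) {
  withr::with_seed(seed, {
    n_chrom <- sample(1:3, 1)
    n_win <- sample(5:300, n_chrom)
    sizes <- stats::setNames(n_win * 1000, paste0("chr", seq_len(n_chrom)))
    lam_s <- sample(c(0.5, 2, 5), 1)
    lam_c <- sample(c(0.5, 2, 5), 1)
    s_counts <- lapply(n_win, function(n) {
      v <- stats::rpois(n, lam_s)
      spikes <- stats::rbinom(n, 1, 0.03) * stats::rpois(n, 40)
      v + spikes
    })
    c_counts <- lapply(n_win, function(n) stats::rpois(n, lam_c))
    names(s_counts) <- names(c_counts) <- names(sizes)
    if (sum(unlist(c_counts)) == 0) c_counts[[1]][1] <- 1L
    list(sizes = sizes,
         sample = window_counts(s_counts, 1000, sizes),
         control = window_counts(c_counts, 1000, sizes),
         s_counts = s_counts, c_counts = c_counts)
  })
}

expect_same_peaks <- function(pk, naive) {
  expect_equal(nrow(pk), nrow(naive))
  if (nrow(pk)) {
    expect_equal(pk$chrom, naive$chrom)
    expect_equal(pk$start, naive$start)
    expect_equal(pk$end, naive$end)
    expect_equal(pk$sample_count, naive$sample_count)
  }
}

# all-pairs nearest-TSS signed distance for one peak
brute_tss_signed <- function(mid, chrom, tss) {
  t_cm <- tss[tss$chrom == chrom, , drop = FALSE]
  if (nrow(t_cm) == 0L) return(NA_real_)
  t_cm <- t_cm[order(t_cm$pos), , drop = FALSE]
  d <- mid - t_cm$pos
  i <- which.min(abs(d))   # first minimum = lower-coordinate TSS on ties
  if (t_cm$strand[i] == "-") -d[i] else d[i]
}

make_fastq <- function(ids, seqs, quals = NULL) {
  data.frame(id = ids, sequence = seqs,
             quality = quals %||% strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
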