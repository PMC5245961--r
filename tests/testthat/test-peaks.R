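sizes1 <- c(chr1 = 10000)

test_that("window counting assigns reads by 5' position and conserves totals", {
  reads <- data.frame(
    chrom = "chr1",
    start = c(1500L, 2000L, 0L, 1500L),
    end = c(1575L, 2075L, 75L, 1575L),
    strand = c("+", "+", "+", "-"),
    stringsAsFactors = FALSE)
  wc <- count_windows(reads, sizes1, 1000)
  v <- wc$counts$chr1
  expect_length(v, 10L)          # ceil(10000 / 1000)
  expect_equal(v[2], 2)          # + read at 1500 and - read (5' end 1574)
  expect_equal(v[3], 1)          # half-open boundary: start 2000 -> window 3
  expect_equal(v[1], 1)
  expect_equal(wc$total_assigned, 4)

  # conservation on a larger random set
  rnd <- withr::with_seed(3, data.frame(
    chrom = "chr1", start = sample(0:9900, 100, TRUE),
    strand = sample(c("+", "-"), 100, TRUE), stringsAsFactors = FALSE))
  rnd$end <- rnd$start + 75L
  rnd$end <- pmin(rnd$end, 10000L)
  expect_equal(count_windows(rnd, sizes1, 1000)$total_assigned, 100)

  expect_error(count_windows(reads, sizes1, 0), "positive")
})

test_that("control scaling follows the library-size ratio", {
  s <- window_counts(list(chr1 = rep(20, 10)), 1000, sizes1)   # total 200
  c0 <- window_counts(list(chr1 = rep(10, 10)), 1000, sizes1)  # total 100
  sc <- scale_control(s, c0)
  expect_equal(sc$counts$chr1, rep(20, 10))
  expect_equal(sc$scale_factor, 2)

  expect_equal(scale_control(s, s)$counts$chr1, rep(20, 10))
  expect_equal(scale_control(s, c0, library_scale = FALSE)$counts$chr1,
               rep(10, 10))

  zero <- window_counts(list(chr1 = rep(0, 10)), 1000, sizes1)
  expect_error(scale_control(s, zero), "zero")
})

test_that("the caller reproduces the worked one-spike example", {
  s <- window_counts(list(chr1 = c(rep(5, 9), 50)), 1000, sizes1)
  c0 <- window_counts(list(chr1 = rep(1, 10)), 1000, sizes1)
  pk <- call_peaks(s, c0, peak_call_config(library_scale = FALSE))
  rep <- peak_report(pk)
  # all ten windows enriched (5 >= 2); mean 9.5, population SD 13.5,
  # threshold exactly 50: only the spike window is significant
  expect_equal(rep$n_enriched, 10L)
  expect_equal(rep$mu, 9.5)
  expect_equal(rep$sigma, 13.5)
  expect_equal(rep$threshold, 50)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 9000L)
  expect_equal(pk$end, 10000L)
  expect_equal(pk$midpoint, 9500L)
  expect_equal(pk$sample_count, 50)
})

test_that("a sample identical to its control yields no peaks, with warning", {
  s <- window_counts(list(chr1 = rep(3, 10)), 1000, sizes1)
  expect_warning(pk <- call_peaks(s, s), "no windows")
  expect_equal(nrow(pk), 0L)
})

test_that("adjacent significant windows merge into one midpointed peak", {
  s <- window_counts(list(chr1 = c(2, 2, 2, 30, 30, 2, 2, 2, 2, 2)),
                     1000, sizes1)
  c0 <- window_counts(list(chr1 = rep(1, 10)), 1000, sizes1)
  pk <- call_peaks(s, c0, peak_call_config(library_scale = FALSE,
                                           sd_mult = 1))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 3000L)
  expect_equal(pk$end, 5000L)
  expect_equal(pk$midpoint, 4000L)
  expect_equal(pk$n_windows, 2L)
  expect_equal(pk$sample_count, 60)

  # unmerged mode keeps the two windows separate
  pk2 <- call_peaks(s, c0, peak_call_config(library_scale = FALSE,
                                            sd_mult = 1, merge = FALSE))
  expect_equal(nrow(pk2), 2L)
})

test_that("raising sd_mult never increases the significant-window count", {
  g <- random_grid(99)
  prev <- Inf
  for (k in seq(0, 4, by = 0.5)) {
    pk <- suppressWarnings(
      call_peaks(g$sample, g$control, peak_call_config(sd_mult = k)))
    n_sig <- peak_report(pk)$n_significant
    expect_lte(n_sig, prev)
    prev <- n_sig
  }
})

test_that("the caller matches the naive three-step reference on random grids", {
  for (seed in 1:5) {
    g <- random_grid(seed)
    pk <- suppressWarnings(call_peaks(g$sample, g$control))
    naive <- naive_call_peaks(g$s_counts, g$c_counts, 1000, g$sizes)
    expect_same_peaks(pk, naive)
  }
})

test_that("peaks round-trip through BED", {
  s <- window_counts(list(chr1 = c(rep(5, 9), 50)), 1000, sizes1)
  c0 <- window_counts(list(chr1 = rep(1, 10)), 1000, sizes1)
  pk <- call_peaks(s, c0, peak_call_config(library_scale = FALSE))
  path <- withr::local_tempfile(fileext = ".bed")
  write_peaks(pk, path)
  back <- read_peaks(path)
  expect_equal(back$chrom, pk$chrom)
  expect_equal(back$start, pk$start)
  expect_equal(back$end, pk$end)
  expect_equal(back$midpoint, pk$midpoint)
  expect_equal(back$sample_count, pk$sample_count)

  # empty set -> header-only file that reads back empty
  write_peaks(empty <- call_peaks(s, c0,
    peak_call_config(library_scale = FALSE, sd_mult = 1e6)), path)
  expect_true(startsWith(readLines(path)[1], "#"))
  expect_equal(nrow(read_peaks(path)), 0L)
})
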