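mk_peaks <- function(chrom, midpoint, half = 500L) {
  data.frame(chrom = chrom, start = midpoint - half, end = midpoint + half,
             midpoint = midpoint, stringsAsFactors = FALSE)
}

test_that("inter-origin distances are successive midpoint differences", {
  pk <- mk_peaks("chr1", c(10000L, 35000L, 61000L))
  res <- inter_origin_distances(pk)
  expect_equal(res$per_chrom$chr1, c(25000, 26000))
  expect_equal(res$distances, c(25000, 26000))
  expect_equal(res$summary$n, 2L)

  # one peak per chromosome contributes nothing
  lone <- mk_peaks(c("chr1", "chr2"), c(1000L, 2000L))
  expect_length(inter_origin_distances(lone)$distances, 0L)

  # pooled median equals the brute-force sort-and-middle value, and the
  # distance count invariant holds: n_peaks - n_chromosomes_with_peaks
  pk2 <- withr::with_seed(21, {
    n <- 80
    mk_peaks(sample(c("chr1", "chr2", "chr3"), n, TRUE),
             as.integer(sample(1e3:1e6, n)))
  })
  res2 <- inter_origin_distances(pk2)
  srt <- sort(res2$distances)
  n <- length(srt)
  brute_med <- if (n %% 2 == 1) srt[(n + 1) / 2] else
    (srt[n / 2] + srt[n / 2 + 1]) / 2
  expect_equal(res2$summary$median, brute_med)
  expect_equal(n, nrow(pk2) - length(unique(pk2$chrom)))
})

test_that("overlap fractions count any shared base pair, both directions", {
  a <- mk_peaks("chr1", c(10000L, 50000L))
  expect_equal(overlap_fraction(a, a)$frac_a_in_b, 1)
  expect_equal(overlap_fraction(a, a)$frac_b_in_a, 1)

  b <- mk_peaks("chr2", c(10000L, 50000L))
  expect_equal(overlap_fraction(a, b)$frac_a_in_b, 0)

  # single shared base pair counts
  x <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  y <- data.frame(chrom = "chr1", start = 199L, end = 300L)
  expect_equal(overlap_fraction(x, y)$frac_a_in_b, 1)
  z <- data.frame(chrom = "chr1", start = 200L, end = 300L)
  expect_equal(overlap_fraction(x, z)$frac_a_in_b, 0)

  # asymmetric denominators, symmetric hit logic
  big <- mk_peaks("chr1", c(10000L, 50000L, 90000L))
  ov <- overlap_fraction(a, big)
  expect_equal(ov$n_a_in_b, 2L)
  expect_equal(ov$n_b_in_a, 2L)
  expect_equal(ov$frac_b_in_a, 2 / 3)
})

test_that("TSS distances are signed by TSS strand and match brute force", {
  tss <- data.frame(chrom = "chr1", pos = c(10000L, 50000L),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  at <- tss_distance_distribution(mk_peaks("chr1", 10000L), tss)
  expect_equal(at$distances, 0)

  down_plus <- tss_distance_distribution(mk_peaks("chr1", 10500L), tss)
  expect_equal(down_plus$distances, 500)

  down_minus <- tss_distance_distribution(mk_peaks("chr1", 49500L), tss)
  expect_equal(down_minus$distances, 500)

  expect_error(tss_distance_distribution(mk_peaks("chr1", 1L),
                                         tss[0, ]), "empty")

  # peaks on chromosomes without any TSS are excluded and counted
  mixed <- mk_peaks(c("chr1", "chrU"), c(10000L, 5000L))
  res <- tss_distance_distribution(mixed, tss)
  expect_equal(res$n_excluded, 1L)
  expect_length(res$distances, 1L)

  # nearest-TSS assignment equals the all-pairs brute force
  set <- withr::with_seed(33, list(
    tss = data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                     pos = as.integer(sample(1e3:5e5, 50)),
                     strand = sample(c("+", "-"), 50, TRUE),
                     stringsAsFactors = FALSE),
    peaks = mk_peaks(sample(c("chr1", "chr2"), 200, TRUE),
                     as.integer(sample(1e3:5e5, 200)))))
  got <- tss_distance_distribution(set$peaks, set$tss)
  want <- unlist(lapply(unique(set$peaks$chrom), function(cm) {
    mids <- set$peaks$midpoint[set$peaks$chrom == cm]
    vapply(mids, brute_tss_signed, numeric(1), chrom = cm, tss = set$tss)
  }))
  expect_equal(sort(got$distances), sort(want))
  expect_equal(sum(got$counts) + got$n_excluded, nrow(set$peaks))
})

test_that("condition comparison reports medians and a rank-sum p", {
  a <- c(20, 25, 30, 35, 40) * 1000
  same <- compare_conditions(a, a)
  expect_equal(same$summary$median[1], same$summary$median[2])
  expect_equal(same$test$p.value, 1)

  shifted <- compare_conditions(a, a + 1000)
  expect_equal(shifted$median_diff, 1000)

  expect_error(compare_conditions(numeric(0), a), "non-empty")
})
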