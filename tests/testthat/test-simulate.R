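test_that("origin placement respects bounds, spacing and determinism", {
  sizes <- c(chr1 = 1e6)
  expect_equal(nrow(simulate_origins(genome_spec(sizes, 0))), 0L)

  sp <- genome_spec(sizes, 10, min_spacing = 10000)
  org <- simulate_origins(sp, seed = 42)
  expect_equal(nrow(org), 10L)
  expect_true(all(org$pos >= 0 & org$pos < 1e6))
  expect_false(is.unsorted(org$pos))
  expect_true(all(diff(org$pos) >= 10000))
  expect_identical(org, simulate_origins(sp, seed = 42))
  expect_false(identical(org$pos, simulate_origins(sp, seed = 43)$pos))

  # multi-chromosome output sorted within each chromosome
  sizes2 <- c(chrA = 5e5, chrB = 5e5)
  org2 <- simulate_origins(genome_spec(sizes2, 30), seed = 1)
  for (cm in names(sizes2)) {
    expect_false(is.unsorted(org2$pos[org2$chrom == cm]))
  }
})

test_that("full TSS bias places every origin within the TSS window", {
  sizes <- c(chr1 = 1e6)
  tss <- simulate_tss(sizes, 40, seed = 5)
  sp <- genome_spec(sizes, 25, tss = tss, origin_tss_bias = 1,
                    tss_window = 1000, min_spacing = 0)
  org <- simulate_origins(sp, seed = 9)
  near <- vapply(org$pos, function(p) min(abs(tss$pos - p)) <= 1000,
                 logical(1))
  expect_true(all(near))
})

test_that("impossible placement errors and names the chromosome", {
  sp <- genome_spec(c(tiny = 50000), 30, min_spacing = 10000)
  expect_error(simulate_origins(sp, seed = 1), "tiny")
})

test_that("BrIP-seq reads stay near their origins and conserve depth", {
  sizes <- c(chr1 = 1e6)
  org <- data.frame(origin_id = 1L, chrom = "chr1", pos = 500000L,
                    efficiency = 1, near_tss = FALSE)

  # zero depth
  empty <- simulate_bripseq(org, sizes,
                            brip_sim_spec(reads_per_origin = 0,
                                          background_rate = 0,
                                          control_rate = 0), seed = 1)
  expect_equal(nrow(empty$sample), 0L)

  # support bound: no background, all reads within the nascent range of
  # the planted origin
  rs <- simulate_bripseq(org, sizes,
                         brip_sim_spec(reads_per_origin = 200,
                                       background_rate = 0,
                                       control_rate = 1), seed = 2)
  expect_true(all(rs$sample$start >= 500000 - 3000 &
                    rs$sample$start <= 500000 + 3000))
  expect_false(is.unsorted(rs$sample$start))
  expect_true(all(rs$sample$end - rs$sample$start == 75))

  # Poisson bound on the stated-control depth: expect rate * genome kb
  rs2 <- simulate_bripseq(org, sizes,
                          brip_sim_spec(reads_per_origin = 0,
                                        background_rate = 0,
                                        control_rate = 2), seed = 3)
  expect_lt(abs(nrow(rs2$control) - 2000), 4 * sqrt(2000))

  # matched-depth control mirrors the sample library size
  rs3 <- simulate_bripseq(org, sizes,
                          brip_sim_spec(reads_per_origin = 100,
                                        background_rate = 0.5), seed = 4)
  expect_equal(nrow(rs3$control), nrow(rs3$sample))

  # determinism
  expect_identical(rs, simulate_bripseq(org, sizes,
                                        brip_sim_spec(reads_per_origin = 200,
                                                      background_rate = 0,
                                                      control_rate = 1),
                                        seed = 2))
})

test_that("poly-T tailing appends exactly the drawn tails", {
  rec <- make_fastq(c("r1", "r2"), c("ACGA", "GGGC"))
  same <- emit_fastq(rec, c(0, 0), seed = 1)
  expect_equal(same$sequence, rec$sequence)
  expect_equal(same$quality, rec$quality)

  tailed <- emit_fastq(make_fastq("r1", "ACGA"), c(5, 5), seed = 1)
  expect_equal(tailed$sequence, "ACGATTTTT")
  expect_equal(nchar(tailed$quality), 9L)

  expect_error(emit_fastq(rec, c(-2, 5), seed = 1), "non-negative")

  # record count conserved from reads to FASTQ
  reads <- data.frame(chrom = "chr1", start = 0L, end = 75L,
                      name = "x", stringsAsFactors = FALSE)
  reads <- reads[rep(1, 17), ]
  reads$name <- sprintf("r%02d", 1:17)
  fq <- fastq_from_reads(reads, seed = 2)
  expect_equal(nrow(fq), 17L)
  expect_true(all(nchar(fq$sequence) == 75L))
})

test_that("fiber patterns hit their deterministic limits", {
  sp <- combing_sim_spec(n_fibers = 15,
                         fiber_len_um = c(mean = 200, sd = 0),
                         fork_rate_kb_min = c(mean = 1.2, sd = 0),
                         iod_kb = c(mean = 96, sd = 0))
  fb <- simulate_fibers(sp, seed = 11)

  # complete second-pulse tracks are exactly rate * pulse2 = 36 kb = 18 um
  idu <- fork_rates(fb$fibers, combing_config(measure = "IdU"))
  expect_gt(nrow(idu), 0)
  expect_equal(idu$rate_kb_min, rep(1.2, nrow(idu)), tolerance = 1e-9)

  # adjacent origin centres sit exactly 48 um = 96 kb apart
  io <- fiber_iods(fb$fibers)
  expect_gt(nrow(io), 0)
  expect_equal(io$iod_kb, rep(96, nrow(io)), tolerance = 1e-9)

  # segments are sorted, non-overlapping, inside the fiber
  for (fid in unique(fb$fibers$fiber_id)) {
    seg <- fb$fibers[fb$fibers$fiber_id == fid, ]
    expect_true(all(seg$start_um >= -1e-9))
    expect_true(all(seg$end_um <= seg$fiber_len_um[1] + 1e-9))
    if (nrow(seg) > 1) {
      expect_true(all(seg$start_um[-1] - seg$end_um[-nrow(seg)] >= -1e-9))
    }
  }
  expect_identical(fb, simulate_fibers(sp, seed = 11))
})

test_that("fibers shorter than one pattern carry truncated segments", {
  sp <- combing_sim_spec(n_fibers = 30,
                         fiber_len_um = c(mean = 25, sd = 0),
                         fork_rate_kb_min = c(mean = 1.2, sd = 0),
                         iod_kb = c(mean = 96, sd = 0))
  fb <- simulate_fibers(sp, seed = 3)
  expect_true(any(fb$fibers$truncated))
  # nothing measurable on fibers that cannot hold a full pattern
  expect_equal(nrow(fiber_iods(fb$fibers)), 0L)
})
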