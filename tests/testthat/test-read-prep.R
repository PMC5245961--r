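test_that("poly-T trimming removes exactly the maximal trailing run", {
  rec <- make_fastq(c("a", "b", "c", "d"),
                    c("ACGTTTT", "ACGA", "TTTT", "ACGTNTT"))
  out <- trim_polyt(rec, min_len_after = 2)
  expect_equal(out$sequence, c("ACG", "ACGA", "", "ACGTN"))
  expect_equal(nchar(out$quality), nchar(out$sequence))
  expect_equal(out$bases_trimmed, c(4L, 0L, 4L, 2L))
  expect_equal(out$discarded, c(FALSE, FALSE, TRUE, FALSE))

  # an all-T read below the length floor is discarded
  short <- trim_polyt(make_fastq("t", "TTTT"), min_len_after = 20)
  expect_true(short$discarded)

  # length mismatch is an error
  bad <- data.frame(id = "x", sequence = "ACGT", quality = "II",
                    stringsAsFactors = FALSE)
  expect_error(trim_polyt(bad), "mismatch")
})

test_that("trimming is idempotent and never lengthens a read", {
  recs <- withr::with_seed(7, {
    n <- 200
    base <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T", "N"), sample(20:60, 1),
                   replace = TRUE), collapse = "")
    }, character(1))
    make_fastq(sprintf("r%03d", seq_len(n)), base)
  })
  tailed <- emit_fastq(recs, c(0, 12), seed = 8)
  once <- trim_polyt(tailed, min_len_after = 0)
  twice <- trim_polyt(once[c("id", "sequence", "quality")],
                      min_len_after = 0)
  expect_equal(twice$sequence, once$sequence)
  expect_equal(twice$quality, once$quality)
  expect_true(all(nchar(once$sequence) <= nchar(tailed$sequence)))
})

test_that("FASTQ files round-trip through write and read", {
  rec <- make_fastq(c("read/1", "read/2"), c("ACGTN", "GGTTA"),
                    c("IIIII", "!!IB#"))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rec, path)
  back <- read_fastq(path)
  expect_equal(back$id, rec$id)
  expect_equal(back$sequence, rec$sequence)
  expect_equal(back$quality, rec$quality)
})

test_that("BED reads parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".bed")

  writeLines(character(), path)
  expect_equal(nrow(load_reads_bed(path)), 0L)

  writeLines(c("# header", "chr1\t100\t175\tr1\t0\t+"), path)
  rd <- load_reads_bed(path)
  expect_equal(rd$chrom, "chr1")
  expect_equal(rd$start, 100L)
  expect_equal(rd$end, 175L)
  expect_equal(rd$strand, "+")

  # malformed lines raise with their line number
  writeLines(c("chr1\t100\t175", "chr1\toops\t200"), path)
  expect_error(load_reads_bed(path), "line 2")
  writeLines(c("chr1\t100\t175", "chr1\t300\t200"), path)
  expect_error(load_reads_bed(path), "line 2")
  writeLines("chr1\t100", path)
  expect_error(load_reads_bed(path), "at least 3 fields")

  # out-of-bounds records are rejected and tallied, not fatal
  writeLines(c("chr1\t100\t175\tr1\t0\t+",
               "chr1\t999990\t1000065\tr2\t0\t-",
               "chrX\t0\t75\tr3\t0\t+"), path)
  rd <- load_reads_bed(path, chrom_sizes = c(chr1 = 1e6))
  expect_equal(nrow(rd), 1L)
  expect_equal(attr(rd, "n_rejected"), 2L)

  # write -> read is the identity on valid records
  reads <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 10L),
                      end = c(75L, 85L), name = c("a", "b"),
                      score = c(0, 0), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  write_reads_bed(reads, path)
  back <- load_reads_bed(path)
  attr(back, "n_rejected") <- NULL
  expect_equal(back, reads)
})

test_that("chromosome-sizes tables round-trip", {
  path <- withr::local_tempfile()
  sizes <- c(chr1 = 123456, chr2 = 7890)
  write_chrom_sizes(sizes, path)
  expect_equal(read_chrom_sizes(path), sizes)
})
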