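# hand-built fiber: one complete origin pattern away from both ends
# (IdU 12-30 | CldU 30-66 | IdU 66-84 on a 100 um fiber; rates 1.2 kb/min
# at 2 kb/um and 30/30 min pulses)
pattern_fiber <- function(fiber_id = 1L, shift = 0, len = 100) {
  data.frame(
    fiber_id = fiber_id, fiber_len_um = len,
    label = c("IdU", "CldU", "IdU"),
    start_um = c(12, 30, 66) + shift,
    end_um = c(30, 66, 84) + shift,
    truncated = FALSE, stringsAsFactors = FALSE)
}

test_that("fork rates follow the configured label convention", {
  fib <- pattern_fiber()

  # IdU convention: 18 um x 2 kb/um / 30 min = 1.2 kb/min, one per flank
  idu <- fork_rates(fib, combing_config(measure = "IdU"))
  expect_equal(idu$rate_kb_min, c(1.2, 1.2))

  # CldU convention: 36 um x 2 / (2 x 30) = 1.2 kb/min, one per pattern
  cld <- fork_rates(fib, combing_config(measure = "CldU"))
  expect_equal(cld$rate_kb_min, 1.2)

  # an IdU segment abutting the fiber end is censored
  edge <- fib
  edge$start_um[3] <- 82
  edge$end_um[3] <- 100
  expect_equal(nrow(fork_rates(edge, combing_config(measure = "IdU"))), 1L)

  # IdU flanked by CldU on both sides = converged forks, excluded by
  # default, measured when requested
  conv <- data.frame(
    fiber_id = 1L, fiber_len_um = 200,
    label = c("IdU", "CldU", "IdU", "CldU", "IdU"),
    start_um = c(12, 30, 66, 78, 114),
    end_um = c(30, 66, 78, 114, 132),
    truncated = FALSE, stringsAsFactors = FALSE)
  strict <- fork_rates(conv, combing_config(measure = "IdU"))
  loose <- fork_rates(conv, combing_config(measure = "IdU",
                                           exclude_converged = FALSE))
  expect_equal(nrow(strict), 2L)
  expect_equal(nrow(loose), 3L)
})

test_that("fiber inter-origin distances use origin centres", {
  two <- data.frame(
    fiber_id = 1L, fiber_len_um = 200,
    label = c("IdU", "CldU", "IdU", "CldU", "IdU"),
    start_um = c(10, 28, 64, 76, 112),
    end_um = c(28, 64, 76, 112, 130),
    truncated = FALSE, stringsAsFactors = FALSE)
  # CldU centres at 46 and 94 um -> 48 um -> 96 kb
  io <- fiber_iods(two)
  expect_equal(io$iod_kb, 96)

  # a single origin yields no distance
  expect_equal(nrow(fiber_iods(pattern_fiber())), 0L)
})

test_that("estimates are invariant under fiber orientation reversal", {
  fb <- simulate_fibers(combing_sim_spec(n_fibers = 60), seed = 5)$fibers
  mirrored <- fb
  mirrored$start_um <- fb$fiber_len_um - fb$end_um
  mirrored$end_um <- fb$fiber_len_um - fb$start_um
  expect_equal(sort(fork_rates(mirrored)$rate_kb_min),
               sort(fork_rates(fb)$rate_kb_min))
  expect_equal(sort(fiber_iods(mirrored)$iod_kb),
               sort(fiber_iods(fb)$iod_kb))
  expect_true(all(fork_rates(fb)$rate_kb_min > 0))
  expect_true(all(fiber_iods(fb)$iod_kb > 0))
})

two_origin_fiber <- function(fiber_id = 1L, shift = 0) {
  data.frame(
    fiber_id = fiber_id, fiber_len_um = 200,
    label = c("IdU", "CldU", "IdU", "CldU", "IdU"),
    start_um = c(10, 28, 64, 76, 112) + shift,
    end_um = c(28, 64, 76, 112, 130) + shift,
    truncated = FALSE, stringsAsFactors = FALSE)
}

test_that("condition reports compare medians and scale as expected", {
  a <- rbind(two_origin_fiber(1L), two_origin_fiber(2L, shift = 5),
             two_origin_fiber(3L, shift = -5))
  same <- suppressWarnings(combing_report(a, a))
  expect_equal(same$p_values[["fork_rate"]], 1)
  expect_equal(same$summary$median[1], same$summary$median[2])

  # uniformly stretching the fiber scales every rate by the same factor
  b <- a
  for (col in c("fiber_len_um", "start_um", "end_um")) {
    b[[col]] <- a[[col]] * 1.25
  }
  rep <- suppressWarnings(combing_report(a, b))
  med <- rep$summary$median[rep$summary$metric == "fork_rate_kb_min"]
  expect_equal(med[2] / med[1], 1.25)

  # empty conditions fail loudly, naming the condition
  none <- pattern_fiber()[0, ]
  expect_error(combing_report(a, none, labels = c("wt", "ko")), "ko")
})

test_that("fiber tables round-trip through TSV", {
  fb <- simulate_fibers(combing_sim_spec(n_fibers = 5), seed = 2)$fibers
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fibers(fb, path)
  expect_equal(read_fibers(path), fb)
  writeLines("fiber_id\tlabel", path)
  expect_error(read_fibers(path), "columns")
})
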