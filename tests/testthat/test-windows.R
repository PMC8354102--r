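make_tu <- function(strand = "+", tss = 1000, pas = 81000, ...) {
  transcription_unit("tu1", "chr1", strand, tss, pas, ...)
}

test_that("window grids tile transcription units as specified", {
  tu <- make_tu()
  body <- make_windows(tu, "body")
  expect_equal(nrow(body), 80)
  expect_true(all(body$end - body$start == 1000))
  # partition: no gaps, no overlaps
  expect_equal(body$start[-1], body$end[-nrow(body)])
  pas <- make_windows(tu, "pas")
  expect_equal(nrow(pas), 120)
  expect_equal(sum(pas$rel < 0), 20)
  expect_equal(sum(pas$rel >= 0), 100)
  # minus strand: window 1 genomically rightmost
  tum <- make_tu("-", tss = 81000, pas = 1000)
  bm <- make_windows(tum, "body")
  expect_equal(bm$start[1], 80000)
  expect_true(all(diff(bm$start) < 0))
  expect_warning(make_windows(transcription_unit("s", "chr1", "+", 0, 500),
                              "body"), "shorter")
})

test_that("strand orientation is rejected when inconsistent", {
  expect_error(transcription_unit("x", "chr1", "+", 500, 100), "downstream")
  expect_error(transcription_unit("x", "chr1", "-", 100, 500), "downstream")
})

test_that("coverage counting sums value x overlap per window", {
  tu <- make_tu(tss = 0, pas = 2000)
  win <- make_windows(tu, "body")
  cov <- data.frame(chrom = "chr1", start = 0, end = 5000, value = 1.0)
  wv <- count_coverage(cov, tu, win)
  expect_equal(wv$count, c(1000, 1000))
  # additivity: counting two tracks then summing equals counting the sum
  cov2 <- data.frame(chrom = "chr1", start = c(0, 700), end = c(700, 5000),
                     value = c(2, 3))
  both <- count_coverage(cov2, tu, win)
  covsum <- data.frame(chrom = "chr1", start = c(0, 700),
                       end = c(700, 5000), value = c(3, 4))
  expect_equal(count_coverage(covsum, tu, win)$count,
               both$count + wv$count)
  # absent chromosome: all-missing with a warning
  expect_warning(
    wv2 <- count_coverage(data.frame(chrom = "chrX", start = 0, end = 10,
                                     value = 1), tu, win),
    "absent")
  expect_true(all(wv2$missing))
})

test_that("exon overlap flags windows missing and input may go negative", {
  tu <- make_tu(tss = 0, pas = 5000,
                exons = data.frame(start = 1500, end = 1600))
  win <- make_windows(tu, "body")
  cov <- data.frame(chrom = "chr1", start = 0, end = 5000, value = 1.0)
  wv <- count_coverage(cov, tu, win)
  expect_identical(wv$missing, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  # input-corrected counts keep negative values
  inp <- data.frame(chrom = "chr1", start = 0, end = 5000, value = 2.0)
  wvc <- count_coverage(cov, tu, win, input = inp)
  expect_equal(wvc$count, rep(-1000, 5))
  expect_equal(censor_counts(wvc$count), rep(0, 5))
})

test_that("strand-keyed coverage respects the TU strand", {
  tu <- make_tu(tss = 0, pas = 2000)
  cov <- list(
    "+" = data.frame(chrom = "chr1", start = 0, end = 5000, value = 1),
    "-" = data.frame(chrom = "chr1", start = 0, end = 5000, value = 5))
  win <- make_windows(tu, "body")
  expect_equal(count_coverage(cov, tu, win)$count, c(1000, 1000))
  expect_equal(count_coverage(cov, tu, win,
                              same_strand_only = FALSE)$count,
               c(6000, 6000))
})

test_that("termination-zone masking applies the three missing rules", {
  grid_rel <- seq(-5000, 24750, 250)
  wv <- window_vector("t", "pas", 250, rep(1, 120), rel = grid_rel)
  # short TU: windows upstream of the whole TU flagged
  tu_short <- transcription_unit("t", "chr1", "+", 10000, 14000)
  f1 <- flag_termination_missing(tu_short, list(), wv)
  expect_true(all(f1$missing[f1$rel < -4000]))
  expect_false(any(f1$missing[f1$rel >= -4000]))
  # same-strand downstream neighbor: windows beyond its TSS flagged
  tu <- transcription_unit("t", "chr1", "+", 2000, 14000)
  nb <- transcription_unit("n", "chr1", "+", 24000, 40000)
  f2 <- flag_termination_missing(tu, list(nb), wv)
  expect_true(all(f2$missing[f2$rel >= 10000]))
  expect_false(any(f2$missing[f2$rel < 10000]))
  # opposite strand or far neighbor: untouched
  nb_minus <- transcription_unit("m", "chr1", "-", 40000, 24000)
  nb_far <- transcription_unit("f", "chr1", "+", 100000, 140000)
  f3 <- flag_termination_missing(tu, list(nb_minus, nb_far), wv)
  expect_false(any(f3$missing))
})

test_that("spike size factors divide by the median total", {
  expect_equal(spike_size_factors(c(10, 20, 40)), c(0.5, 1, 2))
  expect_equal(spike_size_factors(c(7, 7, 7)), c(1, 1, 1))
  expect_equal(spike_size_factors(12), 1)
  expect_error(spike_size_factors(c(10, 0)), "positive")
})

test_that("window tables and bedGraph files round-trip", {
  wv <- window_vector("g1", "body", 1000, c(3, 0, 7), c(FALSE, TRUE, FALSE))
  tmp <- tempfile(fileext = ".tsv")
  write_window_tsv(list(g1 = wv), tmp)
  back <- read_window_tsv(tmp)[["g1"]]
  expect_equal(back$count, wv$count)
  expect_identical(back$missing, wv$missing)
  expect_equal(attr(back, "width_nt"), 1000)
  bg <- data.frame(chrom = "chr1", start = c(0L, 100L), end = c(100L, 250L),
                   value = c(1.5, 2))
  tmp2 <- tempfile(fileext = ".bedGraph")
  write_bedgraph(bg, tmp2)
  expect_equal(read_bedgraph(tmp2), bg)
})
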