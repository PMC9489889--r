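test_that("stitching merges by gap against the 4 kb window", {
  pk <- gr1("chr1", c(101, 3001), c(200, 3100))  # gap 2800 <= 4000
  rd <- stitchPeaks(pk, 4000)
  expect_length(domains(rd), 1L)
  expect_equal(GenomicRanges::start(domains(rd)), 101L)
  expect_equal(GenomicRanges::end(domains(rd)), 3100L)
  expect_equal(S4Vectors::mcols(domains(rd))$n_constituents, 2L)

  pk2 <- gr1("chr1", c(101, 5001), c(200, 5100))  # gap 4800 > 4000
  expect_length(domains(stitchPeaks(pk2, 4000)), 2L)

  expect_error(stitchPeaks(gr1("chr1", 10, 9)), "start >= end")
})

test_that("stitching matches the transitive-closure oracle on random sets", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(50:200, 1)
    chrom <- sample(c("chr1", "chr2"), n, TRUE)
    s <- sample.int(2e5, n)
    e <- s + sample.int(3000, n)
    window <- sample(c(0, 500, 4000), 1)
    rd <- stitchPeaks(gr1(chrom, s, e), window)
    oracle <- bruteStitch(chrom, s, e, window)
    dom <- domains(rd)
    expect_equal(as.character(GenomicRanges::seqnames(dom)), oracle$chrom)
    expect_equal(GenomicRanges::start(dom), oracle$start)
    expect_equal(GenomicRanges::end(dom), oracle$end)
    expect_equal(S4Vectors::mcols(dom)$n_constituents, oracle$n)
  }
})

test_that("stitching is idempotent and monotone in the window", {
  set.seed(22)
  n <- 150
  pk <- gr1(sample(c("chr1", "chr2"), n, TRUE), s <- sample.int(1e5, n),
            s + sample.int(2000, n))
  once <- domains(stitchPeaks(pk, 4000))
  twice <- domains(stitchPeaks(once, 4000))
  expect_equal(GenomicRanges::start(twice), GenomicRanges::start(once))
  expect_equal(GenomicRanges::end(twice), GenomicRanges::end(once))

  counts <- vapply(c(0, 100, 1000, 4000, 20000), function(w)
    length(domains(stitchPeaks(pk, w))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("region scores are background-subtracted span densities", {
  chip <- SignalTrack(list(chr1 = rep(2, 40)), binSize = 50)
  input <- SignalTrack(list(chr1 = rep(0.5, 40)), binSize = 50)
  rd <- stitchPeaks(gr1("chr1", 501, 1500), 4000)  # span 1000 bp
  expect_equal(S4Vectors::mcols(domains(
    scoreRegions(rd, chip, input)))$score, 1500)  # (2 - 0.5) * 1000

  same <- scoreRegions(rd, chip, chip)
  expect_equal(S4Vectors::mcols(domains(same))$score, 0)

  flipped <- scoreRegions(rd, input, chip)  # input > chip, clamped
  expect_equal(S4Vectors::mcols(domains(flipped))$score, 0)
  unclamped <- scoreRegions(rd, input, chip, clampNegative = FALSE)
  expect_equal(S4Vectors::mcols(domains(unclamped))$score, -1500)
})

test_that("constituents scoring sums over peaks only", {
  chip <- SignalTrack(list(chr1 = rep(2, 200)), binSize = 50)
  input <- SignalTrack(list(chr1 = rep(1, 200)), binSize = 50)
  # two 100 bp peaks 3 kb apart: constituents score 2*100*(2-1) = 200,
  # whole-span score (2-1)*3200 = 3200
  rd <- stitchPeaks(gr1("chr1", c(1001, 4101), c(1100, 4200)), 4000)
  expect_equal(S4Vectors::mcols(domains(scoreRegions(
    rd, chip, input, scoreMode = "constituents")))$score, 200)
  expect_equal(S4Vectors::mcols(domains(scoreRegions(
    rd, chip, input)))$score, 3200)
})

test_that("tangent-line cutoff matches the exhaustive oracle", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(10:200, 1)
    scores <- switch(sample(3, 1),
                     runif(n, 0, 10),
                     c(runif(n - 3, 0, 5), runif(3, 100, 500)),
                     rexp(n, 1 / 50))
    res <- findCutoff(scores)
    oracle <- bruteCutoff(scores)
    expect_identical(res$cutoff_index, oracle$cutoff_index)
    expect_identical(res$points_below, oracle$points_below)
    expect_equal(res$cutoff_value, oracle$cutoff_value)
  }
})

test_that("flat score vectors yield a degenerate conservative cutoff", {
  res <- findCutoff(rep(4, 10))
  expect_equal(res$cutoff_index, 1L)
  expect_equal(res$points_below, 0L)
  expect_equal(res$cutoff_value, 4)
  expect_error(findCutoff(7), "at least 2")
  expect_error(findCutoff(c(NA, NA)), "NA")
})

test_that("a planted heavy tail is separated at the cutoff", {
  set.seed(33)
  scores <- c(runif(95, 0, 10), runif(5, 500, 1000))
  res <- findCutoff(scores)
  expect_true(res$cutoff_value < 500)
  expect_equal(sum(scores > res$cutoff_value), 5L)
})

test_that("the full caller ranks, flags and handles degenerate inputs", {
  set.seed(41)
  chip <- SignalTrack(list(chr1 = c(rep(1, 100), rep(10, 100), rep(1, 800))),
                      binSize = 50)
  input <- SignalTrack(list(chr1 = rep(1, 1000)), binSize = 50)
  peaks <- gr1("chr1", c(seq(5001, 9001, 1000), seq(15001, 45001, 3000)),
               c(seq(5300, 9300, 1000), seq(15400, 45400, 3000)))
  rd <- callRichDomains(peaks, chip, input)
  dom <- domains(rd)
  sc <- S4Vectors::mcols(dom)$score
  expect_equal(S4Vectors::mcols(dom)$rank, seq_along(dom))
  expect_true(all(diff(sc) <= 0))  # descending
  # rich is monotone in score: everything above the lowest rich score is rich
  rich <- S4Vectors::mcols(dom)$is_rich
  if (any(rich)) expect_true(all(rich[sc > min(sc[rich])]))
  expect_equal(sum(rich), sum(sc > cutoffInfo(rd)$cutoff_value))

  empty <- callRichDomains(GenomicRanges::GRanges(), chip, input)
  expect_length(domains(empty), 0L)

  expect_warning(single <- callRichDomains(gr1("chr1", 5001, 5300),
                                           chip, input), "single")
  expect_false(any(S4Vectors::mcols(domains(single))$is_rich))
})

test_that("domain BED export round-trips ranks and flags", {
  chip <- SignalTrack(list(chr1 = rep(c(1, 8), each = 200)), binSize = 50)
  input <- SignalTrack(list(chr1 = rep(1, 400)), binSize = 50)
  peaks <- gr1("chr1", c(1001, 3001, 12001, 15001),
               c(1500, 3500, 12500, 15500))
  rd <- callRichDomains(peaks, chip, input)
  f <- tempfile(fileext = ".bed")
  writeDomainBed(rd, f)
  expect_true(file.exists(paste0(f, ".summary.json")))
  back <- readBed(f)
  expect_length(back, length(domains(rd)))
  summ <- jsonlite::read_json(paste0(f, ".summary.json"))
  expect_equal(summ$n_regions, length(domains(rd)))
})
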