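test_that("readBed parses the BED convention and validates input", {
  f <- writeLinesTmp(c("chr1\t100\t200", "chr2\t0\t50\tx\t0\t-"))
  gr <- readBed(f)
  expect_equal(as.character(GenomicRanges::seqnames(gr)), c("chr1", "chr2"))
  expect_equal(GenomicRanges::start(gr), c(101L, 1L))  # 0-based -> 1-based
  expect_equal(GenomicRanges::end(gr), c(200L, 50L))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("*", "-"))

  expect_length(readBed(writeLinesTmp(character())), 0L)
  expect_error(readBed(writeLinesTmp("chr1\t100")), "line 1")
  expect_error(readBed(writeLinesTmp("chr1\t200\t100\tx")), "start")
  expect_error(readBed(writeLinesTmp("chr1\tabc\t100")), "parse")
})

test_that("BED round-trip preserves coordinates and strand exactly", {
  set.seed(11)
  n <- 50
  s <- sort(sample.int(1e6, n))
  gr <- gr1(sample(c("chr1", "chr2"), n, TRUE), s, s + sample.int(5000, n),
            sample(c("+", "-", "*"), n, TRUE))
  S4Vectors::mcols(gr)$name <- sprintf("iv%02d", seq_len(n))
  S4Vectors::mcols(gr)$score <- round(runif(n), 3)
  f <- tempfile(fileext = ".bed")
  writeBed(gr, f)
  back <- readBed(f)
  idx <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr))
  ord <- gr[idx]
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(ord))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(ord))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(ord)))
  expect_equal(S4Vectors::mcols(back)$name, S4Vectors::mcols(ord)$name)
})

test_that("narrowPeak summits follow the offset/-1 convention", {
  f <- writeLinesTmp(c(
    "chr1\t100\t300\tp1\t0\t.\t7.5\t-1\t-1\t50",
    "chr1\t400\t500\tp2\t0\t.\t3.0\t-1\t-1\t-1"), ".narrowPeak")
  pk <- readNarrowPeak(f)
  expect_equal(S4Vectors::mcols(pk)$score, c(7.5, 3.0))
  # summit offset 50 on 0-based [100,300) is absolute position 150
  expect_equal(S4Vectors::mcols(pk)$summit[1] - 1L, 150L)
  expect_true(is.na(S4Vectors::mcols(pk)$summit[2]))
  expect_error(readNarrowPeak(writeLinesTmp("chr1\t1\t2\tx", ".narrowPeak")),
               "10 columns")
})

test_that("bedGraph resampling is coverage-weighted with zero fill", {
  f <- writeLinesTmp("chr1\t0\t100\t2.0", ".bedGraph")
  st <- readBedGraph(f, binSize = 50)
  expect_equal(trackValues(st)$chr1, c(2, 2))

  # half-covered bin: [0,50)=4 at bin 100 -> 4*50/100 = 2
  f2 <- writeLinesTmp("chr1\t0\t50\t4.0", ".bedGraph")
  expect_equal(trackValues(readBedGraph(f2, binSize = 100))$chr1, 2)

  lines <- sprintf("chr1\t%d\t%d\t%g", seq(0, 900, 100), seq(100, 1000, 100),
                   1:10)
  sorted <- readBedGraph(writeLinesTmp(lines, ".bedGraph"), 50)
  set.seed(3)
  shuffled <- readBedGraph(writeLinesTmp(sample(lines), ".bedGraph"), 50)
  expect_identical(trackValues(sorted), trackValues(shuffled))

  bad <- writeLinesTmp(c("chr1\t0\t100\t1", "chr1\t50\t150\t2"), ".bedGraph")
  expect_error(readBedGraph(bad, 50), "contradictory")
})

test_that("meanSignal is a length-weighted bin mean with clipping", {
  st <- SignalTrack(list(chr1 = c(3, 3, 3, 3)), binSize = 100)
  expect_equal(meanSignal(st, gr1("chr1", 51, 350)), 3)

  st2 <- SignalTrack(list(chr1 = c(1, 3)), binSize = 100)
  expect_equal(meanSignal(st2, gr1("chr1", 51, 150)), 2)  # half of each bin

  expect_warning(v <- meanSignal(st2, gr1("chr1", 151, 400)), "clip")
  expect_equal(v, 3)
  expect_error(meanSignal(st2, gr1("chr1", 10, 9)), "zero-length")
  expect_error(meanSignal(st2, gr1("chrZ", 1, 10)), "chrZ")
})

test_that("meanSignal conserves mass over a disjoint union", {
  set.seed(5)
  st <- SignalTrack(list(chr1 = runif(100, 0, 10)), binSize = 37)
  parts <- gr1("chr1", c(1, 501, 1201), c(500, 1200, 3000))
  whole <- gr1("chr1", 1, 3000)
  partMeans <- meanSignal(st, parts)
  w <- GenomicRanges::width(parts)
  expect_equal(sum(partMeans * w) / sum(w), meanSignal(st, whole))
})

test_that("gene tables and expression matrices round-trip", {
  genes <- makeGenes("chr1", c(1000, 5000), c(3000, 9000), c("+", "-"),
                     exons = list(IRanges::IRanges(c(1000, 2500), c(1400, 3000)),
                                  IRanges::IRanges(5000, 9000)))
  f <- tempfile(fileext = ".tsv")
  writeGeneTable(genes, f)
  back <- readGeneTable(f)
  expect_equal(S4Vectors::mcols(back)$gene_id, c("g001", "g002"))
  expect_equal(S4Vectors::mcols(back)$tss, c(1000L, 9000L))
  expect_equal(IRanges::start(S4Vectors::mcols(back)$exons[[1]]),
               c(1000L, 2500L))

  m <- matrix(runif(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  fm <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(m, fm)
  expect_equal(readExpressionMatrix(fm), m, tolerance = 1e-12)
})

test_that("GMT parsing returns named gene sets", {
  f <- writeLinesTmp(c("setA\tdesc\tg1\tg2\tg3", "setB\t-\tg9"), ".gmt")
  sets <- readGmt(f)
  expect_named(sets, c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_error(readGmt(writeLinesTmp("bad\tonly-desc", ".gmt")), "line 1")
})
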