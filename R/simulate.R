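# run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldseed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldseed, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           sample.kind = "Rejection")
  force(expr)
}

#' Simulation configuration
#'
#' Parameters of the synthetic epigenome generator. The defaults describe
#' the study conditions every planted-truth check runs under: a small
#' 3 x 5 Mb genome, 400 genes, 200 background peaks, 5 planted rich domains
#' of 20-60 kb carrying 10x background ChIP signal, a 50% B-compartment
#' genome with domains placed in B with probability 0.9, domain-target
#' genes repressed by 2 log2 units in tumor samples, a 40 tumor / 20 normal
#' cohort, and a driver gene whose promoter methylation anti-correlates
#' with its expression at Spearman -0.25.
#'
#' @param seed integer RNG seed.
#' @param nChromosomes,chromLength genome shape (3 chromosomes of 5 Mb).
#' @param nGenes total gene models (400).
#' @param nBackgroundPeaks background (non-domain) peaks (200).
#' @param nPlantedDomains planted rich domains (5).
#' @param domainLengthMin,domainLengthMax planted domain length range in bp
#'   (20,000-60,000, uniform).
#' @param backgroundSignalMean,backgroundSignalSd per-bin background signal
#'   (Normal, clipped at 0).
#' @param domainSignalMultiplier ChIP multiplier over planted domains (10).
#' @param peakSignalMultiplier ChIP multiplier over background peaks (2).
#' @param bCompartmentFraction genome fraction in B compartment (0.5).
#' @param pDomainInB probability a planted domain is placed in a B bin (0.9).
#' @param repressionDelta log2 expression shift of domain-target genes in
#'   tumor samples (-2).
#' @param nTumor,nNormal cohort sizes (40/20).
#' @param driverMethylationRho target Spearman correlation between driver
#'   promoter methylation and driver expression across tumor samples (-0.25).
#' @param expressionNoiseSd per-sample expression noise, log2 scale (1).
#' @param baselineMean,baselineSd per-gene baseline expression, log2 scale.
#' @param targetGenesPerDomain genes planted with their TSS inside each
#'   domain (8).
#' @param trackBinSize ChIP/input track bin size in bp (200).
#' @param eigenBinSize eigenvector/compartment bin size in bp (25,000;
#'   compartment runs average ~50 kb on the scaled-down genome).
#' @return a validated list of class `SimulationConfig`.
#' @export
simConfig <- function(seed = 1L, nChromosomes = 3L, chromLength = 5e6,
                      nGenes = 400L, nBackgroundPeaks = 200L,
                      nPlantedDomains = 5L,
                      domainLengthMin = 20000L, domainLengthMax = 60000L,
                      backgroundSignalMean = 1, backgroundSignalSd = 0.25,
                      domainSignalMultiplier = 10, peakSignalMultiplier = 2,
                      bCompartmentFraction = 0.5, pDomainInB = 0.9,
                      repressionDelta = -2, nTumor = 40L, nNormal = 20L,
                      driverMethylationRho = -0.25, expressionNoiseSd = 1,
                      baselineMean = 6, baselineSd = 1,
                      targetGenesPerDomain = 8L,
                      trackBinSize = 200L, eigenBinSize = 25000L) {
  cfg <- list(seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
              chromLength = as.numeric(chromLength), nGenes = as.integer(nGenes),
              nBackgroundPeaks = as.integer(nBackgroundPeaks),
              nPlantedDomains = as.integer(nPlantedDomains),
              domainLengthMin = as.integer(domainLengthMin),
              domainLengthMax = as.integer(domainLengthMax),
              backgroundSignalMean = backgroundSignalMean,
              backgroundSignalSd = backgroundSignalSd,
              domainSignalMultiplier = domainSignalMultiplier,
              peakSignalMultiplier = peakSignalMultiplier,
              bCompartmentFraction = bCompartmentFraction,
              pDomainInB = pDomainInB, repressionDelta = repressionDelta,
              nTumor = as.integer(nTumor), nNormal = as.integer(nNormal),
              driverMethylationRho = driverMethylationRho,
              expressionNoiseSd = expressionNoiseSd,
              baselineMean = baselineMean, baselineSd = baselineSd,
              targetGenesPerDomain = as.integer(targetGenesPerDomain),
              trackBinSize = as.integer(trackBinSize),
              eigenBinSize = as.integer(eigenBinSize))
  counts <- c("nChromosomes", "chromLength", "nGenes", "nPlantedDomains",
              "nTumor", "nNormal", "targetGenesPerDomain", "trackBinSize",
              "eigenBinSize", "domainLengthMin", "domainLengthMax")
  for (f in counts) if (cfg[[f]] <= 0) stop(f, " must be positive",
                                            call. = FALSE)
  if (cfg$nBackgroundPeaks < 0) stop("nBackgroundPeaks must be >= 0",
                                     call. = FALSE)
  for (f in c("bCompartmentFraction", "pDomainInB"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must be in [0, 1]", call. = FALSE)
  if (cfg$domainSignalMultiplier <= 1)
    stop("domainSignalMultiplier must be > 1", call. = FALSE)
  if (cfg$domainLengthMax < cfg$domainLengthMin)
    stop("domainLengthMax < domainLengthMin", call. = FALSE)
  if (abs(cfg$driverMethylationRho) >= 1)
    stop("driverMethylationRho must lie in (-1, 1)", call. = FALSE)
  class(cfg) <- "SimulationConfig"
  cfg
}

# alternating A/B runs with geometric lengths whose means are weighted by
# bFrac, so the stationary B fraction is bFrac and per-chromosome fractions
# stay tight around it
.simCompartmentStates <- function(nBins, bFrac, meanBlock = 2) {
  meanB <- max(1, 2 * meanBlock * bFrac)
  meanA <- max(1, 2 * meanBlock * (1 - bFrac))
  lab <- if (stats::runif(1) < bFrac) "B" else "A"
  states <- character(0)
  while (length(states) < nBins) {
    m <- if (lab == "B") meanB else meanA
    states <- c(states, rep(lab, 1L + stats::rgeom(1L, 1 / m)))
    lab <- if (lab == "B") "A" else "B"
  }
  states[seq_len(nBins)]
}

# fraction of [s0, e0) lying in B-labelled bins of a state vector
.stateBFraction <- function(states, bs, s0, e0) {
  isB <- as.numeric(states == "B")
  pref <- c(0, cumsum(isB * bs))
  f <- function(x) {
    fb <- pmin(x %/% bs, length(isB))
    pref[fb + 1L] + ifelse(fb < length(isB), (x - fb * bs) * isB[fb + 1L], 0)
  }
  (f(e0) - f(s0)) / (e0 - s0)
}

.binIdx <- function(s0, e0, bs) (s0 %/% bs + 1L):((e0 - 1L) %/% bs + 1L)

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Writes, under `outDir`: `genes.tsv` (gene models), `peaks.narrowPeak`
#' (background peaks plus peaks tiling each planted domain with gaps well
#' under the 4 kb stitch window), `chip.bedGraph` (clipped-Normal
#' background multiplied over background peaks and, 10x, over planted
#' domains), `input.bedGraph` (background only), `eigen.bedGraph`
#' (compartment eigenvector with a random per-chromosome sign flip),
#' `expr.tsv` (log2-scale expression; domain-target genes shifted by
#' `repressionDelta` in tumor samples; the driver gene coupled to its
#' promoter methylation through a Gaussian copula), `meth.tsv` (promoter
#' methylation beta values), `labels.tsv` (tumor/normal) and `truth.json`
#' (the planted truth manifest). Identical config (including seed) gives
#' byte-identical files.
#'
#' @param config a [simConfig()] object.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with `truth` (the manifest as an R list) and
#'   `files` (named vector of paths).
#' @export
simulateDataset <- function(config = simConfig(), outDir) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  .withSeed(config$seed, {
    chromNames <- paste0("chr", seq_len(config$nChromosomes))
    chromLen <- stats::setNames(rep(config$chromLength, config$nChromosomes),
                                chromNames)
    ebs <- config$eigenBinSize
    nEbins <- as.integer(ceiling(config$chromLength / ebs))

    ## compartments (oriented truth) + raw eigen with arbitrary signs
    states <- lapply(chromNames, function(cn)
      .simCompartmentStates(nEbins, config$bCompartmentFraction))
    names(states) <- chromNames
    eigenOriented <- lapply(states, function(st) {
      mag <- abs(stats::rnorm(length(st), 0.8, 0.3)) + 0.05
      ifelse(st == "A", mag, -mag)
    })
    flips <- stats::setNames(stats::runif(config$nChromosomes) < 0.5,
                             chromNames)
    eigenRaw <- lapply(chromNames, function(cn)
      if (flips[[cn]]) -eigenOriented[[cn]] else eigenOriented[[cn]])
    names(eigenRaw) <- chromNames

    ## planted domains: midpoint in B with probability pDomainInB
    domChrom <- character(config$nPlantedDomains)
    domStart0 <- numeric(config$nPlantedDomains)
    domEnd0 <- numeric(config$nPlantedDomains)
    margin <- 1e5
    for (i in seq_len(config$nPlantedDomains)) {
      len <- round(stats::runif(1, config$domainLengthMin,
                                config$domainLengthMax))
      wantB <- stats::runif(1) < config$pDomainInB
      placed <- FALSE
      # B-assigned domains go fully inside a B run where one fits; the
      # fallback (and the non-B branch) constrain the midpoint bin only
      for (phase in if (wantB) c("full", "mid") else "mid") {
        for (try in seq_len(3000L)) {
          cn <- sample(chromNames, 1L)
          s0 <- floor(stats::runif(1, margin,
                                   config$chromLength - len - margin))
          if (phase == "full") {
            ok <- .stateBFraction(states[[cn]], ebs, s0, s0 + len) == 1
          } else {
            midBin <- as.integer(((s0 + len / 2) %/% ebs) + 1)
            ok <- (states[[cn]][midBin] == "B") == wantB
          }
          if (!ok) next
          prev <- which(domChrom == cn)
          if (length(prev) && any(s0 < domEnd0[prev] + 20000 &
                                  s0 + len > domStart0[prev] - 20000)) next
          domChrom[i] <- cn; domStart0[i] <- s0; domEnd0[i] <- s0 + len
          placed <- TRUE
          break
        }
        if (placed) break
      }
      if (!placed)
        stop("cannot place planted domain within chromosome bounds",
             call. = FALSE)
    }

    ## constituent peaks tiling each domain (gaps < 4 kb, >= 3 peaks)
    peakChrom <- character(0); peakS0 <- numeric(0); peakE0 <- numeric(0)
    peakKind <- character(0)
    for (i in seq_len(config$nPlantedDomains)) {
      pos <- domStart0[i]
      repeat {
        len <- round(stats::runif(1, 500, 1500))
        if (pos + len > domEnd0[i]) break
        peakChrom <- c(peakChrom, domChrom[i])
        peakS0 <- c(peakS0, pos); peakE0 <- c(peakE0, pos + len)
        peakKind <- c(peakKind, sprintf("domain_%d", i))
        pos <- pos + len + round(stats::runif(1, 500, 3000))
      }
      # the recoverable truth is the stitched span of the constituents
      sel <- peakKind == sprintf("domain_%d", i)
      domStart0[i] <- min(peakS0[sel]); domEnd0[i] <- max(peakE0[sel])
    }
    domGr <- GRanges(domChrom, IRanges(domStart0 + 1, domEnd0))

    nBg <- config$nBackgroundPeaks
    placedBg <- 0L
    while (placedBg < nBg) {
      cn <- sample(chromNames, 1L)
      len <- round(stats::runif(1, 200, 1000))
      s0 <- floor(stats::runif(1, 0, config$chromLength - len))
      near <- which(domChrom == cn)
      if (length(near) && any(s0 < domEnd0[near] + 5000 &
                              s0 + len > domStart0[near] - 5000)) next
      peakChrom <- c(peakChrom, cn)
      peakS0 <- c(peakS0, s0); peakE0 <- c(peakE0, s0 + len)
      peakKind <- c(peakKind, "background")
      placedBg <- placedBg + 1L
    }
    peaks <- GRanges(peakChrom, IRanges(peakS0 + 1, peakE0))
    mcols(peaks)$name <- sprintf("peak_%04d", seq_along(peaks))
    mcols(peaks)$score <- round(ifelse(peakKind == "background",
      config$peakSignalMultiplier, config$domainSignalMultiplier) +
      stats::rnorm(length(peaks), 0, 0.2), 3)
    mcols(peaks)$summit <- start(peaks) + width(peaks) %/% 2L

    ## signal tracks
    bs <- config$trackBinSize
    nTbins <- as.integer(ceiling(config$chromLength / bs))
    chipVals <- list(); inputVals <- list()
    for (cn in chromNames) {
      base <- pmax(stats::rnorm(nTbins, config$backgroundSignalMean,
                                config$backgroundSignalSd), 0)
      mult <- rep(1, nTbins)
      for (j in which(peakChrom == cn & peakKind == "background"))
        mult[.binIdx(peakS0[j], peakE0[j], bs)] <- config$peakSignalMultiplier
      for (i in which(domChrom == cn))
        mult[.binIdx(domStart0[i], domEnd0[i], bs)] <-
          config$domainSignalMultiplier
      chipVals[[cn]] <- base * mult
      inputVals[[cn]] <- pmax(stats::rnorm(nTbins, config$backgroundSignalMean,
                                           config$backgroundSignalSd), 0)
    }

    ## gene models: targets planted inside domains, the rest gene-rich in A
    nTargets <- config$targetGenesPerDomain * config$nPlantedDomains
    if (nTargets + 1L > config$nGenes)
      stop("nGenes too small for targetGenesPerDomain x nPlantedDomains",
           call. = FALSE)
    gChrom <- character(config$nGenes); gTss0 <- numeric(config$nGenes)
    for (g in seq_len(nTargets)) {
      i <- ((g - 1L) %% config$nPlantedDomains) + 1L
      gChrom[g] <- domChrom[i]
      gTss0[g] <- floor(stats::runif(1, domStart0[i] + 500,
                                     domEnd0[i] - 500))
    }
    for (g in (nTargets + 1L):config$nGenes) {
      cn <- sample(chromNames, 1L)
      # A-compartment bias ~3:1 so gene density orients the eigenvector
      w <- ifelse(states[[cn]] == "A", 3, 1)
      b <- sample.int(nEbins, 1L, prob = w)
      t0 <- floor(stats::runif(1, (b - 1L) * ebs, min(b * ebs,
                                                      config$chromLength)))
      gChrom[g] <- cn
      gTss0[g] <- min(max(t0, 60000), config$chromLength - 60000)
    }
    gStrand <- sample(c("+", "-"), config$nGenes, replace = TRUE)
    gLen <- round(stats::runif(config$nGenes, 2000, 30000))
    tss1 <- gTss0 + 1  # 1-based TSS position
    gs <- ifelse(gStrand == "+", tss1, pmax(tss1 - gLen + 1, 1))
    ge <- ifelse(gStrand == "+", pmin(tss1 + gLen - 1, config$chromLength),
                 tss1)
    exons <- IRangesList(lapply(seq_len(config$nGenes), function(g) {
      w <- ge[g] - gs[g] + 1
      k <- sample(2:6, 1L)
      b <- sort(sample.int(w - 2L, 2L * k - 2L)) + gs[g]
      bounds <- c(gs[g], b, ge[g])
      IRanges(bounds[seq(1L, 2L * k, 2L)], bounds[seq(2L, 2L * k, 2L)])
    }))
    genes <- GRanges(gChrom, IRanges(gs, ge), strand = gStrand)
    mcols(genes)$gene_id <- sprintf("G%04d", seq_len(config$nGenes))
    mcols(genes)$tss <- ifelse(gStrand == "-", ge, gs)
    mcols(genes)$exons <- exons
    targetGenes <- mcols(genes)$gene_id[seq_len(nTargets)]

    ## expression + methylation-coupled driver
    samples <- c(sprintf("Tumor%02d", seq_len(config$nTumor)),
                 sprintf("Normal%02d", seq_len(config$nNormal)))
    isTumor <- c(rep(TRUE, config$nTumor), rep(FALSE, config$nNormal))
    mu <- stats::rnorm(config$nGenes, config$baselineMean, config$baselineSd)
    expr <- matrix(stats::rnorm(config$nGenes * length(samples), 0,
                                config$expressionNoiseSd),
                   nrow = config$nGenes,
                   dimnames = list(mcols(genes)$gene_id, samples)) + mu
    expr[seq_len(nTargets), isTumor] <-
      expr[seq_len(nTargets), isTumor] + config$repressionDelta
    driverGene <- mcols(genes)$gene_id[nTargets + 1L]
    cop <- simulateMethylationExpression(config$nTumor,
                                         config$driverMethylationRho,
                                         seed = NULL)
    expr[driverGene, isTumor] <- config$baselineMean + 1.5 +
      config$expressionNoiseSd * cop$z_expr
    methDriverTumor <- cop$meth
    methDriverNormal <- pmin(pmax(stats::rnorm(config$nNormal, 0.75, 0.08),
                                  0), 1)
    expr <- pmax(expr, 0)
    extraMeth <- mcols(genes)$gene_id[(nTargets + 2L):(nTargets + 6L)]
    meth <- rbind(c(methDriverTumor, methDriverNormal),
                  matrix(stats::runif(5L * length(samples), 0.1, 0.9), 5L))
    dimnames(meth) <- list(c(driverGene, extraMeth), samples)
    meth <- round(meth, 4)

    ## write everything
    f <- function(x) file.path(outDir, x)
    writeGeneTable(genes, f("genes.tsv"))
    writeNarrowPeak(peaks, f("peaks.narrowPeak"))
    writeBedGraph(SignalTrack(chipVals, bs, "simulated-chip"),
                  f("chip.bedGraph"))
    writeBedGraph(SignalTrack(inputVals, bs, "simulated-input"),
                  f("input.bedGraph"))
    writeBedGraph(SignalTrack(eigenRaw, ebs, "eigenvector"),
                  f("eigen.bedGraph"))
    writeExpressionMatrix(round(expr, 4), f("expr.tsv"))
    writeExpressionMatrix(meth, f("meth.tsv"))
    fwrite(data.table(sample = samples,
                      label = ifelse(isTumor, "tumor", "normal")),
           f("labels.tsv"), sep = "\t", eol = "\n")
    truth <- list(
      seed = config$seed,
      chromosomes = as.list(chromLen),
      planted_domains = data.frame(chrom = domChrom, start = domStart0,
                                   end = domEnd0),
      target_genes = targetGenes,
      driver_gene = driverGene,
      eigen_flipped = as.list(flips),
      compartment_states = lapply(states, paste, collapse = ""),
      params = list(p_domain_in_B = config$pDomainInB,
                    repression_delta = config$repressionDelta,
                    driver_methylation_rho = config$driverMethylationRho,
                    domain_signal_multiplier = config$domainSignalMultiplier,
                    b_compartment_fraction = config$bCompartmentFraction))
    jsonlite::write_json(truth, f("truth.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
    files <- stats::setNames(
      f(c("genes.tsv", "peaks.narrowPeak", "chip.bedGraph", "input.bedGraph",
          "eigen.bedGraph", "expr.tsv", "meth.tsv", "labels.tsv",
          "truth.json")),
      c("genes", "peaks", "chip", "input", "eigen", "expr", "meth",
        "labels", "truth"))
    invisible(list(truth = truth, files = files))
  })
}

#' Expression matrix with planted repression (standalone)
#'
#' The expression component of the generator on its own, for calibration
#' studies: per-gene Normal baselines, Normal noise, and a log2 shift of
#' `repressionDelta` applied to the first `nTargets` genes in tumor
#' samples.
#'
#' @param nGenes,nTargets total and shifted gene counts.
#' @param nTumor,nNormal cohort sizes.
#' @param repressionDelta log2 shift in tumor samples.
#' @param baselineMean,baselineSd,noiseSd distribution parameters
#'   (log2 scale).
#' @param seed RNG seed (`NULL` = use the current RNG stream).
#' @return list with `expr` (matrix), `targetGenes`, `tumorSamples`,
#'   `normalSamples`.
#' @export
simulateExpressionMatrix <- function(nGenes = 400L, nTargets = 40L,
                                     nTumor = 40L, nNormal = 20L,
                                     repressionDelta = -2,
                                     baselineMean = 6, baselineSd = 1,
                                     noiseSd = 1, seed = 1L) {
  gen <- function() {
    samples <- c(sprintf("Tumor%02d", seq_len(nTumor)),
                 sprintf("Normal%02d", seq_len(nNormal)))
    isTumor <- c(rep(TRUE, nTumor), rep(FALSE, nNormal))
    genes <- sprintf("G%04d", seq_len(nGenes))
    mu <- stats::rnorm(nGenes, baselineMean, baselineSd)
    expr <- matrix(stats::rnorm(nGenes * length(samples), 0, noiseSd),
                   nrow = nGenes, dimnames = list(genes, samples)) + mu
    expr[seq_len(nTargets), isTumor] <-
      expr[seq_len(nTargets), isTumor] + repressionDelta
    list(expr = pmax(expr, 0), targetGenes = genes[seq_len(nTargets)],
         tumorSamples = samples[isTumor], normalSamples = samples[!isTumor])
  }
  if (is.null(seed)) gen() else .withSeed(seed, gen())
}

#' Methylation-expression pairs at a target Spearman correlation
#'
#' Draws `n` pairs from a Gaussian copula with the normal correlation
#' `r = 2 sin(pi * rho / 6)` chosen so the population Spearman correlation
#' equals `rho` exactly; the methylation margin is mapped to a beta-value
#' range (0.2-0.8) by the normal CDF and the expression margin is returned
#' as a standard-normal z (monotone transforms leave Spearman unchanged).
#'
#' @param n number of pairs.
#' @param rho target Spearman correlation, in (-1, 1).
#' @param seed RNG seed (`NULL` = use the current RNG stream).
#' @return data.frame with columns `meth` (beta values) and `z_expr`.
#' @export
simulateMethylationExpression <- function(n, rho = -0.25, seed = 1L) {
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  gen <- function() {
    r <- 2 * sin(pi * rho / 6)
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    data.frame(meth = 0.2 + 0.6 * stats::pnorm(z1), z_expr = z2)
  }
  if (is.null(seed)) gen() else .withSeed(seed, gen())
}

#' Two-class score cohort with a requested AUC
#'
#' Binormal model: positive scores ~ Normal(delta, sd), negative ~
#' Normal(0, sd), with `delta = sd * sqrt(2) * qnorm(targetAuc)` so the
#' theoretical AUC is exactly the requested value.
#'
#' @param nPos,nNeg class sizes (>= 5 each).
#' @param targetAuc requested AUC in `[0.5, 1)`.
#' @param sd common standard deviation.
#' @param seed RNG seed.
#' @return list with `scores`, `labels` (logical, `TRUE` = positive),
#'   `delta`.
#' @export
simulateRocCohort <- function(nPos, nNeg, targetAuc, sd = 1, seed = 1L) {
  if (nPos < 5L || nNeg < 5L) stop("class sizes must be >= 5", call. = FALSE)
  if (targetAuc < 0.5 || targetAuc >= 1)
    stop("requested AUC must lie in [0.5, 1)", call. = FALSE)
  .withSeed(seed, {
    delta <- sd * sqrt(2) * stats::qnorm(targetAuc)
    scores <- c(stats::rnorm(nPos, delta, sd), stats::rnorm(nNeg, 0, sd))
    list(scores = scores,
         labels = c(rep(TRUE, nPos), rep(FALSE, nNeg)),
         delta = delta)
  })
}

#' Match called domains to planted truth by Jaccard overlap
#'
#' A called domain matches a truth domain when their interval Jaccard index
#' (intersection / union, in bp) is at least `minJaccard`. Precision is the
#' fraction of called domains with a match, recall the fraction of truth
#' domains matched.
#'
#' @param called,truth `GRanges`.
#' @param minJaccard matching threshold (default 0.5).
#' @return list with `precision`, `recall`, `n_called`, `n_truth`,
#'   `matches` (data.frame of matched index pairs with their Jaccard).
#' @export
domainRecovery <- function(called, truth, minJaccard = 0.5) {
  if (length(truth) == 0L) stop("empty truth set", call. = FALSE)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(called, truth, ignore.strand = TRUE))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    inter <- pmin(end(called)[qi], end(truth)[si]) -
      pmax(start(called)[qi], start(truth)[si]) + 1
    uni <- width(called)[qi] + width(truth)[si] - inter
    jac <- inter / uni
    keep <- jac >= minJaccard
    matches <- data.frame(called = qi[keep], truth = si[keep],
                          jaccard = jac[keep])
  } else {
    matches <- data.frame(called = integer(), truth = integer(),
                          jaccard = numeric())
  }
  list(precision = if (length(called)) length(unique(matches$called)) /
         length(called) else NA_real_,
       recall = length(unique(matches$truth)) / length(truth),
       n_called = length(called), n_truth = length(truth),
       matches = matches)
}

#' Reconstruct the planted compartment track from a truth manifest
#'
#' @param truth the truth list from [simulateDataset()] (or parsed
#'   `truth.json`).
#' @param eigenBinSize bin size of the compartment states (default 100 kb).
#' @return a [CompartmentTrack-class] of the planted (oriented) states.
#' @export
truthCompartments <- function(truth, eigenBinSize = 25000L) {
  labels <- lapply(truth$compartment_states, function(s)
    strsplit(s, "", fixed = TRUE)[[1L]])
  eigen <- lapply(labels, function(l) ifelse(l == "A", 1, -1))
  new("CompartmentTrack", binSize = as.integer(eigenBinSize),
      labels = labels, eigen = eigen)
}
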