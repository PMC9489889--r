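#' Gene-density track at a given bin size
#'
#' Counts TSSs per fixed-width bin; used to orient the sign-arbitrary Hi-C
#' eigenvector (the A compartment is the gene-rich one).
#'
#' @param genes `GRanges` from [readGeneTable()].
#' @param binSize bin width in bp.
#' @param chromLengths optional named vector of chromosome lengths; defaults
#'   to the furthest gene end per chromosome.
#' @return A [SignalTrack-class] with units `"genes-per-bin"`.
#' @export
geneDensityTrack <- function(genes, binSize, chromLengths = NULL) {
  binSize <- as.integer(binSize)
  chrom <- as.character(seqnames(genes))
  if (is.null(chromLengths)) {
    chromLengths <- vapply(split(end(genes), chrom), max, numeric(1))
  }
  values <- lapply(names(chromLengths), function(cn) {
    nbin <- as.integer(ceiling(chromLengths[[cn]] / binSize))
    tssSel <- mcols(genes)$tss[chrom == cn]
    v <- numeric(nbin)
    if (length(tssSel)) {
      b <- tabulate(pmin((tssSel - 1L) %/% binSize + 1L, nbin), nbins = nbin)
      v <- as.numeric(b)
    }
    v
  })
  names(values) <- names(chromLengths)
  SignalTrack(values, binSize, units = "genes-per-bin")
}

#' Orient a Hi-C eigenvector by gene density
#'
#' The sign of the leading Hi-C eigenvector is arbitrary per chromosome.
#' This flips each chromosome's values so that positive correlates with
#' gene density, making positive = A (open, gene-rich) by convention. A
#' chromosome with zero-variance eigenvector is left unflipped with a
#' warning.
#'
#' @param eigenTrack [SignalTrack-class] of raw eigenvector values.
#' @param geneDensity [SignalTrack-class] on the same bins (see
#'   [geneDensityTrack()]); shorter vectors are zero-padded to match.
#' @return The oriented [SignalTrack-class].
#' @export
orientEigenvector <- function(eigenTrack, geneDensity) {
  if (binSize(eigenTrack) != binSize(geneDensity))
    stop("eigenvector and gene-density tracks must share bin_size",
         call. = FALSE)
  .checkChromNaming(trackChroms(eigenTrack), trackChroms(geneDensity),
                    "gene-density track")
  vals <- trackValues(eigenTrack)
  for (chrom in names(vals)) {
    ev <- vals[[chrom]]
    gd <- trackValues(geneDensity)[[chrom]]
    n <- length(ev)
    gd <- if (length(gd) >= n) gd[seq_len(n)] else c(gd, numeric(n - length(gd)))
    if (stats::sd(ev) == 0) {
      warning(sprintf("zero-variance eigenvector on %s: left unflipped",
                      chrom), call. = FALSE)
      next
    }
    if (stats::sd(gd) > 0 && stats::cor(ev, gd) < 0)
      vals[[chrom]] <- -ev
  }
  SignalTrack(vals, binSize(eigenTrack), trackUnits(eigenTrack))
}

#' Assign A/B compartment labels from an oriented eigenvector
#'
#' Positive bins become A, negative bins B; bins with value exactly 0 or
#' missing are left unassigned rather than forced into a class.
#'
#' @param orientedTrack [SignalTrack-class] of oriented eigenvector values.
#' @return A [CompartmentTrack-class].
#' @export
assignCompartments <- function(orientedTrack) {
  labels <- lapply(trackValues(orientedTrack), function(v) {
    lab <- rep("unassigned", length(v))
    lab[is.finite(v) & v > 0] <- "A"
    lab[is.finite(v) & v < 0] <- "B"
    lab
  })
  new("CompartmentTrack", binSize = binSize(orientedTrack),
      labels = labels, eigen = trackValues(orientedTrack))
}

# prefix-sum machinery: bp of label B in [0, x) for many x at once
.labelPrefix <- function(lab, binSize, label) {
  isB <- as.numeric(lab == label)
  pref <- c(0, cumsum(isB * binSize))
  function(x) {
    fb <- pmin(x %/% binSize, length(isB))
    partial <- ifelse(fb < length(isB), (x - fb * binSize) * isB[fb + 1L], 0)
    pref[fb + 1L] + partial
  }
}

.labelledBp <- function(compartments, chrom, starts0, ends0, label) {
  f <- .labelPrefix(compartmentLabels(compartments)[[chrom]],
                    binSize(compartments), label)
  f(ends0) - f(starts0)
}

#' Compartment overlap enrichment of a domain set
#'
#' Tests whether domains preferentially occupy one compartment class.
#' The observed statistic is the bp-weighted fraction of domain territory in
#' bins of the target label (default B, the repressive class). The null
#' places each domain uniformly at random on its own chromosome (length
#' preserved, no overlap constraint) and recomputes that fraction;
#' significance is the one-sided add-one empirical p-value
#' `(1 + #{null >= observed}) / (1 + nPermutations)`, which can never be 0.
#' Deterministic for a fixed `seed`.
#'
#' @param domainGr `GRanges` of domains (non-empty).
#' @param compartments a [CompartmentTrack-class].
#' @param nPermutations number of random placements (default 999).
#' @param seed integer RNG seed.
#' @param label compartment class tested for enrichment (default `"B"`).
#' @return list with `observed_fraction`, `null_mean`, `fold_enrichment`,
#'   `empirical_p`, `n_permutations`, `seed`, `label`, and the vector of
#'   null fractions (`null_fractions`).
#' @export
domainCompartmentEnrichment <- function(domainGr, compartments,
                                        nPermutations = 999L, seed = 1L,
                                        label = "B") {
  if (length(domainGr) == 0L)
    stop("domain set is empty", call. = FALSE)
  if (nPermutations < 1L) stop("nPermutations must be >= 1", call. = FALSE)
  .checkChromNaming(seqnames(domainGr), trackChroms(compartments),
                    "compartment track")
  chrom <- as.character(seqnames(domainGr))
  s0 <- start(domainGr) - 1L
  e0 <- end(domainGr)
  w <- width(domainGr)
  obs_bp <- sum(vapply(seq_along(domainGr), function(i)
    .labelledBp(compartments, chrom[i], s0[i], e0[i], label), numeric(1)))
  observed <- obs_bp / sum(w)

  chromExtent <- vapply(compartmentLabels(compartments), length,
                        integer(1)) * binSize(compartments)
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, envir = globalenv()))
  set.seed(as.integer(seed))
  nullBp <- numeric(nPermutations)
  perDomainNull <- matrix(0, nrow = nPermutations, ncol = length(domainGr))
  for (i in seq_along(domainGr)) {
    maxStart <- chromExtent[[chrom[i]]] - w[i]
    if (maxStart < 0)
      stop(sprintf("domain %d longer than chromosome %s", i, chrom[i]),
           call. = FALSE)
    rs <- floor(stats::runif(nPermutations, 0, maxStart + 1))
    perDomainNull[, i] <- .labelledBp(compartments, chrom[i], rs, rs + w[i],
                                      label)
  }
  nullFrac <- rowSums(perDomainNull) / sum(w)
  nullMean <- mean(nullFrac)
  list(observed_fraction = observed,
       null_mean = nullMean,
       fold_enrichment = if (nullMean > 0) observed / nullMean else Inf,
       empirical_p = (1 + sum(nullFrac >= observed)) / (1 + nPermutations),
       n_permutations = as.integer(nPermutations),
       seed = as.integer(seed),
       label = label,
       null_fractions = nullFrac)
}
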