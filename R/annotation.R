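#' Promoter windows around transcription start sites
#'
#' The promoter of a gene is `[tss - upstream, tss + downstream)` in the
#' direction of transcription: on `-` strand genes "upstream" extends toward
#' higher coordinates. The default window is +/- 2 kb, the promoter
#' definition used throughout the downstream methylation and annotation
#' analyses.
#'
#' @param genes `GRanges` from [readGeneTable()].
#' @param upstream,downstream window half-widths in bp (default 2000 each).
#' @return `GRanges` of promoter windows carrying `gene_id` and `tss`.
#' @export
promoterWindows <- function(genes, upstream = 2000L, downstream = 2000L) {
  if (upstream < 0L || downstream < 0L)
    stop("promoter windows must be >= 0", call. = FALSE)
  tss <- mcols(genes)$tss
  minus <- as.character(strand(genes)) == "-"
  s <- ifelse(minus, tss - downstream + 1L, tss - upstream)
  e <- ifelse(minus, tss + upstream, tss + downstream - 1L)
  out <- GRanges(seqnames(genes), IRanges(pmax(s, 1L), pmax(e, 1L)),
                 strand = strand(genes))
  mcols(out)$gene_id <- mcols(genes)$gene_id
  mcols(out)$tss <- tss
  out
}

# signed, strand-aware distance from an interval to a TSS: 0 when the
# interval contains the TSS, negative upstream, positive downstream.
.signedTssDistance <- function(s, e, tss, minus) {
  d <- numeric(length(s))
  left <- e < tss    # interval entirely before the TSS in genome coords
  right <- s > tss
  d[left] <- (e - tss)[left]
  d[right] <- (s - tss)[right]
  ifelse(minus, -d, d)
}

#' Annotate intervals against gene models
#'
#' Assigns each interval to one of four categories with the fixed priority
#' promoter > exon > intron > distal: overlap with any promoter window wins,
#' then exon overlap, then overlap with a gene body (intron), else distal.
#' The nearest gene is the one with the closest TSS (absolute distance; ties
#' broken by lexicographic `gene_id`); its signed strand-aware distance is
#' reported, negative meaning the interval lies upstream of the TSS.
#'
#' @param intervals `GRanges` to annotate.
#' @param genes `GRanges` from [readGeneTable()].
#' @param promoterUp,promoterDown promoter window in bp around the TSS
#'   (default 2000/2000).
#' @return `intervals` with added metadata columns `category` (factor:
#'   promoter, exon, intron, distal), `nearest_gene` (NA on chromosomes
#'   without genes) and `distance_to_tss`.
#' @export
annotateIntervals <- function(intervals, genes, promoterUp = 2000L,
                              promoterDown = 2000L) {
  if (length(intervals) == 0L) {
    mcols(intervals)$category <- factor(character(),
      levels = c("promoter", "exon", "intron", "distal"))
    mcols(intervals)$nearest_gene <- character()
    mcols(intervals)$distance_to_tss <- numeric()
    return(intervals)
  }
  prom <- promoterWindows(genes, promoterUp, promoterDown)
  exons <- unlist(mcols(genes)$exons)
  exonGr <- GRanges(rep(seqnames(genes), lengths(mcols(genes)$exons)), exons)
  cat_ <- rep("distal", length(intervals))
  # suppress the seqlevel-mismatch warning: intervals on chromosomes with
  # no genes are legitimately distal
  cnt <- function(q, s) suppressWarnings(
    GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE))
  hasProm <- cnt(intervals, prom) > 0L
  hasExon <- cnt(intervals, exonGr) > 0L
  hasBody <- cnt(intervals, genes) > 0L
  cat_[hasBody] <- "intron"
  cat_[hasExon] <- "exon"
  cat_[hasProm] <- "promoter"

  # nearest gene by TSS distance, per chromosome
  nearest_gene <- rep(NA_character_, length(intervals))
  dist_tss <- rep(NA_real_, length(intervals))
  geneChrom <- as.character(seqnames(genes))
  tss <- mcols(genes)$tss
  gid <- mcols(genes)$gene_id
  minus <- as.character(strand(genes)) == "-"
  ichrom <- as.character(seqnames(intervals))
  for (chrom in unique(ichrom)) {
    gsel <- which(geneChrom == chrom)
    isel <- which(ichrom == chrom)
    if (!length(gsel)) next
    # order candidate genes so that ties on |distance| resolve by gene_id
    gord <- gsel[order(gid[gsel])]
    s <- start(intervals)[isel]; e <- end(intervals)[isel]
    for (k in seq_along(isel)) {
      dAbs <- pmax(pmax(tss[gord] - e[k], s[k] - tss[gord]), 0L)
      j <- gord[which.min(dAbs)]
      nearest_gene[isel[k]] <- gid[j]
      dist_tss[isel[k]] <- .signedTssDistance(s[k], e[k], tss[j], minus[j])
    }
  }
  mcols(intervals)$category <- factor(cat_,
    levels = c("promoter", "exon", "intron", "distal"))
  mcols(intervals)$nearest_gene <- nearest_gene
  mcols(intervals)$distance_to_tss <- dist_tss
  intervals
}

#' Category composition of an interval set
#'
#' Counts and fractions of intervals per annotation category (promoter,
#' exon, intron, distal); fractions sum to 1.
#'
#' @inheritParams annotateIntervals
#' @return data.frame with columns `category`, `count`, `fraction`.
#' @export
annotationSummary <- function(intervals, genes, promoterUp = 2000L,
                              promoterDown = 2000L) {
  if (length(intervals) == 0L)
    stop("annotationSummary requires at least one interval", call. = FALSE)
  ann <- annotateIntervals(intervals, genes, promoterUp, promoterDown)
  tab <- table(mcols(ann)$category)
  data.frame(category = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / length(ann),
             stringsAsFactors = FALSE)
}
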