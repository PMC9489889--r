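#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom IRanges IRanges IRangesList
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand strand<-
#' @importFrom GenomeInfoDb seqlevels seqlevels<-
NULL

#' SignalTrack: fixed-bin per-chromosome numeric coverage
#'
#' A `SignalTrack` stores one numeric value per fixed-width genomic bin,
#' chromosome by chromosome. Bin `k` (1-based) covers the 0-based half-open
#' interval `[(k-1)*binSize, k*binSize)`. ChIP signal, input signal and Hi-C
#' compartment eigenvectors are all carried in this container; the `units`
#' label records what the numbers mean (e.g. `"fold-change-over-input"`,
#' `"eigenvector"`) but no unit conversion is ever attempted.
#'
#' @slot binSize integer(1), bin width in bp (> 0).
#' @slot values named list of numeric vectors, one per chromosome.
#' @slot units character(1) free-text label for the signal units.
#'
#' @examples
#' st <- SignalTrack(list(chr1 = c(1, 2, 3)), binSize = 100L)
#' meanSignal(st, GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200)))
#' @export
setClass("SignalTrack",
  representation(binSize = "integer", values = "list", units = "character"))

setValidity("SignalTrack", function(object) {
  msg <- character()
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize <= 0L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (length(object@values) > 0L) {
    if (is.null(names(object@values)) || any(!nzchar(names(object@values))))
      msg <- c(msg, "values must be a named list (chromosome names)")
    if (anyDuplicated(names(object@values)))
      msg <- c(msg, "duplicate chromosome names in values")
    if (!all(vapply(object@values, is.numeric, logical(1))))
      msg <- c(msg, "all per-chromosome value vectors must be numeric")
  }
  if (length(object@units) != 1L)
    msg <- c(msg, "units must be a single character string")
  if (length(msg)) msg else TRUE
})

#' Construct a SignalTrack
#'
#' @param values named list of per-chromosome numeric vectors (one value per
#'   bin, first bin starting at position 0).
#' @param binSize bin width in bp.
#' @param units label describing the signal units.
#' @return A [SignalTrack-class] object.
#' @export
SignalTrack <- function(values, binSize = 50L, units = "signal") {
  new("SignalTrack", binSize = as.integer(binSize),
      values = lapply(values, as.numeric), units = as.character(units))
}

#' CompartmentTrack: per-bin A/B chromatin compartment labels
#'
#' Derived from an oriented Hi-C eigenvector track: bins with a positive
#' eigenvector are labelled `"A"` (open, gene-rich), negative bins `"B"`
#' (closed, repressive), and bins with value exactly 0 or missing are
#' `"unassigned"`. The source eigenvector values are retained.
#'
#' @slot binSize integer(1), bin width in bp.
#' @slot labels named list of character vectors over {A, B, unassigned}.
#' @slot eigen named list of the oriented eigenvector values.
#' @export
setClass("CompartmentTrack",
  representation(binSize = "integer", labels = "list", eigen = "list"))

setValidity("CompartmentTrack", function(object) {
  msg <- character()
  if (length(object@binSize) != 1L || object@binSize <= 0L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (!identical(names(object@labels), names(object@eigen)))
    msg <- c(msg, "labels and eigen must cover the same chromosomes")
  for (chrom in names(object@labels)) {
    lab <- object@labels[[chrom]]
    ev <- object@eigen[[chrom]]
    if (length(lab) != length(ev)) {
      msg <- c(msg, sprintf("%s: label/eigen length mismatch", chrom))
      next
    }
    if (!all(lab %in% c("A", "B", "unassigned")))
      msg <- c(msg, sprintf("%s: labels outside {A, B, unassigned}", chrom))
    bad <- (lab == "A" & !(is.finite(ev) & ev > 0)) |
           (lab == "B" & !(is.finite(ev) & ev < 0)) |
           (lab == "unassigned" & is.finite(ev) & ev != 0)
    if (any(bad))
      msg <- c(msg, sprintf("%s: label inconsistent with eigenvector sign",
                            chrom))
  }
  if (length(msg)) msg else TRUE
})

#' RichDomainSet: stitched, scored and rank-ordered regions
#'
#' The result of the rich-domain caller. Domains are held as a [GRanges]
#' sorted by descending score, with metadata columns `score`
#' (background-subtracted signal), `rank` (1 = highest score),
#' `n_constituents` and `is_rich`. The constituent peaks of each stitched
#' region are kept as a parallel [GRangesList], and the tangent-line cutoff
#' diagnostics as a list (see [findCutoff()]).
#'
#' @slot domains GRanges of stitched regions, descending score order.
#' @slot constituents GRangesList, parallel to `domains`.
#' @slot cutoff list with elements `cutoff_value`, `cutoff_index`,
#'   `points_below` (NULL before [findCutoff()] has run).
#' @export
setClass("RichDomainSet",
  representation(domains = "GRanges", constituents = "GRangesList",
                 cutoff = "list"))

setValidity("RichDomainSet", function(object) {
  msg <- character()
  n <- length(object@domains)
  if (length(object@constituents) != n)
    msg <- c(msg, "constituents must parallel domains")
  mc <- mcols(object@domains)
  need <- c("score", "rank", "n_constituents", "is_rich")
  if (!all(need %in% colnames(mc)))
    msg <- c(msg, paste("domains must carry metadata columns:",
                        paste(need, collapse = ", ")))
  else if (n > 0L) {
    if (!identical(sort(as.integer(mc$rank)), seq_len(n)))
      msg <- c(msg, "ranks must be a permutation of 1..N")
    if (any(!is.na(mc$score) & mc$score < 0))
      msg <- c(msg, "scores must be non-negative after clamping")
  }
  if (length(msg)) msg else TRUE
})
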