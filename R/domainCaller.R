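#' Stitch peaks into clustered regions
#'
#' Merges, per chromosome, consecutive peaks whose gap (next start minus
#' previous end) is at most `stitchWindow` bp, the clustering step of the
#' super-enhancer (ROSE) algorithm. The default 4 kb window is the one used
#' for Polycomb/EZH2 rich-domain definition. Each stitched region spans from
#' the first constituent's start to the last constituent's end; strand is
#' dropped.
#'
#' @param peaks `GRanges` of peaks (may be unsorted; strand ignored).
#' @param stitchWindow maximum gap in bp for two peaks to be merged
#'   (default 4000).
#' @return A [RichDomainSet-class] with unset scores (`NA`), ranks in
#'   genomic order, and `is_rich` all `FALSE`; `constituents()` holds the
#'   member peaks of each region.
#' @export
stitchPeaks <- function(peaks, stitchWindow = 4000L) {
  stitchWindow <- as.integer(stitchWindow)
  if (is.na(stitchWindow) || stitchWindow < 0L)
    stop("stitchWindow must be >= 0", call. = FALSE)
  if (length(peaks) && any(width(peaks) <= 0L))
    stop("peak with start >= end", call. = FALSE)
  strand(peaks) <- "*"
  peaks <- GenomicRanges::sort(.canonicalSeqlevels(peaks),
                               ignore.strand = TRUE)
  # gap <= window  <=>  reduce with min.gapwidth = window + 1
  merged <- GenomicRanges::reduce(peaks, min.gapwidth = stitchWindow + 1L,
                                  ignore.strand = TRUE, with.revmap = TRUE)
  revmap <- mcols(merged)$revmap
  mcols(merged)$revmap <- NULL
  cons <- GRangesList(lapply(seq_along(merged), function(i)
    peaks[revmap[[i]]]))
  mcols(merged)$score <- rep(NA_real_, length(merged))
  mcols(merged)$rank <- seq_len(length(merged))
  mcols(merged)$n_constituents <- lengths(revmap)
  mcols(merged)$is_rich <- rep(FALSE, length(merged))
  new("RichDomainSet", domains = merged, constituents = cons,
      cutoff = list())
}

#' Score stitched regions against input
#'
#' ROSE-style background-subtracted signal: in `whole_span` mode the score
#' of a region is (mean ChIP density minus mean input density over the full
#' stitched span) times the span length; in `constituents` mode the same
#' quantity is summed over the constituent peaks only, ignoring the stitched
#' gaps. Negative scores are clamped to 0 by default, since the downstream
#' tangent-line cutoff assumes a non-negative ascending curve.
#'
#' @param regions a [RichDomainSet-class] from [stitchPeaks()].
#' @param chipTrack,inputTrack [SignalTrack-class] objects sharing bin size
#'   and chromosome naming.
#' @param scoreMode `"whole_span"` (default) or `"constituents"`.
#' @param clampNegative clamp negative scores to 0 (default `TRUE`).
#' @return The region set with the `score` metadata column filled in.
#' @export
scoreRegions <- function(regions, chipTrack, inputTrack,
                         scoreMode = c("whole_span", "constituents"),
                         clampNegative = TRUE) {
  scoreMode <- match.arg(scoreMode)
  if (binSize(chipTrack) != binSize(inputTrack))
    stop("chip and input tracks must share bin_size", call. = FALSE)
  dom <- regions@domains
  if (length(dom) == 0L) return(regions)
  .checkChromNaming(seqnames(dom), trackChroms(chipTrack), "chip track")
  .checkChromNaming(seqnames(dom), trackChroms(inputTrack), "input track")
  score <- if (scoreMode == "whole_span") {
    (meanSignal(chipTrack, dom) - meanSignal(inputTrack, dom)) * width(dom)
  } else {
    vapply(seq_along(dom), function(i) {
      p <- regions@constituents[[i]]
      sum((meanSignal(chipTrack, p) - meanSignal(inputTrack, p)) * width(p))
    }, numeric(1))
  }
  if (clampNegative) score <- pmax(score, 0)
  mcols(regions@domains)$score <- score
  regions
}

#' Tangent-line cutoff on the rank-ordered signal curve
#'
#' The super-enhancer elbow criterion: sort scores ascending (negatives
#' clamped to 0), consider the line of slope `(max - min) / N` through each
#' point of the curve, and pick the point leaving the fewest other points
#' strictly below its line (ties broken toward the smallest index, i.e. the
#' more conservative cutoff). Scores strictly above the cutoff value are
#' called rich.
#'
#' @param scores numeric vector of region scores, length >= 2, at least one
#'   finite value pair required.
#' @return list with `cutoff_value` (the sorted score at the optimum),
#'   `cutoff_index` (position in the ascending-sorted vector) and
#'   `points_below` (count at the optimum).
#' @export
findCutoff <- function(scores) {
  scores <- as.numeric(scores)
  n <- length(scores)
  if (n < 2L) stop("need at least 2 scores for the tangent-line cutoff",
                   call. = FALSE)
  if (all(is.na(scores))) stop("all scores are NA", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  y <- sort(pmax(scores, 0))
  m <- (max(y) - min(y)) / n
  idx <- seq_len(n)
  # line through (i, y_i): count j with y_j < y_i + m * (j - i)
  lineVals <- outer(y, idx, function(yi, j) yi) +
    m * outer(idx, idx, function(i, j) j - i)
  below <- colSums(matrix(y, n, n) < t(lineVals))
  opt <- which.min(below)  # which.min takes the first (smallest index) tie
  list(cutoff_value = y[opt], cutoff_index = opt,
       points_below = as.integer(below[opt]))
}

#' Call rich domains from peaks and signal tracks
#'
#' The full caller: stitch peaks (gap <= `stitchWindow`), score every
#' stitched region against input, find the tangent-line cutoff on the
#' rank-ordered scores, and flag regions scoring strictly above the cutoff
#' as rich. Output is sorted by descending score with `rank` 1 = highest.
#' A single stitched region cannot support a rank-ordered cutoff; it is
#' returned flagged not-rich with a warning.
#'
#' @inheritParams scoreRegions
#' @param peaks `GRanges` of peaks.
#' @param stitchWindow stitch gap in bp (default 4000).
#' @return A [RichDomainSet-class], ranked and flagged; `cutoffInfo()`
#'   exposes the cutoff diagnostics.
#' @export
callRichDomains <- function(peaks, chipTrack, inputTrack,
                            stitchWindow = 4000L,
                            scoreMode = c("whole_span", "constituents"),
                            clampNegative = TRUE) {
  scoreMode <- match.arg(scoreMode)
  regions <- stitchPeaks(peaks, stitchWindow)
  n <- length(regions@domains)
  if (n == 0L) return(regions)
  regions <- scoreRegions(regions, chipTrack, inputTrack,
                          scoreMode = scoreMode,
                          clampNegative = clampNegative)
  if (n == 1L) {
    warning("single stitched region: no rank-ordered cutoff possible; ",
            "flagged not-rich", call. = FALSE)
    mcols(regions@domains)$rank <- 1L
    return(regions)
  }
  score <- mcols(regions@domains)$score
  cut <- findCutoff(score)
  ord <- order(-score, as.character(seqnames(regions@domains)),
               start(regions@domains))
  regions@domains <- regions@domains[ord]
  regions@constituents <- regions@constituents[ord]
  mcols(regions@domains)$rank <- seq_len(n)
  mcols(regions@domains)$is_rich <- mcols(regions@domains)$score >
    cut$cutoff_value
  regions@cutoff <- cut
  regions
}

#' @rdname richdom-accessors
#' @export
setMethod("domains", "RichDomainSet", function(x) x@domains)

#' @rdname richdom-accessors
#' @export
setMethod("richDomains", "RichDomainSet",
          function(x) x@domains[mcols(x@domains)$is_rich])

#' @rdname richdom-accessors
#' @export
setMethod("constituents", "RichDomainSet", function(x) x@constituents)

#' @rdname richdom-accessors
#' @export
setMethod("cutoffInfo", "RichDomainSet", function(x) x@cutoff)

setMethod("show", "RichDomainSet", function(object) {
  n <- length(object@domains)
  nr <- sum(mcols(object@domains)$is_rich)
  cat(sprintf("RichDomainSet: %d stitched region(s), %d rich\n", n, nr))
  if (length(object@cutoff))
    cat(sprintf("  tangent-line cutoff: %.4g (index %d, %d points below)\n",
                object@cutoff$cutoff_value, object@cutoff$cutoff_index,
                object@cutoff$points_below))
  if (n) {
    top <- utils::head(object@domains, 3L)
    for (i in seq_along(top))
      cat(sprintf("  #%d %s:%d-%d score %.4g (%d peaks)%s\n",
                  mcols(top)$rank[i], as.character(seqnames(top))[i],
                  start(top)[i], end(top)[i], mcols(top)$score[i],
                  mcols(top)$n_constituents[i],
                  if (mcols(top)$is_rich[i]) " [rich]" else ""))
  }
})

#' Write a domain set as BED6+3 with a JSON summary sidecar
#'
#' Columns: chrom, start, end, name (rank), score (domain score), strand,
#' then n_constituents, is_rich (0/1). The cutoff diagnostics are written
#' next to the BED file as `<path>.summary.json`.
#'
#' @param x a [RichDomainSet-class].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
writeDomainBed <- function(x, path) {
  dom <- domains(x)
  mcols(dom)$name <- as.character(mcols(dom)$rank)
  mcols(dom)$is_rich <- as.integer(mcols(dom)$is_rich)
  writeBed(dom, path, extraCols = c("n_constituents", "is_rich"))
  summ <- c(x@cutoff,
            list(n_regions = length(dom),
                 n_rich = sum(mcols(dom)$is_rich == 1L)))
  jsonlite::write_json(summ, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
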