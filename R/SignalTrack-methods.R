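#' @rdname richdom-accessors
#' @export
setMethod("binSize", "SignalTrack", function(x) x@binSize)

#' @rdname richdom-accessors
#' @export
setMethod("trackValues", "SignalTrack", function(x) x@values)

#' @rdname richdom-accessors
#' @export
setMethod("trackChroms", "SignalTrack", function(x) names(x@values))

#' @rdname richdom-accessors
#' @export
setMethod("trackUnits", "SignalTrack", function(x) x@units)

#' @rdname richdom-accessors
#' @export
setMethod("binSize", "CompartmentTrack", function(x) x@binSize)

#' @rdname richdom-accessors
#' @export
setMethod("trackChroms", "CompartmentTrack", function(x) names(x@labels))

#' @rdname richdom-accessors
#' @export
setMethod("compartmentLabels", "CompartmentTrack", function(x) x@labels)

setMethod("show", "SignalTrack", function(object) {
  nb <- sum(vapply(object@values, length, integer(1)))
  cat(sprintf("SignalTrack: %d chromosome(s), %d bins of %d bp [%s]\n",
              length(object@values), nb, object@binSize, object@units))
  for (chrom in utils::head(names(object@values), 5L)) {
    v <- object@values[[chrom]]
    cat(sprintf("  %s: %d bins, mean %.4g\n", chrom, length(v),
                mean(v, na.rm = TRUE)))
  }
  if (length(object@values) > 5L)
    cat(sprintf("  ... and %d more\n", length(object@values) - 5L))
})

setMethod("show", "CompartmentTrack", function(object) {
  lab <- unlist(object@labels, use.names = FALSE)
  cat(sprintf(
    "CompartmentTrack: %d chromosome(s), %d bins of %d bp (A: %d, B: %d, unassigned: %d)\n",
    length(object@labels), length(lab), object@binSize,
    sum(lab == "A"), sum(lab == "B"), sum(lab == "unassigned")))
})

# Chromosome-name mismatches are hard errors: silently "fixing" chr1 vs 1
# style differences hides real data errors.
.checkChromNaming <- function(query, trackChromNames, what = "track") {
  q <- unique(as.character(query))
  missing <- setdiff(q, trackChromNames)
  if (length(missing)) {
    stop(sprintf(
      "chromosome(s) %s absent from %s (%s has: %s); no name normalization is attempted",
      paste(missing, collapse = ", "), what, what,
      paste(utils::head(trackChromNames, 5L), collapse = ", ")),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname meanSignal
#' @export
setMethod("meanSignal", signature("SignalTrack", "GRanges"),
  function(track, interval) {
    if (length(interval) == 0L) return(numeric(0))
    if (any(width(interval) == 0L))
      stop("zero-length interval in meanSignal query", call. = FALSE)
    .checkChromNaming(seqnames(interval), trackChroms(track))
    bs <- track@binSize
    out <- numeric(length(interval))
    clipped <- FALSE
    chrs <- as.character(seqnames(interval))
    s0 <- start(interval) - 1L  # 0-based inclusive
    e0 <- end(interval)        # 0-based exclusive
    for (i in seq_along(out)) {
      v <- track@values[[chrs[i]]]
      extent <- length(v) * bs
      s <- s0[i]; e <- e0[i]
      if (e > extent || s < 0L) {
        clipped <- TRUE
        s <- max(s, 0L); e <- min(e, extent)
      }
      if (s >= e) { out[i] <- NA_real_; next }
      b1 <- s %/% bs + 1L
      b2 <- (e - 1L) %/% bs + 1L
      idx <- b1:b2
      ov <- pmin(e, idx * bs) - pmax(s, (idx - 1L) * bs)
      out[i] <- sum(v[idx] * ov) / sum(ov)
    }
    if (clipped)
      warning("interval(s) extend beyond covered track extent; clipped",
              call. = FALSE)
    out
  })
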