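#' Accessors for track and domain-set objects
#'
#' `binSize()` returns the bin width in bp; `trackValues()` the named list of
#' per-chromosome numeric vectors; `trackChroms()` the chromosome names;
#' `trackUnits()` the units label. `domains()` returns the stitched regions
#' of a [RichDomainSet-class] as a `GRanges`, `richDomains()` only the
#' regions flagged rich, `constituents()` the per-region constituent peaks,
#' and `cutoffInfo()` the tangent-line cutoff diagnostics.
#' `compartmentLabels()` returns the per-bin A/B labels of a
#' [CompartmentTrack-class].
#'
#' @param x a SignalTrack, CompartmentTrack or RichDomainSet object.
#' @return See the individual accessor descriptions.
#' @name richdom-accessors
NULL

#' @rdname richdom-accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname richdom-accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname richdom-accessors
#' @export
setGeneric("trackChroms", function(x) standardGeneric("trackChroms"))

#' @rdname richdom-accessors
#' @export
setGeneric("trackUnits", function(x) standardGeneric("trackUnits"))

#' @rdname richdom-accessors
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname richdom-accessors
#' @export
setGeneric("richDomains", function(x) standardGeneric("richDomains"))

#' @rdname richdom-accessors
#' @export
setGeneric("constituents", function(x) standardGeneric("constituents"))

#' @rdname richdom-accessors
#' @export
setGeneric("cutoffInfo", function(x) standardGeneric("cutoffInfo"))

#' @rdname richdom-accessors
#' @export
setGeneric("compartmentLabels", function(x) standardGeneric("compartmentLabels"))

#' Mean per-bp signal over genomic intervals
#'
#' Length-weighted mean of the bins a query interval overlaps. Parts of a
#' query extending beyond the covered extent of the track are clipped with a
#' warning; a zero-width query is an error.
#'
#' @param track a [SignalTrack-class].
#' @param interval a `GRanges` of query intervals.
#' @return numeric vector, one mean per query interval.
#' @export
setGeneric("meanSignal", function(track, interval) standardGeneric("meanSignal"))
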