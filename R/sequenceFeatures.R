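#' @importFrom Biostrings DNAString letterFrequency matchPattern
NULL

.as_dna <- function(seq) {
  if (is(seq, "DNAString")) return(seq)
  DNAString(toupper(as.character(seq)))
}

#' G+C percentage of a sequence
#'
#' `100 * (C + G) / (A + C + G + T)`; `N` bases are excluded from both the
#' numerator and the denominator.
#'
#' @param seq a `DNAString` or character string over `{A,C,G,T,N}`.
#' @return percentage in `[0, 100]`.
#' @export
gcPercent <- function(seq) {
  d <- .as_dna(seq)
  f <- letterFrequency(d, c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) stop("sequence has no non-N bases", call. = FALSE)
  100 * (f[["C"]] + f[["G"]]) / tot
}

#' Observed/expected CpG dinucleotide ratio
#'
#' `Obs` = number of `CG` dinucleotides; `Exp` = (C count x G count) /
#' length (non-N bases); the classical CpG island statistic. When `Exp` is
#' 0 (no C or no G) the ratio is defined as 0.
#'
#' @inheritParams gcPercent
#' @return the Obs/Exp ratio (>= 0).
#' @export
obsExpCpG <- function(seq) {
  d <- .as_dna(seq)
  if (length(d) == 0L) stop("empty sequence", call. = FALSE)
  f <- letterFrequency(d, c("A", "C", "G", "T"))
  len <- sum(f)
  if (len == 0) stop("sequence has no non-N bases", call. = FALSE)
  obs <- length(matchPattern("CG", d))
  expd <- f[["C"]] * f[["G"]] / len
  if (expd == 0) 0 else obs / expd
}

# sliding-window counts via cumulative sums; ws = window start positions
.windowCounts <- function(isX, windowLength) {
  cs <- c(0, cumsum(isX))
  n <- length(isX) - windowLength + 1L
  cs[seq_len(n) + windowLength] - cs[seq_len(n)]
}

#' Sliding-window CpG island scan
#'
#' MethPrimer-style prediction: slide a window of `windowLength` bp by
#' `step` along the sequence; a window passes when its GC percentage and
#' Obs/Exp CpG ratio both strictly exceed their thresholds (computed over
#' non-N bases; windows with more than `maxNFraction` N fail outright).
#' Overlapping or book-ended passing windows are merged by union, merged
#' runs shorter than `minIslandLength` are dropped, and GC / Obs-Exp are
#' recomputed over each merged island for reporting.
#'
#' @inheritParams gcPercent
#' @param minIslandLength minimum merged island length in bp (default 200).
#' @param windowLength scan window in bp (default = `minIslandLength`).
#' @param step window shift in bp (default 1).
#' @param minGcPercent GC threshold, strict (default 50).
#' @param minObsExp Obs/Exp threshold, strict (default 0.6).
#' @param maxNFraction maximum tolerated fraction of N per window
#'   (default 0.1).
#' @return data.frame with one row per island: `start`, `end` (1-based
#'   closed within the scanned sequence), `length`, `gc_percent`,
#'   `obs_exp`. Zero rows (with a warning) when the sequence is shorter
#'   than the window.
#' @export
cpgIslandScan <- function(seq, minIslandLength = 200L,
                          windowLength = minIslandLength, step = 1L,
                          minGcPercent = 50, minObsExp = 0.6,
                          maxNFraction = 0.1) {
  if (minIslandLength <= 0L || windowLength <= 0L || step < 1L)
    stop("island length, window length and step must be positive",
         call. = FALSE)
  d <- .as_dna(seq)
  L <- length(d)
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      gc_percent = numeric(), obs_exp = numeric())
  if (L < windowLength) {
    warning("sequence shorter than scan window: no islands reported",
            call. = FALSE)
    return(empty)
  }
  chars <- strsplit(as.character(d), "", fixed = TRUE)[[1L]]
  isC <- chars == "C"; isG <- chars == "G"; isN <- !(chars %in% c("A", "C", "G", "T"))
  nC <- .windowCounts(isC, windowLength)
  nG <- .windowCounts(isG, windowLength)
  nN <- .windowCounts(isN, windowLength)
  nACGT <- windowLength - nN
  # CG dinucleotide starting at i is inside window [s, s+W) iff i <= s+W-2
  isCG <- c(isC[-L] & isG[-1L], FALSE)
  nCG <- .windowCounts(as.numeric(isCG), windowLength) -
    isCG[seq_along(nC) + windowLength - 1L]
  starts <- seq(1L, L - windowLength + 1L, by = step)
  gc <- ifelse(nACGT[starts] > 0, 100 * (nC + nG)[starts] / nACGT[starts], 0)
  expd <- ifelse(nACGT[starts] > 0, (nC * nG)[starts] / nACGT[starts], 0)
  oe <- ifelse(expd > 0, nCG[starts] / expd, 0)
  pass <- gc > minGcPercent & oe > minObsExp &
    (nN[starts] / windowLength) <= maxNFraction
  if (!any(pass)) return(empty)
  win <- IRanges(starts[pass], width = windowLength)
  merged <- IRanges::reduce(win)  # union of overlapping/adjacent windows
  merged <- merged[IRanges::width(merged) >= minIslandLength]
  if (!length(merged)) return(empty)
  res <- lapply(seq_along(merged), function(i) {
    sub <- d[IRanges::start(merged)[i]:IRanges::end(merged)[i]]
    data.frame(start = IRanges::start(merged)[i],
               end = IRanges::end(merged)[i],
               length = IRanges::width(merged)[i],
               gc_percent = gcPercent(sub),
               obs_exp = obsExpCpG(sub))
  })
  do.call(rbind, res)
}

#' Scan FASTA records for CpG islands
#'
#' Applies [cpgIslandScan()] to every record of a FASTA file (e.g. promoter
#' sequences) and reports islands in record-relative coordinates.
#'
#' @param path FASTA file path.
#' @param ... passed to [cpgIslandScan()].
#' @return data.frame with a leading `seqname` column.
#' @export
cpgIslandScanFasta <- function(path, ...) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    df <- cpgIslandScan(seqs[[i]], ...)
    if (nrow(df)) cbind(seqname = names(seqs)[i], df, stringsAsFactors = FALSE)
    else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), length = integer(),
                      gc_percent = numeric(), obs_exp = numeric()))
  do.call(rbind, out)
}
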