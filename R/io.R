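#' @importFrom data.table fread fwrite data.table setorder :=
NULL

# All on-disk interval formats (BED, narrowPeak, bedGraph, gene table) are
# 0-based half-open; GRanges in memory are 1-based closed. Conversion happens
# here and only here.

# lexicographic chromosome order so sorted output is reproducible
# regardless of record order in the input
.canonicalSeqlevels <- function(gr) {
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  gr
}

.bed_to_granges <- function(chrom, start0, end0, strand = NULL) {
  GRanges(chrom, IRanges(start0 + 1L, end0),
          strand = if (is.null(strand)) "*" else ifelse(strand == ".", "*", strand))
}

.granges_strand_chr <- function(gr) {
  s <- as.character(strand(gr))
  ifelse(s == "*", ".", s)
}

.parse_int <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.integer(x))
  if (any(is.na(v)))
    stop(sprintf("%s: line %d: cannot parse %s '%s'",
                 path, lineno[which(is.na(v))[1L]], what,
                 x[which(is.na(v))[1L]]), call. = FALSE)
  v
}

#' Read a BED file
#'
#' Parses BED3/BED6 with the standard convention: 0-based half-open
#' coordinates, strand from column 6 when present (`.` mapping to `*`).
#'
#' @param path path to a tab-separated BED file.
#' @return `GRanges`; BED name and score columns, when present, become
#'   metadata columns `name` and `score`.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                 !startsWith(lines, "#")]
  if (!length(lines)) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("%s: line %d: expected >= 3 tab-separated columns",
                 path, which(nf < 3L)[1L]), call. = FALSE)
  lineno <- seq_along(lines)
  chrom <- vapply(fields, `[`, character(1), 1L)
  s0 <- .parse_int(vapply(fields, `[`, character(1), 2L), path, lineno, "start")
  e0 <- .parse_int(vapply(fields, `[`, character(1), 3L), path, lineno, "end")
  bad <- s0 >= e0
  if (any(bad))
    stop(sprintf("%s: line %d: start (%d) >= end (%d)", path,
                 which(bad)[1L], s0[which(bad)[1L]], e0[which(bad)[1L]]),
         call. = FALSE)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f)
    if (length(f) >= 6L) f[6L] else ".", character(1)), ".")
  gr <- .bed_to_granges(chrom, s0, e0, strand)
  if (all(nf >= 4L)) mcols(gr)$name <- vapply(fields, `[`, character(1), 4L)
  if (all(nf >= 5L))
    mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[`, character(1), 5L)))
  gr
}

#' Write intervals as BED
#'
#' Emits sorted, tab-separated, newline-terminated BED records (BED6 when
#' name/score metadata are present, BED3 otherwise), converting back to
#' 0-based half-open coordinates.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @param extraCols optional character vector of metadata column names to
#'   append after the first six columns.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path, extraCols = NULL) {
  gr <- GenomicRanges::sort(.canonicalSeqlevels(gr), ignore.strand = TRUE)
  dt <- data.table(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  mc <- mcols(gr)
  if (!is.null(mc$name) || !is.null(mc$score) || length(extraCols)) {
    dt[, c("name", "score", "strand") := list(
      if (is.null(mc$name)) "." else as.character(mc$name),
      if (is.null(mc$score)) 0 else mc$score,
      .granges_strand_chr(gr))]
  }
  for (col in extraCols) dt[[col]] <- mc[[col]]
  fwrite(dt, path, sep = "\t", col.names = FALSE, eol = "\n", scipen = 50)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#'
#' Ten tab-separated columns; column 7 (signalValue) is retained as `score`
#' and column 10 is the peak summit offset from the region start, with -1
#' meaning "no summit" (`summit` metadata column becomes `NA`).
#'
#' @param path path to a narrowPeak file.
#' @return `GRanges` with metadata columns `name`, `score` (signalValue) and
#'   `summit` (absolute 1-based summit position or `NA`).
#' @export
readNarrowPeak <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L))
    stop(sprintf("%s: line %d: narrowPeak requires 10 columns, found %d",
                 path, which(nf != 10L)[1L], nf[which(nf != 10L)[1L]]),
         call. = FALSE)
  lineno <- seq_along(lines)
  chrom <- vapply(fields, `[`, character(1), 1L)
  s0 <- .parse_int(vapply(fields, `[`, character(1), 2L), path, lineno, "start")
  e0 <- .parse_int(vapply(fields, `[`, character(1), 3L), path, lineno, "end")
  bad <- s0 >= e0
  if (any(bad))
    stop(sprintf("%s: line %d: start >= end", path, which(bad)[1L]),
         call. = FALSE)
  gr <- .bed_to_granges(chrom, s0, e0,
                        vapply(fields, `[`, character(1), 6L))
  mcols(gr)$name <- vapply(fields, `[`, character(1), 4L)
  mcols(gr)$score <- as.numeric(vapply(fields, `[`, character(1), 7L))
  summit_off <- .parse_int(vapply(fields, `[`, character(1), 10L), path,
                           lineno, "summit offset")
  if (any(summit_off != -1L & (summit_off < 0L | summit_off >= e0 - s0)))
    stop(path, ": summit offset outside peak", call. = FALSE)
  mcols(gr)$summit <- ifelse(summit_off == -1L, NA_integer_,
                             start(gr) + summit_off)
  gr
}

#' Write peaks in narrowPeak format
#'
#' @param gr `GRanges` with optional `name`, `score` and `summit` (absolute
#'   1-based position) metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNarrowPeak <- function(gr, path) {
  gr <- GenomicRanges::sort(.canonicalSeqlevels(gr), ignore.strand = TRUE)
  mc <- mcols(gr)
  summit <- if (is.null(mc$summit)) rep(NA_integer_, length(gr)) else mc$summit
  dt <- data.table(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L, end = end(gr),
    name = if (is.null(mc$name)) sprintf("peak_%d", seq_along(gr)) else mc$name,
    score = 0L, strand = .granges_strand_chr(gr),
    signalValue = if (is.null(mc$score)) 0 else mc$score,
    pValue = -1, qValue = -1,
    summit = ifelse(is.na(summit), -1L, summit - start(gr)))
  fwrite(dt, path, sep = "\t", col.names = FALSE, eol = "\n", scipen = 50)
  invisible(path)
}

#' Read a bedGraph file onto fixed-width bins
#'
#' Records (which may be unsorted) are resampled onto fixed bins of
#' `binSize` bp by coverage-weighted mean, with uncovered base pairs
#' contributing 0 — so a bin half-covered by value 4 reads 2. Overlapping
#' records with differing values are contradictory and raise an error
#' naming the first conflict; exact duplicate records are tolerated.
#'
#' @param path path to a 4-column bedGraph file.
#' @param binSize target bin width in bp (default 50).
#' @param units units label to attach to the resulting track.
#' @return A [SignalTrack-class].
#' @export
readBedGraph <- function(path, binSize = 50L, units = "signal") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- fread(path, header = FALSE, sep = "\t", colClasses =
                list(character = 1, integer = 2:3, numeric = 4))
  if (!nrow(dt)) return(SignalTrack(list(), binSize, units))
  if (ncol(dt) != 4L)
    stop(path, ": bedGraph requires 4 columns, found ", ncol(dt),
         call. = FALSE)
  names(dt) <- c("chrom", "start", "end", "value")
  if (any(dt$start >= dt$end))
    stop(path, ": record with start >= end at row ",
         which(dt$start >= dt$end)[1L], call. = FALSE)
  dt <- unique(dt)
  setorder(dt, chrom, start, end)
  bs <- as.integer(binSize)
  values <- list()
  for (chrom in unique(dt$chrom)) {
    sel <- which(dt$chrom == chrom)
    d <- as.data.frame(dt)[sel, , drop = FALSE]
    ov <- which(d$start[-1L] < d$end[-nrow(d)])
    if (length(d$start) > 1L && length(ov))
      stop(sprintf(
        "%s: overlapping contradictory records on %s: [%d,%d)=%g vs [%d,%d)=%g",
        path, chrom, d$start[ov[1L]], d$end[ov[1L]], d$value[ov[1L]],
        d$start[ov[1L] + 1L], d$end[ov[1L] + 1L], d$value[ov[1L] + 1L]),
        call. = FALSE)
    nbin <- as.integer(ceiling(max(d$end) / bs))
    acc <- numeric(nbin)
    # spread each record's value*bp into the bins it covers
    for (i in seq_len(nrow(d))) {
      s <- d$start[i]; e <- d$end[i]; v <- d$value[i]
      if (v == 0) next
      b1 <- s %/% bs + 1L; b2 <- (e - 1L) %/% bs + 1L
      idx <- b1:b2
      acc[idx] <- acc[idx] + v * (pmin(e, idx * bs) - pmax(s, (idx - 1L) * bs))
    }
    values[[chrom]] <- acc / bs
  }
  SignalTrack(values, bs, units)
}

#' Write a SignalTrack as bedGraph
#'
#' Adjacent equal-valued bins are merged into single records; zero-valued
#' runs are written too so the covered extent round-trips.
#'
#' @param track a [SignalTrack-class].
#' @param path output path.
#' @param digits number of significant digits for values (fixed so the same
#'   track always serialises byte-identically).
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path, digits = 6L) {
  bs <- binSize(track)
  parts <- lapply(trackChroms(track), function(chrom) {
    v <- signif(trackValues(track)[[chrom]], digits)
    r <- rle(v)
    e <- cumsum(r$lengths) * bs
    s <- c(0L, e[-length(e)])
    data.table(chrom = chrom, start = s, end = e, value = r$values)
  })
  dt <- data.table::rbindlist(parts)
  fwrite(dt, path, sep = "\t", col.names = FALSE, eol = "\n", scipen = 50)
  invisible(path)
}

#' Read a gene-model table
#'
#' The exchange format for gene annotation is a 7-column tab-separated
#' table with header `gene_id chrom start end strand exon_starts exon_ends`,
#' coordinates 0-based half-open, exon starts/ends comma-separated and
#' sorted. The TSS is the start of the interval on `+` genes and the last
#' base on `-` genes.
#'
#' @param path path to the gene table.
#' @return `GRanges` with metadata columns `gene_id` (character), `tss`
#'   (1-based position) and `exons` (an `IRangesList` in absolute 1-based
#'   coordinates).
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- fread(path, header = TRUE, sep = "\t", colClasses = list(
    character = c("gene_id", "chrom", "strand", "exon_starts", "exon_ends"),
    integer = c("start", "end")))
  need <- c("gene_id", "chrom", "start", "end", "strand",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(dt)))
    stop(path, ": gene table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(dt$gene_id))
    stop(path, ": duplicate gene_id", call. = FALSE)
  gr <- .bed_to_granges(dt$chrom, dt$start, dt$end, dt$strand)
  es <- lapply(strsplit(dt$exon_starts, ",", fixed = TRUE), as.integer)
  ee <- lapply(strsplit(dt$exon_ends, ",", fixed = TRUE), as.integer)
  exons <- IRangesList(mapply(function(s, e) IRanges(s + 1L, e),
                              es, ee, SIMPLIFY = FALSE))
  bad <- any(mapply(function(ex, gs, ge)
    length(ex) == 0L || min(start(ex)) < gs || max(end(ex)) > ge ||
      is.unsorted(start(ex)), exons, start(gr), end(gr)))
  if (bad) stop(path, ": exons must be sorted and lie within the gene",
                call. = FALSE)
  mcols(gr)$gene_id <- dt$gene_id
  mcols(gr)$tss <- ifelse(as.character(strand(gr)) == "-", end(gr), start(gr))
  mcols(gr)$exons <- exons
  gr
}

#' Write a gene-model table
#'
#' @param genes `GRanges` as returned by [readGeneTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  ord <- order(as.character(seqnames(genes)), start(genes),
               mcols(genes)$gene_id)
  genes <- genes[ord]
  exons <- mcols(genes)$exons
  dt <- data.table(
    gene_id = mcols(genes)$gene_id,
    chrom = as.character(seqnames(genes)),
    start = start(genes) - 1L, end = end(genes),
    strand = .granges_strand_chr(genes),
    exon_starts = vapply(exons, function(x)
      paste(start(x) - 1L, collapse = ","), character(1)),
    exon_ends = vapply(exons, function(x)
      paste(end(x), collapse = ","), character(1)))
  fwrite(dt, path, sep = "\t", col.names = TRUE, eol = "\n", scipen = 50)
  invisible(path)
}

#' Read an expression matrix
#'
#' Tab-separated, header row = sample ids, first column = gene ids.
#' Duplicate gene or sample ids and non-finite values are errors.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- fread(path, header = TRUE, sep = "\t")
  genes <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, with = FALSE])
  rownames(m) <- genes
  if (anyDuplicated(rownames(m))) stop(path, ": duplicate gene ids",
                                       call. = FALSE)
  if (anyDuplicated(colnames(m))) stop(path, ": duplicate sample ids",
                                       call. = FALSE)
  if (!all(is.finite(m))) stop(path, ": non-finite expression values",
                               call. = FALSE)
  m
}

#' Write an expression matrix
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param idCol name for the gene-id column.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(mat, path, idCol = "gene_id") {
  dt <- data.table(gene = rownames(mat))
  names(dt) <- idCol
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  fwrite(dt, path, sep = "\t", col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop(sprintf("%s: line %d: GMT lines need name, description, >=1 gene",
                 path, which(short)[1L]), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop(path, ": duplicate set names",
                                       call. = FALSE)
  sets
}
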