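# small in-code fixture builders shared across test files

# genes GRanges in the shape readGeneTable() produces; exons default to the
# whole gene body
makeGenes <- function(chrom, start, end, strand, gene_id = NULL,
                      exons = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  n <- length(gr)
  if (is.null(gene_id)) gene_id <- sprintf("g%03d", seq_len(n))
  if (is.null(exons))
    exons <- lapply(seq_len(n), function(i) IRanges::IRanges(start[i], end[i]))
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$tss <- ifelse(strand == "-", end, start)
  S4Vectors::mcols(gr)$exons <- IRanges::IRangesList(exons)
  gr
}

gr1 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand)
}

writeLinesTmp <- function(lines, ext = ".bed") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

truthDomainsGr <- function(truth) {
  d <- as.data.frame(truth$planted_domains)
  GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1, d$end))
}
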