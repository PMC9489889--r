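# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no GRanges machinery, plain loops) so that agreement is
# informative.

# O(N^2) tangent-line cutoff: for every candidate index count points
# strictly below the line of slope (max-min)/N through that point
bruteCutoff <- function(scores) {
  y <- sort(pmax(scores, 0))
  n <- length(y)
  m <- (max(y) - min(y)) / n
  below <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) if (y[j] < y[i] + m * (j - i)) cnt <- cnt + 1L
    below[i] <- cnt
  }
  opt <- which.min(below)
  list(cutoff_value = y[opt], cutoff_index = opt,
       points_below = below[opt])
}

# transitive-closure merge over the pairwise gap relation, via union-find
bruteStitch <- function(chrom, start, end, window) {
  n <- length(chrom)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || chrom[i] != chrom[j]) next
    # 1-based closed intervals: bp gap between [.,e] and [s,.] is s - e - 1
    gap <- max(start[i], start[j]) - min(end[i], end[j]) - 1
    if (gap <= window) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), comp), function(idx)
    data.frame(chrom = chrom[idx[1]], start = min(start[idx]),
               end = max(end[idx]), n = length(idx)))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

# all-pairs AUC: concordant pairs, ties counting 1/2
bruteAuc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exact rank-sum p by enumeration of all group assignments (tie-free data)
enumRankSumP <- function(x, y, alternative) {
  pooled <- c(x, y)
  n1 <- length(x)
  uOf <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  uObs <- uOf(seq_len(n1))
  combs <- utils::combn(length(pooled), n1)
  uAll <- apply(combs, 2, uOf)
  pl <- mean(uAll <= uObs); pg <- mean(uAll >= uObs)
  switch(alternative,
         less = pl, greater = pg,
         two.sided = min(1, 2 * min(pl, pg)))
}

# all-pairs interval annotation mirroring the category contract
bruteAnnotate <- function(is, ie, geneDf, up, down) {
  cat_ <- "distal"
  overlaps <- function(a1, a2, b1, b2) a1 <= b2 && b1 <= a2
  for (g in seq_len(nrow(geneDf))) {
    gd <- geneDf[g, ]
    tss <- if (gd$strand == "-") gd$end else gd$start
    if (gd$strand == "-") {
      ps <- tss - down + 1; pe <- tss + up
    } else {
      ps <- tss - up; pe <- tss + down - 1
    }
    if (overlaps(is, ie, ps, pe)) return("promoter")
  }
  for (g in seq_len(nrow(geneDf))) {
    ex <- geneDf$exons[[g]]
    for (k in seq_len(nrow(ex)))
      if (overlaps(is, ie, ex$start[k], ex$end[k])) cat_ <- "exon"
  }
  if (cat_ == "exon") return("exon")
  for (g in seq_len(nrow(geneDf)))
    if (overlaps(is, ie, geneDf$start[g], geneDf$end[g])) return("intron")
  "distal"
}
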