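#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Thin, explicit wrapper around [stats::wilcox.test()] reporting the U
#' statistic of the first sample. The exact null distribution is used
#' whenever `n1 * n2 <= 10000` and the pooled data are tie-free; otherwise
#' the normal approximation with tie and continuity correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `statistic` (U), `p_value`, `alternative`, `method`
#'   (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @export
rankSumTest <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(c(x, y))))
    stop("samples must be finite", call. = FALSE)
  hasTies <- anyDuplicated(c(x, y)) > 0L
  useExact <- !hasTies && length(x) * length(y) <= 10000
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = useExact, correct = TRUE))
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       alternative = alternative,
       method = if (useExact) "exact" else "normal_approx",
       n1 = length(x), n2 = length(y))
}

#' Expression repression test for domain-associated genes
#'
#' Compares the expression of genes associated with rich domains against all
#' other genes with a one-sided rank-sum test (alternative: domain genes
#' lower), the comparison behind "low expression of genes with factor
#' enrichment at promoters". Per-gene expression is the mean over the
#' selected samples of a log2(x+1)-scale matrix.
#'
#' @param expr numeric matrix, genes x samples, log2(x+1) scale.
#' @param domainGenes character vector of domain-associated gene ids.
#' @param samples optional character vector of sample ids to average over
#'   (default: all columns).
#' @param alternative test direction (default `"less"`).
#' @return the [rankSumTest()] result plus `median_domain`,
#'   `median_background`, `n_domain`, `n_background`.
#' @export
compareDomainGeneExpression <- function(expr, domainGenes, samples = NULL,
                                        alternative = "less") {
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expr must have gene rownames and sample colnames", call. = FALSE)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(expr))
    if (length(missing))
      stop("samples absent from matrix: ", paste(missing, collapse = ", "),
           call. = FALSE)
    expr <- expr[, samples, drop = FALSE]
  }
  domainGenes <- intersect(domainGenes, rownames(expr))
  bgGenes <- setdiff(rownames(expr), domainGenes)
  if (length(domainGenes) < 3L || length(bgGenes) < 3L)
    stop("need >= 3 genes in both the domain and background groups",
         call. = FALSE)
  gm <- rowMeans(expr)
  res <- rankSumTest(gm[domainGenes], gm[bgGenes], alternative = alternative)
  res$median_domain <- stats::median(gm[domainGenes])
  res$median_background <- stats::median(gm[bgGenes])
  res$n_domain <- length(domainGenes)
  res$n_background <- length(bgGenes)
  res
}

#' Pearson/Spearman correlation with least-squares line
#'
#' Both correlation coefficients with their p-values (Spearman on midranks,
#' asymptotic p so ties are handled), plus the least-squares slope and
#' intercept of y on x — the combination reported for
#' methylation-versus-expression scatter plots.
#'
#' @param x,y paired numeric vectors, n >= 3, finite.
#' @return list with `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `slope`, `intercept`, `n`.
#' @export
correlationTest <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in x", call. = FALSE)
  if (stats::sd(y) == 0) stop("zero variance in y", call. = FALSE)
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  slope <- stats::cov(x, y) / stats::var(x)
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       slope = slope, intercept = mean(y) - slope * mean(x),
       n = length(x))
}

#' ROC analysis with Youden-optimal cutoff
#'
#' AUC by Mann-Whitney pair counting (tied pairs count 1/2), the full
#' (FPR, TPR) curve over all score thresholds, and the cutoff maximising
#' the Youden index J = sensitivity + specificity - 1 (ties broken toward
#' higher specificity, i.e. the higher cutoff). A sample is predicted
#' positive when its score is >= the cutoff.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, `TRUE` = positive class; both
#'   classes must be present.
#' @return list with `auc`, `points` (data.frame fpr/tpr/cutoff, from
#'   (0,0) to (1,1)), `optimal_cutoff`, `sensitivity_at_cutoff`,
#'   `specificity_at_cutoff`, `youden_j`.
#' @export
rocAnalysis <- function(scores, labels) {
  scores <- as.numeric(scores)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stop("numeric labels must be 0/1", call. = FALSE)
    labels <- labels == 1
  }
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must be paired", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks: tied pairs contribute 1/2
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(cuts, function(ct) sum(scores[labels] >= ct) / n1, numeric(1))
  spec <- vapply(cuts, function(ct) sum(scores[!labels] < ct) / n0, numeric(1))
  pts <- data.frame(fpr = c(0, 1 - spec, 1), tpr = c(0, sens, 1),
                    cutoff = c(Inf, cuts, -Inf))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]  # higher specificity = higher cutoff
  list(auc = auc, points = pts,
       optimal_cutoff = cuts[best],
       sensitivity_at_cutoff = sens[best],
       specificity_at_cutoff = spec[best],
       youden_j = j[best])
}

#' Over-representation analysis (one-sided Fisher / hypergeometric)
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap when `n` hits are sampled from a universe
#' of `N` genes containing `K` set members, with Benjamini-Hochberg
#' adjustment across sets. Sets are intersected with the universe before
#' testing.
#'
#' @param hits character vector of hit gene ids (subset of `universe`).
#' @param geneSets named list of character vectors (e.g. [readGmt()]).
#' @param universe character vector of all testable gene ids.
#' @return data.frame sorted by p-value with columns `set`, `k` (overlap),
#'   `K` (set size in universe), `n` (hits), `N` (universe), `odds_ratio`,
#'   `p_value`, `adj_p_value`.
#' @export
overRepresentation <- function(hits, geneSets, universe) {
  universe <- unique(as.character(universe))
  hits <- unique(as.character(hits))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(hits)) stop("empty hit list", call. = FALSE)
  out <- setdiff(hits, universe)
  if (length(out))
    stop("hits not in universe: ", paste(utils::head(out, 3), collapse = ", "),
         call. = FALSE)
  N <- length(universe); n <- length(hits)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(geneSets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, hits))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or <- (k * (N - K - n + k)) / max((K - k) * (n - k), .Machine$double.eps)
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$adj_p_value <- stats::p.adjust(df$p_value, method = "BH")
  df[order(df$p_value, df$set), , drop = FALSE]
}

#' Split a cohort by a driver gene's expression
#'
#' Ranks samples by the driver's expression and takes the top and bottom
#' `nPerGroup` as the high and low cohorts (the 20-vs-20 patient split used
#' for driver-high vs driver-low comparisons). Ties on the driver value are
#' broken by lexicographic sample id, so the split is deterministic.
#'
#' @param expr numeric matrix, genes x samples.
#' @param driverGene row name of the driver gene.
#' @param nPerGroup samples per cohort (default 20).
#' @return list with `driver`, `high` and `low` (character vectors of
#'   sample ids, each of length `nPerGroup`), `n_per_group`.
#' @export
splitByDriver <- function(expr, driverGene, nPerGroup = 20L) {
  if (!driverGene %in% rownames(expr))
    stop("driver gene ", driverGene, " absent from matrix", call. = FALSE)
  nPerGroup <- as.integer(nPerGroup)
  ids <- colnames(expr)
  if (length(ids) < 2L * nPerGroup)
    stop(sprintf("need >= %d samples for two groups of %d; have %d",
                 2L * nPerGroup, nPerGroup, length(ids)), call. = FALSE)
  v <- expr[driverGene, ]
  ordAsc <- ids[order(v, ids)]
  ordDesc <- ids[order(-v, ids)]
  list(driver = driverGene,
       high = ordDesc[seq_len(nPerGroup)],
       low = ordAsc[seq_len(nPerGroup)],
       n_per_group = nPerGroup)
}

#' Per-sample signature score (mean z-score over a gene set)
#'
#' Each signature gene is z-scored across samples (sample standard
#' deviation, n-1 denominator by default) and scores are averaged per
#' sample — a generic unweighted stand-in for proprietary program scores
#' such as senescence signatures. Signature genes missing from the matrix
#' are dropped with a warning; zero-variance genes are an error since their
#' z-score is undefined.
#'
#' @param expr numeric matrix, genes x samples (>= 2 samples).
#' @param geneSet character vector of signature gene ids.
#' @param sdMethod `"sample"` (n-1, default) or `"population"` (n).
#' @return named numeric vector of per-sample scores.
#' @export
signatureScore <- function(expr, geneSet,
                           sdMethod = c("sample", "population")) {
  sdMethod <- match.arg(sdMethod)
  if (ncol(expr) < 2L) stop("need >= 2 samples", call. = FALSE)
  present <- intersect(geneSet, rownames(expr))
  if (!length(present))
    stop("signature entirely absent from matrix", call. = FALSE)
  if (length(present) < length(unique(geneSet)))
    warning(sprintf("%d signature gene(s) absent from matrix",
                    length(unique(geneSet)) - length(present)),
            call. = FALSE)
  sub <- expr[present, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1L, stats::sd)
  if (sdMethod == "population")
    sdv <- sdv * sqrt((ncol(sub) - 1) / ncol(sub))
  zero <- sdv == 0
  if (any(zero))
    stop("zero-variance signature gene(s): ",
         paste(utils::head(present[zero], 5), collapse = ", "),
         call. = FALSE)
  z <- (sub - mu) / sdv
  colMeans(z)
}
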