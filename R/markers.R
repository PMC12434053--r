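## Specificity-index marker discovery, tertile stratification, contamination
## scoring and cross-platform correlation.

typeMeans <- function(m, groups) {
  types <- sort(unique(groups))
  out <- vapply(types, function(ct)
    rowMeans(m[, groups == ct, drop = FALSE]), numeric(nrow(m)))
  colnames(out) <- types
  out
}

#' Specificity index
#'
#' For gene g and cell type A, the specificity index is the mean, over every
#' other type B, of g's rank (descending, average ranks for ties) of the
#' expression advantage \eqn{\Delta(g; A, B) = mean_A - mean_B} on the log2
#' scale. Ranks are averaged over bootstrap iterations that resample samples
#' with replacement within each cell type, so the index reflects
#' between-donor stability. Low SI = highly specific.
#'
#' @param expr log2-scale \code{\link{ExpressionMatrix}}.
#' @param groups Cell-type label per sample (aligned to columns).
#' @param nIter Bootstrap iterations (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return \code{\link{SpecificityTable}}.
#' @export
specificityIndex <- function(expr, groups, nIter = 1000, seed = 1) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (scaleTag(expr) != "log2_pm")
    stop("specificityIndex expects log2_pm expression")
  if (length(groups) != ncol(expr))
    stop("groups must align with expression columns")
  types <- sort(unique(groups))
  if (length(types) < 2) stop("need at least two cell types")
  n0 <- table(factor(groups, levels = types))
  if (any(n0 == 0)) stop("cell type with zero samples")
  set.seed(as.integer(seed))
  m <- expr@.Data
  G <- nrow(m); K <- length(types)
  idxByType <- lapply(types, function(ct) which(groups == ct))
  acc <- matrix(0, G, K, dimnames = list(rownames(m), types))
  acc2 <- matrix(0, G, K, dimnames = list(rownames(m), types))
  for (it in seq_len(nIter)) {
    cols <- unlist(lapply(idxByType, function(ix)
      if (nIter == 1L) ix else sample(ix, length(ix), replace = TRUE)))
    grp <- rep(types, times = lengths(idxByType))
    tm <- typeMeans(m[, cols, drop = FALSE], grp)
    for (a in seq_len(K)) {
      rsum <- numeric(G)
      for (b in seq_len(K)[-a]) {
        delta <- tm[, a] - tm[, b]
        rsum <- rsum + rank(-delta, ties.method = "average")
      }
      si <- rsum / (K - 1)
      acc[, a] <- acc[, a] + si
      acc2[, a] <- acc2[, a] + si^2
    }
  }
  si <- acc / nIter
  sd2 <- pmax(acc2 / nIter - si^2, 0)
  new("SpecificityTable", si = si, siSD = sqrt(sd2),
      nIter = as.integer(nIter), seed = as.integer(seed))
}

#' Select cell-type-specific genes
#'
#' Top-k genes per cell type by ascending specificity index, ties broken by
#' gene identifier.
#'
#' @param table \code{\link{SpecificityTable}}.
#' @param k Genes per type (default 500).
#' @return Named list of character vectors, one per cell type.
#' @export
selectSpecificGenes <- function(table, k = 500) {
  stopifnot(is(table, "SpecificityTable"))
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(table@si)) stop("k exceeds the number of genes")
  lapply(setNames(colnames(table@si), colnames(table@si)), function(ct) {
    ord <- order(table@si[, ct], rownames(table@si))
    rownames(table@si)[ord[seq_len(k)]]
  })
}

#' Tertile stratification of specific genes
#'
#' Per cell type, the mean expression of each specific gene over that type's
#' samples is split at its empirical 33\% and 66\% quantiles
#' (linear-interpolation quantiles, \code{type = 7}) into half-open bins:
#' low [0, q33), medium [q33, q66), high [q66, Inf).
#'
#' @param expr log2-scale \code{\link{ExpressionMatrix}}.
#' @param specificGenes Named list of per-type gene vectors.
#' @param groups Cell-type label per sample.
#' @return data.frame with \code{gene}, \code{cell_type}, \code{meanExpr},
#'   \code{tertile}.
#' @export
assignTertiles <- function(expr, specificGenes, groups) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (length(groups) != ncol(expr))
    stop("groups must align with expression columns")
  out <- lapply(names(specificGenes), function(ct) {
    genes <- specificGenes[[ct]]
    if (length(genes) < 3) stop("need >= 3 specific genes for '", ct, "'")
    miss <- setdiff(genes, rownames(expr))
    if (length(miss)) stop("specific gene(s) absent from expression: ",
                           miss[1])
    cols <- which(groups == ct)
    if (length(cols) == 0) stop("no samples for cell type '", ct, "'")
    mu <- rowMeans(expr@.Data[genes, cols, drop = FALSE])
    q <- quantile(mu, c(0.33, 0.66), type = 7, names = FALSE)
    if (q[1] == q[2])
      warning("degenerate expression quantiles for '", ct,
              "'; genes collapse into one bin")
    tertile <- ifelse(mu < q[1], "low", ifelse(mu < q[2], "medium", "high"))
    data.frame(gene = genes, cell_type = ct, meanExpr = unname(mu),
               tertile = tertile, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Contamination score of source-type markers in other groups
#'
#' Per target group: the mean log2 expression of a source cell type's marker
#' genes and the fraction of (marker, sample) pairs with expression > 0. The
#' source group's own values serve as the reference.
#'
#' @param expr log2-scale \code{\link{ExpressionMatrix}}.
#' @param markerGenes Marker genes of the source cell type.
#' @param groups Cell-type label per sample.
#' @param sourceGroup Label of the source type (for the \code{isSource}
#'   flag).
#' @return data.frame per group: \code{meanLog2}, \code{fracPositive},
#'   \code{isSource}.
#' @export
contaminationScore <- function(expr, markerGenes, groups, sourceGroup) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (length(markerGenes) == 0) stop("empty marker list")
  miss <- setdiff(markerGenes, rownames(expr))
  if (length(miss)) stop("marker gene(s) absent from expression: ", miss[1])
  types <- sort(unique(groups))
  out <- lapply(types, function(ct) {
    sub <- expr@.Data[markerGenes, groups == ct, drop = FALSE]
    data.frame(group = ct, meanLog2 = mean(sub),
               fracPositive = mean(sub > 0),
               isSource = ct == sourceGroup, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-platform correlation of cell-type mean profiles
#'
#' Pearson correlation of log expression between every pair of cell types
#' from two platforms/cohorts, on the genes shared by both (inner join on
#' gene identifier).
#'
#' @param meansA,meansB gene-by-cell-type matrices of log expression.
#' @return Correlation matrix, types of A by types of B.
#' @export
crossPlatformCorrelation <- function(meansA, meansB) {
  shared <- intersect(rownames(meansA), rownames(meansB))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  cor(meansA[shared, , drop = FALSE], meansB[shared, , drop = FALSE],
      method = "pearson")
}
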