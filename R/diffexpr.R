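## Simplified covariate-aware differential expression: per-gene ordinary
## least squares on log2 per-million expression with observed covariates and
## residual-PCA hidden covariates. Deliberately not a negative-binomial
## shrinkage/Wald framework; downstream stages consume only
## (baseMean, log2FC, stat, pvalue, padj), so the interface matches.

buildDesign <- function(n, primary, covariates = NULL) {
  X <- cbind(intercept = rep(1, n), primary = primary)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must align with samples")
    X <- cbind(X, covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  X
}

## Per-gene OLS of Y (genes x samples) on design X; t-test on column `coefIdx`.
olsPerGene <- function(Y, X, coefIdx) {
  n <- ncol(Y); p <- ncol(X)
  if (n <= p) stop("need more samples than design columns")
  qrX <- qr(X)
  B <- t(qr.coef(qrX, t(Y)))               # genes x p
  fitted <- B %*% t(X)
  res <- Y - fitted
  rss <- rowSums(res^2)
  df <- n - p
  sigma2 <- rss / df
  xtxinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtxinv[coefIdx, coefIdx])
  beta <- B[, coefIdx]
  constant <- apply(Y, 1, function(r) var(r) == 0)
  stat <- ifelse(se > 0, beta / se, 0)
  pval <- 2 * pt(-abs(stat), df)
  pval[constant] <- 1
  stat[constant] <- 0
  list(beta = beta, stat = stat, pvalue = pval, df = df,
       flagged = constant, residuals = res)
}

#' Infer hidden covariates by residual PCA
#'
#' Regresses each gene on the primary design, then returns the top-k
#' principal components of the residual matrix as inferred covariates — a
#' simplified, deterministic analogue of surrogate-variable detection of
#' unwanted technical variation. Sign convention as in \code{\link{runPCA}}.
#'
#' @param expr log2-scale \code{\link{ExpressionMatrix}}.
#' @param primary Primary variable (condition factor/indicator or numeric).
#' @param k Number of components to infer (default 2).
#' @param covariates Optional observed covariates included in the primary
#'   regression and passed through.
#' @return List with \code{inferred} (samples x k matrix, columns SV1..SVk)
#'   and \code{observed} (the covariates passed through, possibly NULL).
#' @export
estimateHiddenCovariates <- function(expr, primary, k = 2, covariates = NULL) {
  stopifnot(is(expr, "ExpressionMatrix"))
  n <- ncol(expr)
  primary <- encodePrimary(primary)
  X <- buildDesign(n, primary, covariates)
  if (n < ncol(X) + k + 2)
    stop("k = ", k, " too large for ", n, " samples and ", ncol(X),
         " design columns")
  if (k == 0)
    return(list(inferred = matrix(numeric(0), n, 0), observed = covariates))
  fit <- olsPerGene(expr@.Data, X, 2L)
  pc <- prcomp(t(fit$residuals), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  sv <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) sv[, j] <- -sv[, j]
  }
  colnames(sv) <- paste0("SV", seq_len(k))
  rownames(sv) <- colnames(expr)
  list(inferred = sv, observed = covariates)
}

encodePrimary <- function(primary) {
  if (is.character(primary) || is.factor(primary)) {
    f <- factor(primary)
    if (nlevels(f) != 2) stop("primary factor must have exactly two levels")
    ## control/AT convention: control is the reference when present
    if ("control" %in% levels(f)) f <- stats::relevel(f, "control")
    as.numeric(f) - 1
  } else as.numeric(primary)
}

#' Differential expression by per-gene linear model
#'
#' Ordinary least squares of log2 per-million expression on the condition
#' (AT vs control) plus covariates; t-test on the condition coefficient with
#' Benjamini-Hochberg correction over all tested genes. Zero-variance genes
#' are reported with p = 1 and flagged. \code{baseMean} is the mean linear
#' per-million expression, the scale the enrichment rank-list filter uses.
#'
#' @param expr log2-scale \code{\link{ExpressionMatrix}}.
#' @param condition control/AT labels per sample (control = reference).
#' @param covariates Optional samples-x-p matrix/data.frame (observed plus
#'   inferred, e.g. \code{estimateHiddenCovariates()$inferred}).
#' @param linearExpr Optional linear_pm \code{\link{ExpressionMatrix}} for
#'   \code{baseMean}; by default it is recovered as \code{2^x - 1}.
#' @return data.frame: \code{gene}, \code{baseMean}, \code{log2FC},
#'   \code{stat}, \code{pvalue}, \code{padj}, \code{flagged}.
#' @export
fitDE <- function(expr, condition, covariates = NULL, linearExpr = NULL) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (scaleTag(expr) != "log2_pm") stop("fitDE expects log2_pm expression")
  if (length(condition) != ncol(expr))
    stop("condition must align with samples")
  primary <- encodePrimary(condition)
  if (length(unique(primary)) < 2) stop("both conditions must be present")
  X <- buildDesign(ncol(expr), primary, covariates)
  fit <- olsPerGene(expr@.Data, X, 2L)
  baseMean <- if (!is.null(linearExpr)) {
    rowMeans(linearExpr@.Data[rownames(expr), , drop = FALSE])
  } else rowMeans(pmax(2^expr@.Data - 1, 0))
  out <- data.frame(gene = rownames(expr), baseMean = unname(baseMean),
                    log2FC = unname(fit$beta), stat = unname(fit$stat),
                    pvalue = unname(fit$pvalue),
                    flagged = unname(fit$flagged),
                    stringsAsFactors = FALSE)
  out$padj <- p.adjust(out$pvalue, method = "BH")
  out[, c("gene", "baseMean", "log2FC", "stat", "pvalue", "padj", "flagged")]
}

#' Per-gene association with age
#'
#' Per-gene regression of log2 expression on age in years (slope per year),
#' with optional covariates, over a sample subset (typically controls).
#'
#' @param expr log2-scale \code{\link{ExpressionMatrix}}.
#' @param age Ages in years, aligned to samples.
#' @param subset Logical or index vector of samples to use (default: all).
#' @param covariates Optional covariates (subset along with samples).
#' @return data.frame as \code{\link{fitDE}} with \code{slope} (per year)
#'   in place of \code{log2FC}.
#' @export
ageAssociation <- function(expr, age, subset = NULL, covariates = NULL) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (length(age) != ncol(expr)) stop("age must align with samples")
  if (!is.null(subset)) {
    expr2 <- expr@.Data[, subset, drop = FALSE]
    age <- age[subset]
    if (!is.null(covariates))
      covariates <- as.matrix(covariates)[subset, , drop = FALSE]
  } else expr2 <- expr@.Data
  if (length(unique(age)) < 2) stop("age is constant in the chosen subset")
  if (ncol(expr2) < 4) stop("need >= 4 samples")
  X <- buildDesign(ncol(expr2), as.numeric(age), covariates)
  fit <- olsPerGene(expr2, X, 2L)
  out <- data.frame(gene = rownames(expr), slope = unname(fit$beta),
                    stat = unname(fit$stat), pvalue = unname(fit$pvalue),
                    flagged = unname(fit$flagged), stringsAsFactors = FALSE)
  out$padj <- p.adjust(out$pvalue, method = "BH")
  out$baseMean <- rowMeans(pmax(2^expr2 - 1, 0))
  out[, c("gene", "baseMean", "slope", "stat", "pvalue", "padj", "flagged")]
}

#' Cross-cell-type sharing of differentially expressed genes
#'
#' For each cell type, tabulates its significant genes by the number of cell
#' types in which they are significant; "specific" genes are significant in
#' exactly one.
#'
#' @param deList Named list of \code{\link{fitDE}} results, one per cell
#'   type.
#' @param padjMax Significance cutoff on \code{padj} (default 0.05).
#' @return data.frame: \code{cell_type}, \code{shared_by} (1..K),
#'   \code{count}, plus \code{percentSpecific} per type.
#' @export
deSpecificityFrequency <- function(deList, padjMax = 0.05) {
  if (length(deList) < 2) stop("need results for at least two cell types")
  sig <- lapply(deList, function(de) de$gene[!is.na(de$padj) &
                                               de$padj < padjMax])
  if (all(lengths(sig) == 0)) stop("no significant genes in any cell type")
  tally <- table(unlist(sig))
  K <- length(deList)
  out <- lapply(names(deList), function(ct) {
    g <- sig[[ct]]
    shared <- factor(as.integer(tally[g]), levels = seq_len(K))
    cnt <- as.integer(table(shared))
    data.frame(cell_type = ct, shared_by = seq_len(K), count = cnt,
               percentSpecific = if (length(g)) 100 * cnt[1] / length(g)
                                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a preranked gene list (.rnk)
#'
#' Two tab-separated columns, gene and statistic, sorted by statistic
#' descending (ties by gene ID), per the preranked-GSEA convention.
#'
#' @param de \code{\link{fitDE}}-style data.frame with \code{gene} and
#'   \code{stat}.
#' @param path Output path.
#' @export
writeRnk <- function(de, path) {
  ord <- order(-de$stat, de$gene)
  write.table(de[ord, c("gene", "stat")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
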