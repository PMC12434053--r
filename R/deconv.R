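## Signature construction, simplex-constrained global deconvolution, the
## comparative target-vs-rest mode, and condition contrasts on fractions.

## Exact solvers ------------------------------------------------------------

## Least squares over the probability simplex by enumeration of supports.
## For each candidate support the equality-constrained stationary point is
## the restricted optimum (KKT); the global optimum appears among feasible
## candidates, so for positive-definite subproblems the search is exact.
## K is small (<= 9 cell types), so 2^K - 1 supports are cheap.
simplexSolve <- function(x, S) {
  sc <- mean(S)
  if (sc <= 0) stop("signature matrix must have positive mean")
  x <- x / sc; S <- S / sc
  K <- ncol(S)
  Q <- crossprod(S); b <- drop(crossprod(S, x)); cs <- mean(diag(Q))
  best <- NULL; bobj <- Inf
  for (m in seq_len(2^K - 1)) {
    A <- which(bitwAnd(m, 2^(seq_len(K) - 1)) > 0)
    n <- length(A)
    M <- rbind(cbind(Q[A, A, drop = FALSE], cs), c(rep(cs, n), 0))
    sol <- tryCatch(solve(M, c(b[A], cs)), error = function(e) NULL)
    if (is.null(sol)) next
    f <- sol[seq_len(n)]
    if (all(f >= -1e-10)) {
      fa <- pmax(f, 0)
      obj <- sum((x - S[, A, drop = FALSE] %*% fa)^2)
      if (obj < bobj) {
        bobj <- obj
        best <- numeric(K); best[A] <- fa / sum(fa)
      }
    }
  }
  if (is.null(best))
    return(list(f = rep(1 / K, K), objective = NA_real_, converged = FALSE))
  list(f = best, objective = bobj * sc^2, converged = TRUE)
}

## Non-negative least squares by the same support enumeration (no equality
## constraint); used for the optional free-scale mode.
nnlsSolve <- function(x, S) {
  sc <- mean(S)
  x <- x / sc; S <- S / sc
  K <- ncol(S)
  Q <- crossprod(S); b <- drop(crossprod(S, x))
  best <- numeric(K); bobj <- sum(x^2)
  for (m in seq_len(2^K - 1)) {
    A <- which(bitwAnd(m, 2^(seq_len(K) - 1)) > 0)
    sol <- tryCatch(solve(Q[A, A, drop = FALSE], b[A]),
                    error = function(e) NULL)
    if (is.null(sol)) next
    if (all(sol >= -1e-10)) {
      g <- pmax(sol, 0)
      obj <- sum((x - S[, A, drop = FALSE] %*% g)^2)
      if (obj < bobj) { bobj <- obj; best <- numeric(K); best[A] <- g }
    }
  }
  list(g = best, objective = bobj * sc^2)
}

asSampleMatrix <- function(x, genes) {
  if (is(x, "ExpressionMatrix")) {
    if (scaleTag(x) != "linear_pm")
      stop("deconvolution expects linear_pm expression")
    x <- x@.Data
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1,
                                   dimnames = list(names(x), "sample1"))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("sample", seq_len(ncol(x)))
  if (is.null(rownames(x))) {
    ## unnamed input: assume already aligned to the signature genes
    if (nrow(x) != length(genes))
      stop("unnamed sample expression must match the signature gene count")
    rownames(x) <- genes
  }
  miss <- setdiff(genes, rownames(x))
  if (length(miss))
    stop("sample expression lacks signature gene(s), e.g. ", miss[1])
  x[genes, , drop = FALSE]
}

## Signature construction ---------------------------------------------------

#' Build a signature matrix from sorted profiles
#'
#' Per-cell-type mean of linear per-million expression over the sorted
#' samples, restricted to a gene set (typically the union of top specific
#' genes from \code{\link{selectSpecificGenes}}).
#'
#' @param expr linear_pm \code{\link{ExpressionMatrix}} of sorted samples.
#' @param metadata Sample table with \code{sample_id} and \code{cell_type}.
#' @param genes Gene set for the signature (default: all genes).
#' @param cellTypes Cell types required (default: the eight sorted types).
#' @return \code{\link{SignatureMatrix}}.
#' @export
buildSignatureMatrix <- function(expr, metadata, genes = rownames(expr),
                                 cellTypes = setdiff(CELL_TYPES, "unsorted")) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (scaleTag(expr) != "linear_pm")
    stop("signature construction expects linear_pm expression")
  if (length(genes) == 0) stop("genes must be non-empty")
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) stop("gene(s) not in expression matrix: ", miss[1])
  metadata <- metadata[match(colnames(expr), metadata$sample_id), ]
  if (anyNA(metadata$sample_id))
    stop("metadata lacks rows for some expression samples")
  absent <- setdiff(cellTypes, unique(metadata$cell_type))
  if (length(absent))
    stop("no sorted samples for cell type(s): ",
         paste(absent, collapse = ", "))
  sig <- vapply(cellTypes, function(ct) {
    rowMeans(expr@.Data[genes, metadata$cell_type == ct, drop = FALSE])
  }, numeric(length(genes)))
  dimnames(sig) <- list(genes, cellTypes)
  new("SignatureMatrix", sig,
      provenance = paste0("mean of ", nrow(metadata), " sorted samples"))
}

#' Noise-free signature from a ground-truth reference
#'
#' The reference profiles scaled to the per-million scale (columns sum to
#' 1e6 over the full gene catalog), as a \code{\link{SignatureMatrix}}.
#'
#' @param ref \code{\link{GroundTruthReference}}.
#' @param genes Optional gene subset (after per-million scaling).
#' @return \code{\link{SignatureMatrix}}.
#' @export
truthSignature <- function(ref, genes = NULL) {
  stopifnot(is(ref, "GroundTruthReference"))
  sig <- sweep(ref@profiles, 2, colSums(ref@profiles), "/") * 1e6
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(sig))
    if (length(miss)) stop("unknown gene(s): ", miss[1])
    sig <- sig[genes, , drop = FALSE]
  }
  new("SignatureMatrix", sig, provenance = "ground-truth profiles")
}

## Global deconvolution -----------------------------------------------------

#' Global cell-type deconvolution
#'
#' Estimates, for each unsorted sample, the simplex of cell-type fractions
#' minimizing \eqn{\|x - S f\|_2} subject to \eqn{f \ge 0}, \eqn{\sum f = 1}
#' (exact active-set solution). The sample expression and the signature must
#' share the per-million scale; with \code{rescale = TRUE} a free positive
#' scale factor is fitted jointly (equivalent to non-negative least squares
#' followed by renormalization), making the fractions invariant to
#' rescaling of \code{x}.
#'
#' @param x Sample expression: linear_pm \code{\link{ExpressionMatrix}},
#'   matrix, or single named vector, aligned (or alignable) to the
#'   signature genes.
#' @param S \code{\link{SignatureMatrix}}.
#' @param rescale Fit a free scale factor (default \code{FALSE}).
#' @return data.frame, one row per sample: one fraction column per cell
#'   type, plus \code{residualNorm} and \code{converged}.
#' @export
deconvolveGlobal <- function(x, S, rescale = FALSE) {
  stopifnot(is(S, "SignatureMatrix"))
  Sm <- S@.Data
  xm <- asSampleMatrix(x, rownames(Sm))
  res <- lapply(seq_len(ncol(xm)), function(j) {
    if (rescale) {
      nn <- nnlsSolve(xm[, j], Sm)
      tot <- sum(nn$g)
      if (tot <= 0)
        return(list(f = rep(NA_real_, ncol(Sm)), objective = nn$objective,
                    converged = FALSE))
      list(f = nn$g / tot, objective = nn$objective, converged = TRUE)
    } else simplexSolve(xm[, j], Sm)
  })
  out <- data.frame(sample = colnames(xm),
                    do.call(rbind, lapply(res, `[[`, "f")))
  colnames(out)[-1] <- colnames(Sm)
  out$residualNorm <- sqrt(vapply(res, `[[`, numeric(1), "objective"))
  out$converged <- vapply(res, `[[`, logical(1), "converged")
  if (any(!out$converged))
    warning("deconvolution did not converge for ",
            sum(!out$converged), " sample(s)")
  out
}

## Comparative deconvolution ------------------------------------------------

#' Build comparative (target-vs-rest) panels
#'
#' One two-column panel per signature cell type: the target signature and
#' the unweighted average of all other types. When marker assignments are
#' supplied, each panel is restricted to genes that are not specific to any
#' individual rest type (the target's own markers plus the shared
#' background), so that the pooled rest column represents every non-target
#' type equally; without this restriction the rest average misstates the
#' granule-dominated mixtures the panels are fitted to (see the methods
#' vignette).
#'
#' @param S \code{\link{SignatureMatrix}} (full gene universe recommended).
#' @param markers Optional named list of per-type marker genes.
#' @return Named list of \code{\link{ComparativePanel}} objects.
#' @export
buildComparativePanels <- function(S, markers = NULL) {
  stopifnot(is(S, "SignatureMatrix"))
  if (ncol(S) < 2) stop("need at least two cell types")
  types <- colnames(S)
  panels <- lapply(types, function(ct) {
    genes <- rownames(S)
    if (!is.null(markers)) {
      drop <- unlist(markers[setdiff(names(markers), ct)], use.names = FALSE)
      genes <- setdiff(genes, drop)
    }
    tgt <- S@.Data[genes, ct]
    rest <- rowMeans(S@.Data[genes, setdiff(types, ct), drop = FALSE])
    new("ComparativePanel", target = ct,
        panel = cbind(target = tgt, rest = rest))
  })
  names(panels) <- types
  panels
}

#' Comparative deconvolution (fraction of similarity)
#'
#' Two-component simplex-constrained fit of each sample against one
#' \code{\link{ComparativePanel}}; returns the target's fraction, the
#' "fraction of similarity" between the sample and the target cell type
#' relative to the average of all other types.
#'
#' @param x Sample expression as in \code{\link{deconvolveGlobal}}.
#' @param panel \code{\link{ComparativePanel}}.
#' @param rescale As in \code{\link{deconvolveGlobal}}.
#' @return data.frame with \code{sample}, \code{target}, \code{fraction},
#'   \code{residualNorm}, \code{converged}.
#' @export
deconvolveComparative <- function(x, panel, rescale = FALSE) {
  stopifnot(is(panel, "ComparativePanel"))
  Sm <- panel@panel
  xm <- asSampleMatrix(x, rownames(Sm))
  res <- lapply(seq_len(ncol(xm)), function(j) {
    if (rescale) {
      nn <- nnlsSolve(xm[, j], Sm)
      tot <- sum(nn$g)
      list(f = if (tot > 0) nn$g / tot else c(NA_real_, NA_real_),
           objective = nn$objective, converged = tot > 0)
    } else simplexSolve(xm[, j], Sm)
  })
  data.frame(sample = colnames(xm), target = panel@target,
             fraction = vapply(res, function(r) r$f[1], numeric(1)),
             residualNorm = sqrt(vapply(res, `[[`, numeric(1), "objective")),
             converged = vapply(res, `[[`, logical(1), "converged"))
}

## Condition contrasts ------------------------------------------------------

#' Contrast similarity fractions between conditions
#'
#' Welch two-sample t-test per cell type on per-sample fractions, with
#' Benjamini-Hochberg correction across the cell types tested in one call.
#' The fold change is the ratio of group means, reported as
#' control/AT with direction \code{"decrease"} when the control mean is
#' larger, and AT/control with direction \code{"increase"} otherwise.
#'
#' @param fractions data.frame with columns \code{sample}, \code{target},
#'   \code{fraction} (e.g. row-bound \code{\link{deconvolveComparative}}
#'   results).
#' @param condition Named vector (names = sample IDs) or vector aligned to
#'   \code{fractions$sample}, with levels control / AT.
#' @return data.frame per cell type: group means, \code{fold},
#'   \code{direction}, \code{t}, \code{df}, \code{pvalue}, \code{padj}.
#' @export
contrastConditions <- function(fractions, condition) {
  if (!is.null(names(condition)))
    condition <- condition[fractions$sample]
  if (length(condition) != nrow(fractions))
    stop("condition must align with fractions rows")
  out <- lapply(split(seq_len(nrow(fractions)), fractions$target),
                function(idx) {
    f <- fractions$fraction[idx]; cc <- condition[idx]
    a <- f[cc == "control"]; b <- f[cc == "AT"]
    if (length(a) < 2 || length(b) < 2)
      stop("need >= 2 samples per group for cell type '",
           fractions$target[idx[1]], "'")
    tt <- stats::t.test(a, b)
    dec <- mean(a) >= mean(b)
    data.frame(cell_type = fractions$target[idx[1]],
               meanControl = mean(a), meanAT = mean(b),
               fold = if (dec) mean(a) / mean(b) else mean(b) / mean(a),
               direction = if (dec) "decrease" else "increase",
               t = unname(tt$statistic), df = unname(tt$parameter),
               pvalue = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$padj <- p.adjust(out$pvalue, method = "BH")
  out
}

#' Mann-Whitney comparison of flow-cytometry proportions
#'
#' Per cell type, a two-sided Mann-Whitney U test of percentage composition
#' between conditions: exact when the pooled sample size is at most 20 (and
#' untied), normal approximation with tie/continuity correction otherwise.
#' Fully tied inputs return p = 1 with a warning.
#'
#' @param percents data.frame or matrix, samples x cell types, of
#'   percentage compositions.
#' @param condition Vector of control/AT labels aligned to rows.
#' @return data.frame per cell type with \code{U} (statistic for the
#'   control group) and \code{pvalue}.
#' @export
compareFlowProportions <- function(percents, condition) {
  percents <- as.data.frame(percents)
  if (length(condition) != nrow(percents))
    stop("condition must align with percent-table rows")
  a <- condition == "control"; b <- condition == "AT"
  if (sum(a) == 0 || sum(b) == 0) stop("both groups must be non-empty")
  out <- lapply(colnames(percents), function(ct) {
    x <- percents[[ct]][a]; y <- percents[[ct]][b]
    n <- length(x) + length(y)
    if (length(unique(c(x, y))) == 1L) {
      warning("all values tied for '", ct, "'; p set to 1")
      return(data.frame(cell_type = ct, U = length(x) * length(y) / 2,
                        pvalue = 1))
    }
    wt <- suppressWarnings(
      wilcox.test(x, y, exact = n <= 20, correct = TRUE))
    data.frame(cell_type = ct, U = unname(wt$statistic), pvalue = wt$p.value)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
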