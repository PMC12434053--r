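## Preranked gene-set enrichment, gene-set scoring with group contrasts,
## set construction from external DE tables, signature-panel tests and the
## transcriptomic age axis.

#' Build a preranked gene list
#'
#' Removes low-expressed genes (baseMean strictly below
#' \code{basemeanMin}) to reduce noise, then orders the remainder by the
#' test statistic, descending, ties broken by gene identifier.
#'
#' @param de \code{\link{fitDE}}-style data.frame with \code{gene},
#'   \code{stat}, \code{baseMean}.
#' @param basemeanMin Filter threshold (default 10).
#' @return data.frame with \code{gene} and \code{stat}, ranked.
#' @export
buildRankList <- function(de, basemeanMin = 10) {
  if (nrow(de) == 0) stop("empty DE table")
  if (anyDuplicated(de$gene)) stop("duplicate gene identifiers in DE table")
  keep <- de$baseMean >= basemeanMin
  if (!any(keep)) stop("all genes removed by the baseMean filter")
  out <- de[keep, c("gene", "stat")]
  out <- out[order(-out$stat, out$gene), ]
  rownames(out) <- NULL
  out
}

## Enrichment score of one set against a ranked list: weighted running sum,
## hit increments proportional to |stat|^weight (normalized to sum 1), miss
## decrements 1/(N - n). Returns the signed maximum deviation and the
## position of the extremum.
esRunningSum <- function(stat, hit, weight = 1) {
  N <- length(stat); n <- sum(hit)
  w <- abs(stat)^weight
  w[!hit] <- 0
  tot <- sum(w)
  if (tot == 0) { w[hit] <- 1; tot <- n }   # all-zero stats: equal weights
  steps <- ifelse(hit, w / tot, -1 / (N - n))
  rs <- cumsum(steps)
  i <- which.max(abs(rs))
  list(es = rs[i], peak = i, running = rs)
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov-like enrichment score on a preranked
#' list, with a gene-label permutation null: for each set, \code{nPerm}
#' random same-size gene sets are scored; NES is ES divided by the mean
#' |null ES| of matching sign, the nominal p is the same-sign null
#' exceedance fraction, and FDR q follows the standard NES-based procedure
#' (pooled same-sign null NES). Sets smaller than \code{minSize} in the
#' ranked universe, or spanning the entire universe, are skipped with a
#' message.
#'
#' @param ranked \code{\link{buildRankList}} output (or a data.frame with
#'   \code{gene}, \code{stat}, ranked descending).
#' @param sets Named list of gene vectors.
#' @param weight Hit-weight exponent (default 1).
#' @param nPerm Permutations (default 1000; 0 skips inference, ES only).
#' @param minSize Minimum set size in the universe (default 5).
#' @param seed RNG seed for the permutations.
#' @return data.frame per scored set: \code{set}, \code{size}, \code{ES},
#'   \code{NES}, \code{pvalue}, \code{qvalue}, \code{leadingEdge}
#'   (comma-separated gene IDs).
#' @export
gseaPreranked <- function(ranked, sets, weight = 1, nPerm = 1000,
                          minSize = 5, seed = 1) {
  genes <- ranked$gene; stat <- ranked$stat
  if (anyDuplicated(genes)) stop("duplicate genes in ranked list")
  N <- length(genes)
  set.seed(as.integer(seed))
  keep <- vapply(sets, function(s) {
    n <- sum(s %in% genes)
    n >= minSize && n < N
  }, logical(1))
  skipped <- names(sets)[!keep]
  if (length(skipped))
    message("skipping set(s) below minSize or spanning the universe: ",
            paste(skipped, collapse = ", "))
  sets <- sets[keep]
  if (length(sets) == 0) return(data.frame(
    set = character(0), size = integer(0), ES = numeric(0), NES = numeric(0),
    pvalue = numeric(0), qvalue = numeric(0), leadingEdge = character(0)))
  obs <- lapply(sets, function(s) {
    hit <- genes %in% s
    r <- esRunningSum(stat, hit, weight)
    le <- if (r$es >= 0) genes[which(hit & seq_len(N) <= r$peak)]
          else genes[which(hit & seq_len(N) >= r$peak)]
    list(es = r$es, size = sum(hit), leadingEdge = le)
  })
  sizes <- vapply(obs, `[[`, numeric(1), "size")
  es <- vapply(obs, `[[`, numeric(1), "es")
  if (nPerm > 0) {
    nullES <- matrix(NA_real_, nPerm, length(sets))
    for (u in unique(sizes)) {
      cols <- which(sizes == u)
      for (p in seq_len(nPerm)) {
        hit <- logical(N)
        hit[sample.int(N, u)] <- TRUE
        e <- esRunningSum(stat, hit, weight)$es
        nullES[p, cols] <- e
      }
    }
    nes <- numeric(length(sets)); pval <- numeric(length(sets))
    nullNES <- nullES
    for (j in seq_along(sets)) {
      same <- nullES[, j][sign(nullES[, j]) == sign(es[j])]
      denom <- if (length(same)) mean(abs(same)) else NA_real_
      nes[j] <- if (is.na(denom) || denom == 0) NA_real_ else es[j] / denom
      pval[j] <- if (length(same))
        (sum(abs(same) >= abs(es[j])) + 1) / (length(same) + 1) else NA_real_
      ## normalize the null the same way for the FDR pool
      pos <- nullES[, j] >= 0
      mp <- mean(nullES[pos, j]); mn <- mean(abs(nullES[!pos, j]))
      nullNES[pos, j] <- if (is.finite(mp) && mp > 0) nullES[pos, j] / mp else NA
      nullNES[!pos, j] <- if (is.finite(mn) && mn > 0) nullES[!pos, j] / mn else NA
    }
    pool <- as.vector(nullNES)
    qval <- vapply(seq_along(sets), function(j) {
      if (is.na(nes[j])) return(NA_real_)
      if (nes[j] >= 0) {
        nullFrac <- mean(pool >= nes[j], na.rm = TRUE) /
          max(mean(pool >= 0, na.rm = TRUE), .Machine$double.eps)
        obsFrac <- mean(nes[nes >= 0] >= nes[j]) /
          max(mean(nes >= 0), .Machine$double.eps)
      } else {
        nullFrac <- mean(pool <= nes[j], na.rm = TRUE) /
          max(mean(pool < 0, na.rm = TRUE), .Machine$double.eps)
        obsFrac <- mean(nes[nes < 0] <= nes[j]) /
          max(mean(nes < 0), .Machine$double.eps)
      }
      min(1, nullFrac / max(obsFrac, .Machine$double.eps))
    }, numeric(1))
  } else {
    nes <- rep(NA_real_, length(sets))
    pval <- rep(NA_real_, length(sets))
    qval <- rep(NA_real_, length(sets))
  }
  data.frame(set = names(sets), size = as.integer(sizes), ES = es,
             NES = nes, pvalue = pval, qvalue = qval,
             leadingEdge = vapply(obs, function(o)
               paste(o$leadingEdge, collapse = ","), character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build gene sets from an external differential-expression table
#'
#' Per source cluster/state, selects genes with adjusted p strictly below
#' \code{padjMax}, fraction of cells expressing the gene of at least
#' \code{minFrac} (inclusive), and fold change in the requested direction.
#'
#' @param table data.frame with columns \code{cluster}, \code{gene},
#'   \code{padj}, \code{frac}, \code{log2FC}.
#' @param padjMax Strict upper bound on padj (default 0.05).
#' @param minFrac Inclusive lower bound on the expressing fraction
#'   (default 0.25).
#' @param direction \code{"up"} or \code{"down"}.
#' @return Named list of gene vectors (one per cluster with passing genes).
#' @export
buildSetsFromDE <- function(table, padjMax = 0.05, minFrac = 0.25,
                            direction = c("up", "down")) {
  direction <- match.arg(direction)
  need <- c("cluster", "gene", "padj", "frac", "log2FC")
  miss <- setdiff(need, colnames(table))
  if (length(miss)) stop("table missing column(s): ",
                         paste(miss, collapse = ", "))
  pass <- table$padj < padjMax & table$frac >= minFrac &
    (if (direction == "up") table$log2FC > 0 else table$log2FC < 0)
  sub <- table[pass, ]
  sets <- split(sub$gene, sub$cluster)
  lapply(sets, unique)
}

#' Gene-set score with a group contrast
#'
#' Per-sample score = mean log2 expression over the set genes (optionally
#' z-scored per gene first); the contrast Delta is the difference of group
#' mean scores (AT - control), a log2 fold change of geometric-mean
#' expression, tested by Welch's t.
#'
#' @param expr log2-scale \code{\link{ExpressionMatrix}}.
#' @param set Gene identifiers (>= 3 must be present).
#' @param condition control/AT labels per sample.
#' @param zscore Z-score each gene across samples first (default FALSE).
#' @return List: \code{scores} (per sample), \code{delta}, \code{t},
#'   \code{df}, \code{pvalue}, \code{nGenes}.
#' @export
geneSetScore <- function(expr, set, condition, zscore = FALSE) {
  stopifnot(is(expr, "ExpressionMatrix"))
  present <- intersect(set, rownames(expr))
  if (length(present) < 3) stop("fewer than 3 set genes present")
  m <- expr@.Data[present, , drop = FALSE]
  if (zscore) {
    sds <- apply(m, 1, sd)
    sds[sds == 0] <- 1
    m <- (m - rowMeans(m)) / sds
  }
  scores <- colMeans(m)
  a <- scores[condition == "control"]; b <- scores[condition == "AT"]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 samples per group")
  tt <- stats::t.test(b, a)   # AT - control
  list(scores = scores, delta = mean(b) - mean(a),
       t = unname(tt$statistic), df = unname(tt$parameter),
       pvalue = tt$p.value, nGenes = length(present))
}

#' Score a collection of gene sets
#'
#' \code{\link{geneSetScore}} over each set, Benjamini-Hochberg correction
#' across the sets scored in one call.
#'
#' @inheritParams geneSetScore
#' @param sets Named list of gene vectors.
#' @return data.frame per set: \code{set}, \code{nGenes}, \code{delta},
#'   \code{t}, \code{pvalue}, \code{padj}.
#' @export
scoreGeneSets <- function(expr, sets, condition, zscore = FALSE) {
  res <- lapply(names(sets), function(nm) {
    r <- geneSetScore(expr, sets[[nm]], condition, zscore)
    data.frame(set = nm, nGenes = r$nGenes, delta = r$delta, t = r$t,
               pvalue = r$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}

#' Signature-panel tests (e.g. A1/A2/PAN, microglial states)
#'
#' Per panel, each gene contributes its control mean and its disease mean;
#' the pooled per-gene means are compared by a paired-across-genes t-test.
#' The per-sample gene-set score contrast is reported alongside.
#' Benjamini-Hochberg correction across panels (applied to both tests).
#'
#' @inheritParams scoreGeneSets
#' @param panels Named list of gene vectors (the signature panels).
#' @return data.frame per panel: paired test (\code{pairedT},
#'   \code{pairedP}, \code{pairedPadj}) and score contrast (\code{delta},
#'   \code{t}, \code{pvalue}, \code{padj}).
#' @export
signaturePanelTest <- function(expr, panels, condition, zscore = FALSE) {
  res <- lapply(names(panels), function(nm) {
    present <- intersect(panels[[nm]], rownames(expr))
    if (length(present) < 3) stop("fewer than 3 panel genes present for '",
                                  nm, "'")
    m <- expr@.Data[present, , drop = FALSE]
    mc <- rowMeans(m[, condition == "control", drop = FALSE])
    ma <- rowMeans(m[, condition == "AT", drop = FALSE])
    pt_ <- stats::t.test(ma, mc, paired = TRUE)
    gs <- geneSetScore(expr, present, condition, zscore)
    data.frame(panel = nm, nGenes = length(present),
               pairedT = unname(pt_$statistic), pairedP = pt_$p.value,
               delta = gs$delta, t = gs$t, pvalue = gs$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pairedPadj <- p.adjust(out$pairedP, method = "BH")
  out$padj <- p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}

#' Transcriptomic age axis
#'
#' PC1 of the significant age-associated genes over all samples, oriented so
#' that the control slope versus age is positive. Control samples define the
#' reference aging line (PC1 ~ age); the acceleration summary is the mean
#' disease PC1 position expressed in control-years minus the mean disease
#' chronological age. When PC1 barely tracks age in controls
#' (|r| < 0.3) the acceleration is undefined and flagged.
#'
#' @param expr log2-scale \code{\link{ExpressionMatrix}} (all samples).
#' @param ageTable \code{\link{ageAssociation}} result.
#' @param age Ages in years per sample.
#' @param condition control/AT labels per sample.
#' @param padjMax Significance cutoff for age genes (default 0.05).
#' @return List: \code{genes}, \code{pc1} (per sample), \code{controlFit}
#'   (intercept, slope), \code{conditionFits}, \code{controlCor},
#'   \code{acceleration} (years), \code{flagged}.
#' @export
transcriptomicAgeAxis <- function(expr, ageTable, age, condition,
                                  padjMax = 0.05) {
  stopifnot(is(expr, "ExpressionMatrix"))
  genes <- ageTable$gene[!is.na(ageTable$padj) & ageTable$padj < padjMax]
  if (length(genes) < 5) stop("fewer than 5 significant age genes")
  ctrl <- condition == "control"
  if (diff(range(age[ctrl])) < 20)
    stop("control samples must span >= 20 years of age")
  pca <- runPCA(new("ExpressionMatrix", expr@.Data, scaleTag = scaleTag(expr)),
                genes = genes)
  pc1 <- pca$scores[, 1]
  fit <- lm(pc1[ctrl] ~ age[ctrl])
  if (coef(fit)[2] < 0) {           # orient: control aging increases PC1
    pc1 <- -pc1
    fit <- lm(pc1[ctrl] ~ age[ctrl])
  }
  r <- cor(pc1[ctrl], age[ctrl])
  fits <- lapply(split(seq_along(pc1), condition), function(ix)
    coef(lm(pc1[ix] ~ age[ix])))
  flagged <- abs(r) < 0.3
  accel <- if (flagged) NA_real_ else {
    b <- coef(fit)
    (mean(pc1[!ctrl]) - b[1]) / b[2] - mean(age[!ctrl])
  }
  list(genes = genes, pc1 = pc1,
       controlFit = c(intercept = unname(coef(fit)[1]),
                      slope = unname(coef(fit)[2])),
       conditionFits = fits, controlCor = r,
       acceleration = unname(accel), flagged = flagged)
}
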