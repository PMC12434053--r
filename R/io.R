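## Readers/writers for the plain-text formats the pipeline touches, plus
## normalization, variable-gene selection and PCA shared by later stages.

sortedCellTypes <- function() setdiff(CELL_TYPES, "unsorted")

checkCountValues <- function(m, where) {
  if (anyNA(m) || any(!is.finite(m)))
    stop("non-finite count in ", where)
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative count in ", where, " at gene '",
         rownames(m)[bad[1, 1]], "', sample '", colnames(m)[bad[1, 2]], "'")
  invisible(TRUE)
}

#' Read a gene-by-sample count matrix
#'
#' TSV layout: header row of sample IDs, first column gene IDs,
#' tab-separated. MTX layout: MatrixMarket coordinate file with sidecar
#' \code{genes.txt} / \code{samples.txt} (one identifier per line) next to it.
#' Input order is preserved; values are validated as finite and non-negative
#' and identifiers as unique.
#'
#' @param path Path to the TSV or MTX file.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @param transpose Set \code{TRUE} if the TSV is samples-by-genes; the
#'   result is always genes-by-samples (never guessed).
#' @return Numeric genes-by-samples matrix.
#' @export
readCounts <- function(path, format = c("tsv", "mtx"), transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed header in ", path,
                           ": need gene column plus at least one sample")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
      stop("duplicate gene identifier '", ids[duplicated(ids)][1],
           "' in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      badcol <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
      stop("non-numeric value in ", path, ", sample column '",
           colnames(df)[-1][badcol], "'")
    }
    rownames(m) <- ids
    storage.mode(m) <- "double"
    if (anyDuplicated(colnames(m)))
      stop("duplicate sample identifier in ", path)
    if (transpose) m <- t(m)
    checkCountValues(m, path)
    return(m)
  }
  ## MatrixMarket with sidecars
  dir <- dirname(path)
  gf <- file.path(dir, "genes.txt"); sf <- file.path(dir, "samples.txt")
  if (!file.exists(gf) || !file.exists(sf))
    stop("mtx sidecar files genes.txt/samples.txt not found next to ", path)
  m <- as.matrix(Matrix::readMM(path))
  genes <- readLines(gf); samples <- readLines(sf)
  if (anyDuplicated(genes)) stop("duplicate gene identifier in ", gf)
  if (anyDuplicated(samples)) stop("duplicate sample identifier in ", sf)
  if (transpose) m <- t(m)
  if (nrow(m) != length(genes) || ncol(m) != length(samples))
    stop("mtx shape ", nrow(m), "x", ncol(m),
         " does not match sidecar lengths")
  dimnames(m) <- list(genes, samples)
  checkCountValues(m, path)
  m
}

#' Write a count matrix as TSV
#'
#' Inverse of \code{\link{readCounts}} for the TSV layout; integer counts
#' round-trip bit-identically.
#'
#' @param counts genes-by-samples matrix.
#' @param path Output path.
#' @export
writeCounts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' CSV with header; required columns \code{sample_id}, \code{donor_id},
#' \code{cell_type}, \code{condition}, \code{age}; optional \code{sex},
#' \code{pmi}, \code{batch}. \code{cell_type} must come from the controlled
#' vocabulary in \code{\link{CELL_TYPES}} and \code{condition} from
#' \{control, AT\}.
#'
#' @param path Path to the CSV file.
#' @return data.frame, one row per sample.
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validateMetadata(df)
}

validateMetadata <- function(df) {
  need <- c("sample_id", "donor_id", "cell_type", "condition", "age")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  bad <- setdiff(unique(df$cell_type), CELL_TYPES)
  if (length(bad))
    stop("unknown cell_type '", bad[1], "'; allowed: ",
         paste(CELL_TYPES, collapse = ", "))
  badc <- setdiff(unique(df$condition), c("control", "AT"))
  if (length(badc))
    stop("unknown condition '", badc[1], "'; allowed: control, AT")
  if (any(df$age < 0)) stop("age must be >= 0")
  df
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then gene IDs, tab-separated
#' (MSigDB convention). Duplicated genes within a set are dropped with a
#' warning; empty sets and duplicated set names are errors.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; descriptions kept in
#'   \code{attr(, "description")}.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 tab-separated fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set name: ",
                              nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    if (length(g) == 0) stop("empty gene set '", f[1], "'")
    if (anyDuplicated(g)) {
      warning("duplicated gene in set '", f[1], "'; deduplicated")
      g <- unique(g)
    }
    g
  })
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(fields, `[[`, character(1), 2L), nm)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named character vector of descriptions.
#' @export
writeGMT <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- setNames(rep("na", length(sets)),
                                                    names(sets))
  lines <- vapply(names(sets), function(n)
    paste(c(n, description[[n]], sets[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-million normalization of raw counts
#'
#' Scales every sample (column) to counts per million; optionally
#' log-transforms as \code{log2(cpm + pseudocount)}. No gene-length
#' correction is applied: with intron-inclusive nuclear counting a length
#' correction is ill-defined, so the per-million scale is used throughout.
#'
#' @param counts genes-by-samples non-negative matrix.
#' @param log If \code{TRUE} return the log2 scale.
#' @param pseudocount Added before log2 (default 1).
#' @return \code{\link{ExpressionMatrix}} tagged \code{"linear_pm"} or
#'   \code{"log2_pm"}.
#' @examples
#' cnt <- matrix(c(1, 1, 2), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
#' normalizeCounts(cnt)[, 1]   # 250000 250000 500000
#' @export
normalizeCounts <- function(counts, log = FALSE, pseudocount = 1) {
  checkCountValues(counts, "counts")
  tot <- colSums(counts)
  if (any(tot == 0))
    stop("zero-total sample: ", colnames(counts)[which(tot == 0)[1]])
  pm <- sweep(counts, 2, tot, "/") * 1e6
  if (log) new("ExpressionMatrix", log2(pm + pseudocount), scaleTag = "log2_pm")
  else new("ExpressionMatrix", pm, scaleTag = "linear_pm")
}

#' Top variable genes
#'
#' The \code{n} genes with the largest across-sample variance of log2
#' expression; ties broken by gene identifier order for reproducibility.
#'
#' @param expr log2-scale \code{\link{ExpressionMatrix}}.
#' @param n Number of genes (default 500).
#' @return Character vector of gene IDs.
#' @export
topVariableGenes <- function(expr, n = 500) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (scaleTag(expr) != "log2_pm")
    stop("topVariableGenes expects log2_pm expression")
  if (n <= 0) stop("n must be positive")
  if (n > nrow(expr)) stop("n exceeds the number of genes")
  v <- apply(expr@.Data, 1, var)
  ord <- order(-v, rownames(expr))
  rownames(expr)[ord[seq_len(n)]]
}

#' Principal component analysis of expression
#'
#' Gene-wise centered PCA over samples on a chosen gene subset. Sign
#' convention: each loading vector's largest-magnitude entry is positive,
#' making results deterministic.
#'
#' @param expr \code{\link{ExpressionMatrix}} (any scale; log2 recommended).
#' @param genes Genes to use (default: all).
#' @return List with \code{scores} (samples x components), \code{loadings}
#'   (genes x components) and \code{explainedVariance} per component.
#' @export
runPCA <- function(expr, genes = rownames(expr)) {
  if (ncol(expr) < 2) stop("PCA needs at least 2 samples")
  miss <- setdiff(genes, rownames(expr))
  if (length(miss)) stop("genes not in expression matrix: ", miss[1])
  x <- t(as.matrix(expr)[genes, , drop = FALSE])  # samples x genes
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ## sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       explainedVariance = pc$sdev^2)
}
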