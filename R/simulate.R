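## Synthetic sorted/unsorted nuclear RNA-seq cohorts with known ground truth:
## composition, marker structure, RNA-content factors, ambient contamination,
## donor effects. Every downstream stage is validated against these truths.

#' Control cerebellar composition preset
#'
#' Nuclei fractions of the eight sorted cerebellar cell types in control
#' tissue. Granule 0.70, Purkinje 0.007, astrocyte 0.022 and
#' oligodendrocyte 0.013 follow the deconvolution estimates reported for
#' control cerebellum; the remaining four types (basket 0.060, Golgi 0.020,
#' OPC 0.065, microglia 0.113) are configuration defaults that close the
#' simplex and are not literature claims.
#'
#' @return Named numeric vector summing to 1.
#' @export
controlCerebellum <- function() {
  c(granule = 0.70, basket = 0.060, golgi = 0.020, purkinje = 0.007,
    astrocyte = 0.022, microglia = 0.113, oligodendrocyte = 0.013,
    opc = 0.065)
}

#' Disease effect preset (A-T cerebellum)
#'
#' Published fold changes of cell-type abundance in ataxia-telangiectasia
#' versus control cerebellum: losses of Purkinje (1.85x), granule (1.35x),
#' Golgi (1.52x) and basket (1.45x) neurons; gains of oligodendrocytes
#' (2x), OPCs (1.35x), astrocytes (1.37x) and microglia (1.44x).
#'
#' @return data.frame with columns \code{cell_type}, \code{fold},
#'   \code{direction}.
#' @export
atEffects <- function() {
  data.frame(
    cell_type = c("purkinje", "granule", "golgi", "basket",
                  "oligodendrocyte", "opc", "astrocyte", "microglia"),
    fold = c(1.85, 1.35, 1.52, 1.45, 2.0, 1.35, 1.37, 1.44),
    direction = c("decrease", "decrease", "decrease", "decrease",
                  "increase", "increase", "increase", "increase"),
    stringsAsFactors = FALSE)
}

#' Build a ground-truth reference
#'
#' Draws per-cell-type mean expression profiles with a planted marker
#' structure. Background gene means are log-normal (log2 mean 1, sd 1) with
#' a small independent per-type log-normal deviation (\code{typeDevSd} on
#' the log2 scale) so cell types differ genome-wide, as real sorted profiles
#' do. Marker genes are modelled as balanced panels: each panel gene has the
#' same base magnitude (\code{markerBase}) in every cell type and is
#' enriched \code{boost}-fold in its own type only, mirroring the strong,
#' magnitude-matched enrichment of canonical sorted-nuclei markers. Balanced
#' panels keep the comparative rest-average representative of every
#' non-target type (see the methods vignette).
#'
#' @param nGenes Total genes (default 2000).
#' @param cellTypes Cell-type labels (default the eight sorted types).
#' @param markersPerType Markers planted per type (default 30).
#' @param boost Marker enrichment factor, >= 1 (default 300).
#' @param dispersion Per-gene NB dispersion (inverse size), recycled
#'   (default 0.1).
#' @param typeDevSd log2 sd of the dense per-type deviation (default 0.1).
#' @param markerBase Base magnitude of marker genes (default 0.5).
#' @param seed RNG seed.
#' @return \code{\link{GroundTruthReference}}.
#' @export
makeReference <- function(nGenes = 2000, cellTypes = setdiff(CELL_TYPES, "unsorted"),
                          markersPerType = 30, boost = 300, dispersion = 0.1,
                          typeDevSd = 0.1, markerBase = 0.5, seed = 1) {
  K <- length(cellTypes)
  if (K < 2) stop("need at least two cell types")
  if (boost < 1) stop("boost must be >= 1")
  if (nGenes < K * markersPerType)
    stop("marker demand (", K * markersPerType, ") exceeds gene count (",
         nGenes, ")")
  seed <- as.integer(seed)
  set.seed(seed)
  genes <- sprintf("GENE%05d", seq_len(nGenes))
  base <- 2^rnorm(nGenes, 1, 1)
  dev <- if (typeDevSd > 0) {
    matrix(2^rnorm(nGenes * K, 0, typeDevSd), nGenes, K)
  } else matrix(1, nGenes, K)
  profiles <- base * dev
  dimnames(profiles) <- list(genes, cellTypes)
  midx <- sample.int(nGenes, K * markersPerType)
  markers <- split(genes[midx], rep(cellTypes, each = markersPerType))
  markers <- markers[cellTypes]
  for (k in seq_len(K)) {
    rows <- markers[[k]]
    profiles[rows, ] <- markerBase
    profiles[rows, k] <- markerBase * boost
  }
  new("GroundTruthReference", profiles = profiles, markers = markers,
      dispersion = rep_len(dispersion, nGenes), boost = boost, seed = seed)
}

#' Apply a single composition effect
#'
#' Multiplies (increase) or divides (decrease) one cell type's fraction by
#' \code{fold}; the compensating mass is taken from / added to the granule
#' fraction, the dominant population. When the target is granule itself the
#' compensating mass is spread over the other types proportionally to their
#' preset fractions. The result stays on the simplex. One effect per cohort
#' keeps every printed abundance ratio exactly reproducible, which a joint
#' application of all effects cannot do (the published per-type ratios are
#' not simplex-consistent).
#'
#' @param preset Named composition vector (sums to 1).
#' @param target Cell type to perturb.
#' @param fold Positive fold change.
#' @param direction \code{"decrease"} or \code{"increase"}.
#' @return Named composition vector on the simplex.
#' @export
singleEffectComposition <- function(preset, target,
                                    fold, direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  if (!target %in% names(preset)) stop("target '", target, "' not in preset")
  if (fold <= 0) stop("fold must be > 0")
  w <- preset
  newf <- if (direction == "decrease") w[[target]] / fold else w[[target]] * fold
  if (newf < 0 || newf > 1) stop("resulting fraction outside [0, 1]")
  delta <- w[[target]] - newf
  w[[target]] <- newf
  if (target == "granule") {
    others <- setdiff(names(preset), "granule")
    w[others] <- w[others] + delta * preset[others] / sum(preset[others])
  } else {
    g <- w[["granule"]] + delta
    if (g < 0 || g > 1) stop("resulting fraction outside [0, 1]")
    w[["granule"]] <- g
  }
  if (abs(sum(w) - 1) > 1e-9) stop("internal error: composition off simplex")
  w
}

nbSample <- function(mu, dispersion) {
  size <- ifelse(dispersion > 0, 1 / dispersion, Inf)
  n <- length(mu)
  out <- numeric(n)
  pois <- !is.finite(size)
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois],
                                        size = size[!pois])
  out
}

drawLibsize <- function(n, libsize, libsizeSd) {
  rlnorm(n, log(libsize), libsizeSd)
}

makeSampleRow <- function(sample_id, donor_id, cell_type, condition, age,
                          sex, batch) {
  data.frame(sample_id = sample_id, donor_id = donor_id,
             cell_type = cell_type, condition = condition, age = age,
             sex = sex, pmi = NA_real_, batch = batch,
             stringsAsFactors = FALSE)
}

buildSE <- function(counts, meta, truth) {
  rownames(meta) <- meta$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta))
  S4Vectors::metadata(se)$truth <- truth
  se
}

#' Simulate a sorted (FANS-purified) cohort
#'
#' One sample per (donor, cell type). Counts are negative binomial around
#' \code{libsize * p} where \code{p} is the per-gene proportion vector of
#' \code{(1 - alpha) * own profile + alpha * ambient}, the ambient pool
#' being the control-composition-weighted mixture of all profiles (granule
#' dominated, emulating ambient RNA in droplet-based data when
#' \code{alpha > 0}). A per-donor per-gene log-normal effect (sd
#' \code{donorSd} on the natural log) is shared across that donor's samples.
#'
#' @param ref \code{\link{GroundTruthReference}}.
#' @param donorsPerType Donors (= samples per cell type).
#' @param ambientAlpha Ambient contamination rate in [0, 1).
#' @param condition Condition label for all samples.
#' @param ages Range ages are drawn from, uniformly (default 8-96).
#' @param libsize,libsizeSd Log-normal library-size model (default 2e6, 0.2).
#' @param donorSd Donor effect sd on the natural-log scale (default 0.1).
#' @param seed RNG seed.
#' @return \code{SummarizedExperiment} with a \code{counts} assay, sample
#'   metadata in \code{colData} and ground truth in
#'   \code{metadata(se)$truth}.
#' @export
simulateSorted <- function(ref, donorsPerType = 3, ambientAlpha = 0,
                           condition = "control", ages = c(8, 96),
                           libsize = 2e6, libsizeSd = 0.2, donorSd = 0.1,
                           seed = 1) {
  stopifnot(is(ref, "GroundTruthReference"))
  if (donorsPerType < 1) stop("donorsPerType must be >= 1")
  if (ambientAlpha < 0 || ambientAlpha >= 1)
    stop("ambientAlpha must be in [0, 1)")
  set.seed(as.integer(seed))
  prof <- ref@profiles
  types <- colnames(prof)
  G <- nrow(prof)
  wAmb <- controlCerebellum()[types]
  ambient <- as.vector(prof %*% (wAmb / sum(wAmb)))
  donors <- sprintf("%s_D%02d", condition, seq_len(donorsPerType))
  donorEff <- matrix(rlnorm(G * donorsPerType, 0, donorSd), G, donorsPerType,
                     dimnames = list(rownames(prof), donors))
  donorAge <- round(runif(donorsPerType, ages[1], ages[2]), 1)
  donorSex <- sample(c("M", "F"), donorsPerType, replace = TRUE)
  nS <- donorsPerType * length(types)
  counts <- matrix(0L, G, nS, dimnames = list(rownames(prof), NULL))
  meta <- NULL
  compo <- matrix(0, nS, length(types), dimnames = list(NULL, types))
  alphaVec <- numeric(nS)
  j <- 0
  for (d in seq_len(donorsPerType)) {
    for (ct in types) {
      j <- j + 1
      own <- prof[, ct] / sum(prof[, ct])
      mix <- (1 - ambientAlpha) * own + ambientAlpha * ambient / sum(ambient)
      mu <- mix * donorEff[, d]
      mu <- mu / sum(mu) * drawLibsize(1, libsize, libsizeSd)
      counts[, j] <- nbSample(mu, ref@dispersion)
      sid <- sprintf("%s_%s", donors[d], ct)
      meta <- rbind(meta, makeSampleRow(sid, donors[d], ct, condition,
                                        donorAge[d], donorSex[d], "b1"))
      compo[j, ] <- (1 - ambientAlpha) * (types == ct) +
        ambientAlpha * wAmb / sum(wAmb)
      alphaVec[j] <- ambientAlpha
    }
  }
  colnames(counts) <- meta$sample_id
  rownames(compo) <- meta$sample_id
  buildSE(counts, meta,
          list(composition = compo, alpha = alphaVec, rho = NULL,
               reference = ref, seed = as.integer(seed)))
}

#' Simulate an unsorted (bulk nuclei) cohort
#'
#' Mixture samples with known composition. The expected per-gene mRNA pool
#' is proportional to \code{sum_c w_c * rho_c * profile_c}, with \code{w}
#' the nuclei fractions and \code{rho} per-type RNA-content factors (all 1
#' by default; with \code{rho} equal to 1 the expected mRNA fraction equals
#' the nuclei fraction). Each sample gets its own donor (log-normal per-gene
#' effect) and a log-normal library size; counts are negative binomial.
#'
#' @param ref \code{\link{GroundTruthReference}}.
#' @param preset Named composition vector over the reference cell types.
#' @param nSamples Number of unsorted samples.
#' @param rho Named RNA-content factors (default 1 for every type).
#' @param condition Condition label.
#' @param ages Age range, drawn uniformly.
#' @param libsize,libsizeSd,donorSd As in \code{\link{simulateSorted}}.
#' @param seed RNG seed.
#' @return \code{SummarizedExperiment}; ground truth in
#'   \code{metadata(se)$truth}.
#' @export
simulateUnsorted <- function(ref, preset = controlCerebellum(), nSamples = 25,
                             rho = NULL, condition = "control",
                             ages = c(8, 96), libsize = 2e6, libsizeSd = 0.2,
                             donorSd = 0.1, seed = 1) {
  stopifnot(is(ref, "GroundTruthReference"))
  prof <- ref@profiles
  types <- colnames(prof)
  if (!all(types %in% names(preset)))
    stop("preset must name every reference cell type")
  w <- preset[types]
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("preset must be non-negative and sum to 1")
  if (is.null(rho)) rho <- setNames(rep(1, length(types)), types)
  if (!all(types %in% names(rho))) stop("rho must name every cell type")
  rho <- rho[types]
  if (any(rho <= 0)) stop("rho must be strictly positive")
  set.seed(as.integer(seed))
  G <- nrow(prof)
  mixture <- as.vector(prof %*% (w * rho))
  mixture <- mixture / sum(mixture)
  counts <- matrix(0L, G, nSamples, dimnames = list(rownames(prof), NULL))
  meta <- NULL
  donorAge <- round(runif(nSamples, ages[1], ages[2]), 1)
  donorSex <- sample(c("M", "F"), nSamples, replace = TRUE)
  for (j in seq_len(nSamples)) {
    de <- rlnorm(G, 0, donorSd)
    mu <- mixture * de
    mu <- mu / sum(mu) * drawLibsize(1, libsize, libsizeSd)
    counts[, j] <- nbSample(mu, ref@dispersion)
    did <- sprintf("%s_U%02d", condition, j)
    meta <- rbind(meta, makeSampleRow(paste0(did, "_unsorted"), did,
                                      "unsorted", condition, donorAge[j],
                                      donorSex[j], "b1"))
  }
  colnames(counts) <- meta$sample_id
  compo <- matrix(rep(w, each = nSamples), nSamples, length(types),
                  dimnames = list(meta$sample_id, types))
  buildSE(counts, meta,
          list(composition = compo, alpha = rep(0, nSamples), rho = rho,
               preset = preset, reference = ref, seed = as.integer(seed)))
}
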