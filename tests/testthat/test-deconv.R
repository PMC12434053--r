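test_that("signature construction averages per type deterministically", {
  ref <- makeReference(nGenes = 200, markersPerType = 5, seed = 20)
  se <- simulateSorted(ref, donorsPerType = 1, seed = 20)
  expr <- normalizeCounts(SummarizedExperiment::assay(se))
  md <- as.data.frame(SummarizedExperiment::colData(se))
  S <- buildSignatureMatrix(expr, md)
  ## one sample per type: columns equal those samples' expression
  for (ct in colnames(S)) {
    sid <- md$sample_id[md$cell_type == ct]
    expect_equal(unname(S@.Data[, ct]), unname(expr@.Data[, sid]))
  }
  ## duplicating a sample leaves the mean unchanged
  expr2 <- new("ExpressionMatrix",
               cbind(expr@.Data, dup = expr@.Data[, 1]),
               scaleTag = "linear_pm")
  md2 <- rbind(md, within(md[1, ], sample_id <- "dup"))
  colnames(expr2@.Data)[ncol(expr2)] <- "dup"
  S2 <- buildSignatureMatrix(expr2, md2)
  ct1 <- md$cell_type[1]
  expect_equal(S2@.Data[, ct1], S@.Data[, ct1])

  keep <- md$cell_type != "golgi"
  expr3 <- new("ExpressionMatrix", expr@.Data[, keep],
               scaleTag = "linear_pm")
  expect_error(buildSignatureMatrix(expr3, md[keep, ]), "golgi")
})

test_that("signature columns track the truth profiles", {
  ref <- makeReference(nGenes = 400, markersPerType = 10, boost = 32,
                       dispersion = 0.01, seed = 21)
  se <- simulateSorted(ref, donorsPerType = 3, ambientAlpha = 0, seed = 21)
  expr <- normalizeCounts(SummarizedExperiment::assay(se))
  md <- as.data.frame(SummarizedExperiment::colData(se))
  mk <- unlist(ref@markers)
  S <- buildSignatureMatrix(expr, md, genes = mk)
  tru <- truthSignature(ref, genes = mk)
  for (ct in colnames(S))
    expect_gt(cor(S@.Data[, ct], tru@.Data[, ct]), 0.99)
})

test_that("global deconvolution is exact on noise-free mixtures", {
  ref <- makeReference(nGenes = 300, markersPerType = 8, seed = 22)
  S <- truthSignature(ref, genes = unlist(ref@markers))
  ## a pure signature column returns the unit vector at zero residual
  x <- S@.Data[, "purkinje"]
  f <- deconvolveGlobal(x, S)
  expect_equal(f$purkinje, 1, tolerance = 1e-9)
  expect_lt(f$residualNorm, 1e-6)

  ## an exact 50/50 mixture of two signatures
  x2 <- 0.5 * S@.Data[, "granule"] + 0.5 * S@.Data[, "astrocyte"]
  f2 <- deconvolveGlobal(x2, S)
  expect_equal(f2$granule, 0.5, tolerance = 1e-6)
  expect_equal(f2$astrocyte, 0.5, tolerance = 1e-6)

  ## fractions live on the simplex
  cols <- setdiff(colnames(f2), c("sample", "residualNorm", "converged"))
  expect_equal(sum(f2[, cols]), 1, tolerance = 1e-8)
  expect_true(all(f2[, cols] >= 0))
})

test_that("solver objective matches the simplex grid-search oracle", {
  set.seed(23)
  for (i in 1:8) {
    K <- sample(2:4, 1)
    G <- sample(20:60, 1)
    S <- matrix(runif(G * K, 0, 5), G, K,
                dimnames = list(sprintf("g%03d", 1:G), paste0("t", 1:K)))
    w <- runif(K); w <- w / sum(w)
    x <- as.vector(S %*% w) + rnorm(G, 0, 0.05)
    sig <- new("SignatureMatrix", S, provenance = "test")
    f <- deconvolveGlobal(x, sig)
    myObj <- f$residualNorm^2
    gridObj <- gridObjective(x, S, step = 0.001)
    expect_lte(myObj, gridObj + 1e-6)
  }
})

test_that("rescaled mode makes fractions scale invariant", {
  ref <- makeReference(nGenes = 200, markersPerType = 5, seed = 24)
  S <- truthSignature(ref, genes = unlist(ref@markers))
  w <- controlCerebellum()[colnames(S)]
  x <- as.vector(S@.Data %*% w)
  f1 <- deconvolveGlobal(x, S, rescale = TRUE)
  f2 <- deconvolveGlobal(17 * x, S, rescale = TRUE)
  cols <- colnames(S)
  expect_equal(f1[, cols], f2[, cols], tolerance = 1e-9)
  expect_equal(unname(unlist(f1[, cols])), unname(w), tolerance = 1e-6)
})

test_that("global fractions recover the simulated composition", {
  ## parameter recovery at the stated conditions: rho = 1, alpha = 0
  ref <- makeReference(seed = 25)
  se <- simulateUnsorted(ref, nSamples = 25, seed = 25)
  expr <- normalizeCounts(SummarizedExperiment::assay(se))
  S <- truthSignature(ref, genes = unlist(ref@markers))
  f <- deconvolveGlobal(expr, S)
  truth <- S4Vectors::metadata(se)$truth$composition
  est <- as.matrix(f[, colnames(truth)])
  rmse <- sqrt(rowMeans((est - truth)^2))
  expect_lt(mean(rmse), 0.02)
})

test_that("RNA-content bias shifts mRNA fractions in the expected direction", {
  ## smaller granule RNA content: estimated granule mRNA fraction must
  ## underrepresent the nuclei fraction in essentially every sample
  ref <- makeReference(nGenes = 800, markersPerType = 15, seed = 26)
  rho <- setNames(rep(1, 8), colnames(ref@profiles))
  rho["granule"] <- 0.5
  se <- simulateUnsorted(ref, nSamples = 25, rho = rho, seed = 26)
  expr <- normalizeCounts(SummarizedExperiment::assay(se))
  S <- truthSignature(ref, genes = unlist(ref@markers))
  f <- deconvolveGlobal(expr, S)
  under <- f$granule < 0.70
  expect_gte(mean(under), 24 / 25)   # sign test, one-sided
})

test_that("comparative panels and fractions behave on exact inputs", {
  ref <- makeReference(nGenes = 300, markersPerType = 8, seed = 27)
  S <- truthSignature(ref)
  panels <- buildComparativePanels(S, markers = ref@markers)
  expect_length(panels, 8)
  ## rest-specific genes are excluded from each panel
  expect_false(any(ref@markers$granule %in%
                     rownames(panels$purkinje@panel)))
  expect_true(all(ref@markers$purkinje %in%
                    rownames(panels$purkinje@panel)))

  p <- panels$purkinje
  ## pure target: fraction 1; pure rest mean: fraction 0; exact blend: 0.3
  expect_equal(deconvolveComparative(p@panel[, 1], p)$fraction, 1,
               tolerance = 1e-9)
  expect_equal(deconvolveComparative(p@panel[, 2], p)$fraction, 0,
               tolerance = 1e-9)
  mix <- 0.3 * p@panel[, 1] + 0.7 * p@panel[, 2]
  expect_equal(deconvolveComparative(mix, p)$fraction, 0.3,
               tolerance = 1e-6)

  ## two-type signature: panels are each other's columns
  S2 <- new("SignatureMatrix", S@.Data[, c("granule", "purkinje")],
            provenance = "test")
  p2 <- buildComparativePanels(S2)
  expect_equal(p2$granule@panel[, "rest"], p2$purkinje@panel[, "target"])

  ## identical signatures are rejected
  Sbad <- new("SignatureMatrix",
              cbind(a = S@.Data[, 1], b = S@.Data[, 1]),
              provenance = "test")
  expect_error(buildComparativePanels(Sbad), "identical")
})

test_that("condition contrasts match the direct Welch formula", {
  fr <- data.frame(sample = paste0("s", 1:6),
                   target = "purkinje",
                   fraction = c(0.4, 0.5, 0.6, 0.1, 0.2, 0.3))
  cond <- c(rep("control", 3), rep("AT", 3))
  ct <- contrastConditions(fr, cond)
  expect_equal(ct$fold, 2.5)
  expect_equal(ct$direction, "decrease")
  ## hand-computed Welch t: mean diff 0.3, var 0.01 each, n = 3
  tHand <- 0.3 / sqrt(0.01 / 3 + 0.01 / 3)
  dfHand <- (0.01 / 3 + 0.01 / 3)^2 /
    ((0.01 / 3)^2 / 2 + (0.01 / 3)^2 / 2)
  expect_equal(ct$t, tHand, tolerance = 1e-12)
  expect_equal(ct$df, dfHand, tolerance = 1e-12)
  expect_equal(ct$pvalue, 2 * pt(-tHand, dfHand), tolerance = 1e-12)

  ## identical groups: fold 1, p ~= 1
  fr2 <- fr; fr2$fraction <- rep(c(0.2, 0.3, 0.4), 2)
  ct2 <- contrastConditions(fr2, cond)
  expect_equal(ct2$fold, 1)
  expect_gt(ct2$pvalue, 0.95)

  expect_error(contrastConditions(fr[1:4, ], cond[1:4]), ">= 2")
})

test_that("BH correction spans the cell types of one contrast run", {
  set.seed(28)
  fr <- do.call(rbind, lapply(c("a", "b", "c"), function(ct)
    data.frame(sample = paste0(ct, 1:8), target = ct,
               fraction = c(rnorm(4, 0.5, 0.02), rnorm(4, 0.3, 0.02)))))
  cond <- rep(c(rep("control", 4), rep("AT", 4)), 3)
  ct <- contrastConditions(fr, cond)
  expect_equal(ct$padj, p.adjust(ct$pvalue, "BH"))
  expect_true(all(ct$padj >= ct$pvalue))
})

test_that("flow-proportion Mann-Whitney matches exhaustive enumeration", {
  tbl <- data.frame(astro = c(5, 6, 7, 1, 2, 3))
  cond <- c(rep("control", 3), rep("AT", 3))
  mw <- compareFlowProportions(tbl, cond)
  expect_equal(mw$U, 9)       # maximal separation
  expect_equal(mw$pvalue, 0.1)  # 2 of C(6,3) = 20 arrangements as extreme

  ## identical groups: U = n1 n2 / 2
  tbl2 <- data.frame(astro = rep(c(1, 2, 3), 2))
  mw2 <- suppressWarnings(compareFlowProportions(tbl2, cond))
  expect_equal(mw2$U, 4.5)

  expect_error(compareFlowProportions(tbl, rep("control", 6)), "non-empty")
  expect_warning(compareFlowProportions(data.frame(x = rep(1, 6)), cond),
                 "tied")
})
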