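test_that("rank lists apply the strict baseMean filter and a total order", {
  de <- data.frame(gene = paste0("g", 1:5),
                   baseMean = c(12, 9, 10, 3, 100),
                   stat = c(1, 5, 2, 4, 3))
  rl <- buildRankList(de, basemeanMin = 10)
  expect_setequal(rl$gene, c("g1", "g3", "g5"))  # 9 and 3 removed, 10 kept
  expect_equal(rl$gene, c("g5", "g3", "g1"))     # stat descending

  deTie <- data.frame(gene = c("b", "a"), baseMean = c(50, 50),
                      stat = c(1, 1))
  expect_equal(buildRankList(deTie)$gene, c("a", "b"))

  expect_error(buildRankList(de[c(1, 1), ]), "duplicate")
  expect_error(buildRankList(de, basemeanMin = 1e6), "all genes removed")
})

test_that("enrichment scores equal the brute-force running sum exactly", {
  ## hand-checkable case: set = top 2 of 10 equal-|stat| genes
  genes <- paste0("g", 1:10)
  stat <- rep(1, 10)
  ranked <- data.frame(gene = genes, stat = stat)
  res <- gseaPreranked(ranked, list(top = genes[1:2]), nPerm = 0,
                       minSize = 2)
  ## running sum: +1/2 at 1,2 then -1/8 each: max is 1 after position 2
  expect_equal(res$ES, 1)
  expect_equal(res$leadingEdge, "g1,g2")

  set.seed(31)
  for (i in 1:40) {
    N <- sample(20:200, 1)
    genes <- sprintf("r%04d", seq_len(N))
    stat <- sort(rnorm(N), decreasing = TRUE)
    n <- sample(3:15, 1)
    set <- sample(genes, n)
    ranked <- data.frame(gene = genes, stat = stat)
    got <- gseaPreranked(ranked, list(s = set), nPerm = 0, minSize = 3)$ES
    expect_identical(got, bruteForceES(genes, stat, set))
  }
})

test_that("ES agrees with fgsea's score on clean cases", {
  skip_if_not_installed("fgsea")
  set.seed(32)
  N <- 100
  genes <- sprintf("f%03d", 1:N)
  stat <- sort(rnorm(N), decreasing = TRUE)
  names(stat) <- genes
  sets <- list(a = sample(genes, 10), b = sample(genes, 20))
  mine <- gseaPreranked(data.frame(gene = genes, stat = stat), sets,
                        nPerm = 0, minSize = 3)
  ref <- suppressWarnings(
    fgsea::fgsea(sets, stat, minSize = 3, maxSize = N, nPermSimple = 101))
  expect_equal(mine$ES[match(ref$pathway, mine$set)], ref$ES,
               tolerance = 1e-12)
})

test_that("degenerate sets are skipped and permutations are reproducible", {
  genes <- paste0("g", 1:30)
  ranked <- data.frame(gene = genes, stat = seq(3, -3, length.out = 30))
  expect_message(
    res <- gseaPreranked(ranked, list(all = genes, tiny = genes[1:2],
                                      ok = genes[1:8]),
                         nPerm = 100, seed = 7),
    "skipping")
  expect_equal(res$set, "ok")
  res2 <- suppressMessages(
    gseaPreranked(ranked, list(all = genes, tiny = genes[1:2],
                               ok = genes[1:8]), nPerm = 100, seed = 7))
  expect_identical(res, res2)
})

test_that("planted enrichment is detected with q below 0.05", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    N <- 400
    genes <- sprintf("p%04d", 1:N)
    stat <- sort(rnorm(N), decreasing = TRUE)
    planted <- genes[1:20]                 # the largest stats
    decoys <- lapply(1:5, function(i) sample(genes, 20))
    names(decoys) <- paste0("d", 1:5)
    res <- gseaPreranked(data.frame(gene = genes, stat = stat),
                         c(list(planted = planted), decoys),
                         nPerm = 200, seed = s)
    row <- res[res$set == "planted", ]
    row$NES > 0 && row$qvalue < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("gene sets built from DE tables follow the boundary rules", {
  tbl <- data.frame(cluster = rep("MG01", 4),
                    gene = paste0("g", 1:4),
                    padj = c(0.04, 0.05, 0.04, 0.01),
                    frac = c(0.25, 0.9, 0.24, 0.5),
                    log2FC = c(1, 1, 1, -1))
  up <- buildSetsFromDE(tbl, direction = "up")
  ## padj 0.05 excluded (strict), frac 0.25 included (inclusive),
  ## frac 0.24 excluded, downregulated gene excluded
  expect_equal(up$MG01, "g1")
  dn <- buildSetsFromDE(tbl, direction = "down")
  expect_equal(dn$MG01, "g4")
  expect_error(buildSetsFromDE(tbl[, -3]), "padj")
})

test_that("gene-set scores match hand arithmetic and invariances", {
  ## toy 2-gene set, 2 + 2 samples with printed values
  m <- rbind(gA = c(1, 3, 5, 7), gB = c(2, 4, 6, 8))
  colnames(m) <- paste0("s", 1:4)
  cond <- c("control", "control", "AT", "AT")
  gs <- geneSetScore(exprFrom(rbind(m, gC = rep(0, 4))),
                     c("gA", "gB", "gC"), cond)
  scores <- colMeans(rbind(m, 0))
  expect_equal(unname(gs$scores), unname(scores))
  expect_equal(gs$delta, mean(scores[3:4]) - mean(scores[1:2]))
  tt <- t.test(scores[3:4], scores[1:2])
  expect_equal(gs$t, unname(tt$statistic))
  expect_equal(gs$pvalue, tt$p.value)

  ## doubling every set gene (linear scale) in one group moves delta by 1
  set.seed(33)
  base <- matrix(runif(6 * 8, 2, 6), 6, 8,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  cond2 <- rep(c("control", "AT"), each = 4)
  doubled <- base
  doubled[, cond2 == "AT"] <- doubled[, cond2 == "AT"] + 1  # log2 of x2
  d0 <- geneSetScore(exprFrom(base), paste0("g", 1:6), cond2)
  d1 <- geneSetScore(exprFrom(doubled), paste0("g", 1:6), cond2)
  expect_equal(d1$delta - d0$delta, 1, tolerance = 1e-12)

  ## invariance to a per-gene constant shared across samples
  shift <- matrix(rep(runif(6, 0, 2), 8), 6, 8)
  d2 <- geneSetScore(exprFrom(base + shift), paste0("g", 1:6), cond2)
  expect_equal(d2$delta, d0$delta, tolerance = 1e-12)

  ## identical groups: delta 0
  same <- base[, c(1:4, 1:4)]
  colnames(same) <- paste0("s", 1:8)
  dSame <- geneSetScore(exprFrom(same), paste0("g", 1:6), cond2)
  expect_equal(dSame$delta, 0)

  expect_error(geneSetScore(exprFrom(base), c("g1", "g2"), cond2), "3 set")
})

test_that("signature-panel tests recover planted activation directions", {
  set.seed(34)
  G <- 80; n <- 20
  cond <- rep(c("control", "AT"), each = 10)
  m <- matrix(rnorm(G * n, 6, 0.4), G, n,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:n)))
  a1 <- sprintf("g%03d", 1:20)    # upregulated x1.5 (log2 ~ 0.585)
  a2 <- sprintf("g%03d", 21:40)   # unchanged
  pan <- sprintf("g%03d", 41:60)  # upregulated
  m[c(1:20, 41:60), cond == "AT"] <- m[c(1:20, 41:60), cond == "AT"] +
    log2(1.5)
  res <- signaturePanelTest(exprFrom(pmax(m, 0)),
                            list(A1 = a1, A2 = a2, PAN = pan), cond)
  expect_equal(nrow(res), 3)
  expect_gt(res$delta[res$panel == "A1"], 0.4)
  expect_lt(abs(res$delta[res$panel == "A2"]), 0.15)
  expect_lt(res$pairedPadj[res$panel == "A1"], 0.01)
  expect_lt(res$pairedPadj[res$panel == "PAN"], 0.01)
  expect_equal(res$pairedPadj, p.adjust(res$pairedP, "BH"))
})

test_that("the transcriptomic age axis recovers planted acceleration", {
  coh <- makeAgingCohort(seed = 35)
  aa <- ageAssociation(coh$expr, coh$age, subset = coh$condition == "control")
  ax <- transcriptomicAgeAxis(coh$expr, aa, coh$age, coh$condition)
  expect_false(ax$flagged)
  expect_equal(ax$acceleration, 50, tolerance = 10)
  expect_gt(ax$controlFit["slope"], 0)

  ## disease samples on the control aging line: acceleration ~ 0
  coh0 <- makeAgingCohort(atChronAge = 40, atExprAge = 40, seed = 36)
  aa0 <- ageAssociation(coh0$expr, coh0$age,
                        subset = coh0$condition == "control")
  ax0 <- transcriptomicAgeAxis(coh0$expr, aa0, coh0$age, coh0$condition)
  expect_lt(abs(ax0$acceleration), 10)

  ## orientation rule: inverting the expression scale flips every loading,
  ## but PC1 is re-oriented to the control aging line, so the acceleration
  ## is unchanged
  flipped <- exprFrom(max(coh$expr@.Data) - coh$expr@.Data)
  axF <- transcriptomicAgeAxis(flipped, aa, coh$age, coh$condition)
  expect_equal(axF$acceleration, ax$acceleration, tolerance = 1e-6)
})
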