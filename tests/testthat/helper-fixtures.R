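## Shared fixtures and independent oracles, built in code at test time.

tinyCounts <- function() {
  matrix(c(1, 5, 0,
           2, 5, 4), nrow = 3,
         dimnames = list(c("GA", "GB", "GC"), c("s1", "s2")))
}

exprFrom <- function(m, tag = "log2_pm") {
  new("ExpressionMatrix", m, scaleTag = tag)
}

## Toy specificity-index fixture: 4 genes x 3 types, one sample per type.
siToy <- function() {
  m <- cbind(T1 = c(10, 6, 0, 2),
             T2 = c(0, 5, 8, 2),
             T3 = c(0, 4, 0, 9))
  rownames(m) <- paste0("g", 1:4)
  exprFrom(m)
}

## Independent brute-force GSEA running sum: the running sum is re-derived
## from scratch at every list position (O(N * N) evaluation of the
## definition), rather than accumulated.
bruteForceES <- function(genes, stat, set, weight = 1) {
  N <- length(genes)
  hit <- genes %in% set
  n <- sum(hit)
  w <- abs(stat)^weight
  tot <- sum(w[hit])
  if (tot == 0) { w[] <- 1; tot <- n }
  steps <- ifelse(hit, w / tot, -1 / (N - n))
  vals <- vapply(seq_len(N), function(i) sum(steps[seq_len(i)]), numeric(1))
  vals[which.max(abs(vals))]
}

## Exhaustive / refined simplex grid search oracle for the deconvolution
## objective ||x - S f||^2. Exact full grid for K <= 3; for K = 4 a full
## 0.01 grid plus a 0.001 refinement box around the coarse optimum (the
## objective is convex, so the refined local box contains the grid optimum).
gridObjective <- function(x, S, step = 0.001) {
  K <- ncol(S)
  evalF <- function(F) {           # F: K x m candidate fractions
    best <- Inf
    m <- ncol(F)
    bs <- 20000L
    for (i0 in seq(1, m, by = bs)) {
      ii <- i0:min(i0 + bs - 1L, m)
      R <- x - S %*% F[, ii, drop = FALSE]
      best <- min(best, min(colSums(R^2)))
    }
    best
  }
  gridK <- function(lo, hi, st) {
    sq <- lapply(seq_len(K - 1), function(i) seq(lo[i], hi[i], by = st))
    G <- as.matrix(expand.grid(sq))
    last <- 1 - rowSums(G)
    ok <- last >= -1e-12
    F <- t(cbind(G[ok, , drop = FALSE], pmax(last[ok], 0)))
    F
  }
  if (K <= 3) {
    evalF(gridK(rep(0, K - 1), rep(1, K - 1), step))
  } else {
    F0 <- gridK(rep(0, K - 1), rep(1, K - 1), 0.01)
    obj0 <- apply(F0, 2, function(f) sum((x - S %*% f)^2))
    f0 <- F0[, which.min(obj0)]
    lo <- pmax(f0[seq_len(K - 1)] - 0.01, 0)
    hi <- pmin(f0[seq_len(K - 1)] + 0.01, 1)
    evalF(gridK(lo, hi, step))
  }
}

## Planted-aging-program expression: nAgeGenes genes rise with age at
## `slope` log2-units/year; disease samples sit at a young chronological age
## but express an old transcriptome. Returns expr, age, condition.
makeAgingCohort <- function(nCtrl = 30, nAT = 10, nAgeGenes = 100,
                            nNullGenes = 200, slope = 0.05,
                            atChronAge = 20, atExprAge = 70, noiseSd = 0.3,
                            seed = 1) {
  set.seed(seed)
  ageCtrl <- runif(nCtrl, 10, 90)
  age <- c(ageCtrl, rep(atChronAge, nAT))
  exprAge <- c(ageCtrl, rep(atExprAge, nAT))
  G <- nAgeGenes + nNullGenes
  base <- runif(G, 4, 8)
  m <- matrix(0, G, nCtrl + nAT,
              dimnames = list(sprintf("AG%04d", seq_len(G)),
                              sprintf("s%02d", seq_len(nCtrl + nAT))))
  for (j in seq_len(ncol(m))) {
    mu <- base
    mu[seq_len(nAgeGenes)] <- mu[seq_len(nAgeGenes)] + slope * exprAge[j]
    m[, j] <- pmax(mu + rnorm(G, 0, noiseSd), 0)
  }
  list(expr = exprFrom(m), age = age,
       condition = c(rep("control", nCtrl), rep("AT", nAT)))
}
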