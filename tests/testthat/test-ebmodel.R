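test_that("GRM has VanRaden structure: duplicates, scaling, eigen contract", {
  geno <- makeToyGeno(60, 80, seed = 4)
  # duplicate an individual's genotypes
  h1 <- hapMatrix(geno, 1); h2 <- hapMatrix(geno, 2)
  h1[2, ] <- h1[1, ]; h2[2, ] <- h2[1, ]
  m <- markerMap(geno)
  dup <- PhasedGenotypes(h1, h2, chrom = as.character(GenomeInfoDb::seqnames(m)),
                         pos = GenomicRanges::start(m),
                         ref = S4Vectors::mcols(m)$ref,
                         alt = S4Vectors::mcols(m)$alt)
  kin <- grm(dup)
  K <- kinshipMatrix(kin)
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])
  # VanRaden normalization: mean diagonal near 1 for unrelated individuals
  kin2 <- grm(makeToyGeno(400, 300, seed = 16))
  expect_equal(mean(diag(kinshipMatrix(kin2))), 1, tolerance = 0.05)
  # decomposition reconstructs K
  recon <- eigenVectors(kin2) %*% (eigenValues(kin2) * t(eigenVectors(kin2)))
  expect_lt(max(abs(recon - kinshipMatrix(kin2))), 1e-8)
  expect_true(all(diff(eigenValues(kin2)) <= 1e-12))
  # all-monomorphic panel is an error
  gm <- PhasedGenotypes(matrix(0L, 10, 2), matrix(0L, 10, 2),
                        chrom = c("1", "1"), pos = c(1L, 2L) * 100L,
                        ref = c("A", "A"), alt = c("C", "C"))
  expect_error(grm(gm), "monomorphic")
})

.manualBlock <- function(hapPair, nHaps, freqs = NULL) {
  n <- nrow(hapPair)
  if (is.null(freqs)) {
    cnt <- tabulate(c(hapPair), nbins = nHaps)
    freqs <- cnt / (2 * n)
  }
  haps <- c("00", "01", "10", "11")[seq_len(nHaps)]
  new("HaplotypeBlock", blockId = "toy", chrom = "1",
      markerIndices = 1:2, startBp = 100, endBp = 200,
      haplotypes = haps, hapPair = hapPair, frequencies = freqs)
}

test_that("Z rows reproduce the worked inheritance patterns", {
  hp <- rbind(c(1L, 2L),   # carries first and second haplotypes
              c(3L, 3L),   # homozygote for the third
              c(4L, 1L),
              c(2L, 2L),
              c(1L, 3L), c(2L, 4L), c(1L, 4L), c(3L, 2L), c(1L, 2L),
              c(4L, 4L))
  b <- .manualBlock(hp, 4L)
  Z <- buildZ(b, minHapCount = 1L)
  expect_equal(unname(Z[1, ]), c(1, 1, 0, 0))
  expect_equal(unname(Z[2, ]), c(0, 0, 2, 0))
  expect_true(all(rowSums(Z) == 2))
  expect_true(all(apply(Z, 1, function(r) sum(r != 0)) <= 2))
})

test_that("rare haplotypes pool into one column and keep rows summing to 2", {
  set.seed(6)
  hp <- cbind(sample(1:2, 40, TRUE), sample(1:2, 40, TRUE))
  hp[1, ] <- c(3L, 4L)  # two singleton haplotypes
  b <- .manualBlock(hp, 4L)
  Z <- buildZ(b, minHapCount = 5L)
  expect_equal(colnames(Z)[3], "rare")
  expect_equal(ncol(Z), 3L)
  expect_equal(unname(Z[1, ]), c(0, 0, 2))
  expect_true(all(rowSums(Z) == 2))
  # a block with one dominant haplotype and scattered rares is skipped
  hp2 <- cbind(rep(1L, 40), c(rep(1L, 36), 2L, 3L, 4L, 2L))
  expect_error(buildZ(.manualBlock(hp2, 4L), minHapCount = 5L),
               class = "blockSkipped")
})

test_that("the identity-covariance limit reduces to OLS REML", {
  set.seed(10)
  n <- 50; X <- cbind(1, rnorm(n)); y <- rnorm(n)
  Z <- randomZ(n, 3)
  d <- sort(runif(n, 0.2, 3), decreasing = TRUE)  # arbitrary spectrum
  L <- profiledRemlLoglik(y, X, Z, d, 0, 0)
  rss <- sum(stats::lm.fit(X, y)$residuals^2)
  Lols <- -0.5 * as.numeric(determinant(crossprod(X))$modulus) -
    (n - 2) / 2 * log(rss)
  expect_equal(L, Lols, tolerance = 1e-10)
})

test_that("eigen-accelerated likelihood and effects match the dense oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 40; h <- sample(2:6, 1)
    K <- randomPDKinship(n, seed + 100)
    e <- eigen(K, symmetric = TRUE)
    kin <- new("KinshipEigen", K = K, U = e$vectors, values = e$values)
    y <- rnorm(n); X <- cbind(1, rnorm(n))
    Z <- randomZ(n, h)
    lk <- runif(1, 0.05, 1); l <- runif(1, 0.05, 2)
    td <- eigenTransform(kin, y, X, Z)
    dense <- denseBlockStats(y, X, Z, K, lk, l)
    expect_equal(profiledRemlLoglik(td$yStar, td$XStar, td$ZStar, td$d, lk, l),
                 dense$loglik, tolerance = 1e-8)
    eff <- blockEffects(td$yStar, td$XStar, td$ZStar, td$d, lk, l)
    expect_lt(max(abs(eff$gammaHat - dense$gamma)), 1e-8)
    expect_lt(max(abs(eff$gammaCov - dense$gammaCov)), 1e-8)
    mme <- hendersonGamma(y, X, Z, K, lk, l)
    expect_lt(max(abs(eff$gammaHat - mme$gamma)), 1e-8)
    expect_lt(max(abs(eff$betaHat - mme$beta)), 1e-8)
  }
})

test_that("likelihood is invariant to phenotype location given an intercept", {
  set.seed(9)
  n <- 60
  K <- randomPDKinship(n, 9)
  e <- eigen(K, symmetric = TRUE)
  kin <- new("KinshipEigen", K = K, U = e$vectors, values = e$values)
  y <- rnorm(n); X <- matrix(1, n, 1); Z <- randomZ(n, 4)
  t1 <- eigenTransform(kin, y, X, Z)
  t2 <- eigenTransform(kin, y + 17.3, X, Z)
  L1 <- profiledRemlLoglik(t1$yStar, t1$XStar, t1$ZStar, t1$d, 0.2, 0.5)
  L2 <- profiledRemlLoglik(t2$yStar, t2$XStar, t2$ZStar, t2$d, 0.2, 0.5)
  expect_lt(abs(L1 - L2), 1e-10)
})

test_that("likelihood is invariant to reordering the eigenbasis", {
  set.seed(11)
  n <- 30
  y <- rnorm(n); X <- matrix(1, n, 1); Z <- randomZ(n, 3)
  d <- sort(runif(n, 0, 2), decreasing = TRUE)
  L <- profiledRemlLoglik(y, X, Z, d, 0.4, 0.8)
  perm <- sample(n)
  Lp <- profiledRemlLoglik(y[perm], X[perm, , drop = FALSE],
                           Z[perm, ], d[perm], 0.4, 0.8)
  expect_equal(L, Lp, tolerance = 1e-10)
})

test_that("fitted likelihood dominates the null corner and sigma2 is positive", {
  cfg <- simConfig(nIndividuals = 250, nBlocks = 12, nCausalBlocks = 2L,
                   h2Block = 0.1, h2Polygenic = 0.3, blockLd = 1, seed = 77)
  geno <- simulateGenotypes(cfg)
  sim <- simulatePhenotypes(geno, cfg)
  kin <- grm(geno)
  scan <- scanBlocks(geno, sim$phenotype, plantedBlocks(geno), kinship = kin)
  res <- results(scan)
  expect_true(all(res$sigma2 > 0))
  td <- eigenTransform(kin, sim$phenotype[individualIds(geno)])
  for (id in res$block_id[res$converged]) {
    b <- Filter(function(x) x@blockId == id, plantedBlocks(geno))[[1]]
    Zs <- crossprod(eigenVectors(kin), buildZ(b))
    L0 <- profiledRemlLoglik(td$yStar, td$XStar, Zs, td$d, 1e-13, 1e-13)
    expect_gte(res$loglik[res$block_id == id], L0 - 1e-6)
  }
})

test_that("the Wald statistic behaves at its reference points", {
  # gammaCov entirely zero: W = 0, p = 1
  f0 <- new("BlockFit", blockId = "z", lambda = 0.1, lambdaK = 0,
            sigma2 = 1, betaHat = 0, gammaHat = c(0, 0),
            gammaCov = matrix(0, 2, 2), W = 0, p = 1, loglik = 0,
            converged = TRUE, nIter = 1L, hapLabels = c("a", "b"))
  expect_equal(waldTest(f0), list(W = 0, p = 1))
  # chi-square quantile identity: W = 3.841459 gives p near 0.05
  v <- c(1, -1) / sqrt(2)
  gcov <- 0.5 * tcrossprod(v)
  gam <- sqrt(3.841459 * 0.5) * v
  f1 <- new("BlockFit", blockId = "q", lambda = 0.1, lambdaK = 0.2,
            sigma2 = 1, betaHat = 0, gammaHat = gam, gammaCov = gcov,
            W = 0, p = 1, loglik = 0, converged = TRUE, nIter = 1L,
            hapLabels = c("a", "b"))
  wt <- waldTest(f1)
  expect_equal(wt$W, 3.841459, tolerance = 1e-6)
  expect_equal(wt$p, 0.05, tolerance = 1e-4)
  # df = "rank" option uses the covariance rank instead
  wt2 <- waldTest(f1, remlControl(df = "rank"))
  expect_equal(wt2$p, pchisq(wt2$W, 1, lower.tail = FALSE))
})

test_that("a strong causal block attains the minimum p in a scan", {
  cfg <- simConfig(nIndividuals = 500, nBlocks = 20, nCausalBlocks = 1L,
                   h2Block = 0.25, h2Polygenic = 0.2, blockLd = 1, seed = 88)
  geno <- simulateGenotypes(cfg)
  sim <- simulatePhenotypes(geno, cfg)
  scan <- scanBlocks(geno, sim$phenotype, plantedBlocks(geno))
  res <- results(scan)
  expect_equal(res$block_id[which.min(res$p)], sim$truth@causalBlockIds[1])
  # determinism: identical inputs give an identical table
  scan2 <- scanBlocks(geno, sim$phenotype, plantedBlocks(geno))
  expect_identical(res, results(scan2))
})

test_that("scans validate id alignment and tolerate empty block lists", {
  geno <- makeToyGeno(30, 6, seed = 3)
  y <- stats::setNames(rnorm(30), paste0("x", 1:30))
  expect_error(scanBlocks(geno, y, list()), "mismatch")
  y2 <- stats::setNames(rnorm(30), individualIds(geno))
  empty <- scanBlocks(geno, y2, list())
  expect_s4_class(empty, "ScanResult")
  expect_equal(nrow(results(empty)), 0L)
})

test_that("the single-SNP path is the block path with a one-column design", {
  cfg <- simConfig(nIndividuals = 200, nBlocks = 4, nCausalBlocks = 1L,
                   h2Block = 0.2, h2Polygenic = 0.2, blockLd = 1, seed = 23)
  geno <- simulateGenotypes(cfg)
  sim <- simulatePhenotypes(geno, cfg)
  kin <- grm(geno)
  snp <- singleSnpScan(geno, sim$phenotype, kinship = kin, markers = 1:3)
  td <- eigenTransform(kin, sim$phenotype[individualIds(geno)])
  for (j in 1:3) {
    Zs <- crossprod(eigenVectors(kin), dosage(geno)[, j, drop = FALSE])
    fit <- fitBlock(td$yStar, td$XStar, Zs, td$d)
    expect_equal(results(snp)$W[j], fit@W, tolerance = 1e-10)
    expect_equal(results(snp)$p[j], fit@p, tolerance = 1e-10)
  }
  expect_true(all(results(snp)$n_snps == 1L))
})

test_that("single-SNP scan localizes a causal marker", {
  cfg <- simConfig(nIndividuals = 600, nBlocks = 15, nCausalBlocks = 1L,
                   h2Block = 0.25, h2Polygenic = 0.2, blockLd = 1,
                   snpsPerBlock = 2L, haplotypePool = "pair", seed = 61)
  geno <- simulateGenotypes(cfg)
  sim <- simulatePhenotypes(geno, cfg)
  snp <- singleSnpScan(geno, sim$phenotype)
  res <- results(snp)
  sb <- S4Vectors::mcols(markerMap(geno))$simBlock
  causalIdx <- which(sprintf("sim%04d", sb) == sim$truth@causalBlockIds[1])
  expect_lt(min(res$p[causalIdx]), median(res$p))
})
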