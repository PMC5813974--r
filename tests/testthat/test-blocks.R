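test_that("dprimeCI recognizes complete LD and independence", {
  # perfectly coupled: only "00" and "11" chromosomes observed
  a <- rep(c(0L, 1L), c(300, 200)); b <- a
  ci <- dprimeCI(a, b)
  expect_equal(ci$dprime, 1)
  expect_equal(ci$upper, 1)
  expect_gt(ci$lower, 0.9)
  # independent markers at 2n = 2000: point estimate near zero
  set.seed(14)
  x <- rbinom(2000, 1, 0.4); y <- rbinom(2000, 1, 0.3)
  ci2 <- dprimeCI(x, y)
  expect_lt(ci2$dprime, 0.2)
  expect_lt(ci2$upper, 0.9)
})

test_that("dprimeCI is invariant to marker order and allele relabeling", {
  set.seed(2)
  for (rep in 1:5) {
    x <- rbinom(400, 1, runif(1, 0.1, 0.9))
    y <- ifelse(rbinom(400, 1, 0.7) == 1, x, rbinom(400, 1, 0.5))
    if (var(x) == 0 || var(y) == 0) next
    ci <- dprimeCI(x, y)
    expect_equal(dprimeCI(y, x), ci)
    expect_equal(dprimeCI(1L - x, y), ci)
    expect_equal(dprimeCI(x, 1L - y), ci)
  }
})

test_that("dprimeCI rejects in-sample monomorphic markers", {
  expect_error(dprimeCI(rep(0L, 100), rbinom(100, 1, 0.5)), "monomorphic")
})

test_that("haplotype enumeration counts, orders and labels correctly", {
  # chromosomes split 3:1 between "01" and "10"
  h1 <- rbind(c(0L, 1L), c(0L, 1L), c(0L, 1L), c(1L, 0L))
  h2 <- rbind(c(0L, 1L), c(0L, 1L), c(1L, 0L), c(0L, 1L))
  geno <- PhasedGenotypes(h1, h2, chrom = c("1", "1"), pos = c(10L, 20L),
                          ref = c("A", "A"), alt = c("C", "C"))
  b <- enumerateHaplotypes(geno, 1:2)
  expect_equal(b@haplotypes, c("01", "10"))
  expect_equal(b@frequencies, c(0.75, 0.25))
  expect_equal(unname(b@hapPair[4, ]), c(2L, 1L))
  # all homozygous for one haplotype
  gmono <- PhasedGenotypes(matrix(0L, 5, 2), matrix(0L, 5, 2),
                           chrom = c("1", "1"), pos = c(10L, 20L),
                           ref = c("A", "A"), alt = c("C", "C"))
  bm <- enumerateHaplotypes(gmono, 1:2)
  expect_equal(bm@haplotypes, "00")
  expect_equal(bm@frequencies, 1)
  expect_error(enumerateHaplotypes(geno, c(1L, 3L)), "consecutive")
})

test_that("haplotype frequencies equal a brute-force chromosome tally", {
  geno <- makeToyGeno(60, 4, seed = 31)
  b <- enumerateHaplotypes(geno, 2:4)
  A <- rbind(hapMatrix(geno, 1)[, 2:4], hapMatrix(geno, 2)[, 2:4])
  strings <- apply(A, 1, paste, collapse = "")
  for (k in seq_along(b@haplotypes)) {
    expect_equal(b@frequencies[k],
                 sum(strings == b@haplotypes[k]) / nrow(A))
  }
  expect_equal(sum(b@frequencies), 1, tolerance = 1e-12)
  # descending frequency, lexicographic ties
  expect_true(all(diff(b@frequencies) <= 0))
})

test_that("gabrielBlocks recovers planted perfect-LD blocks exactly", {
  pc <- plantedChromosome(c(2, 3, 4, 3, 2), n = 300, seed = 7)
  found <- gabrielBlocks(pc$geno)
  expect_length(found, length(pc$truth))
  for (k in seq_along(found))
    expect_equal(found[[k]]@markerIndices, as.integer(pc$truth[[k]]))
  # ids follow the <size>-<counter> convention and never overlap
  ids <- vapply(found, function(b) b@blockId, character(1))
  expect_equal(ids, c("B2-1", "B3-1", "B4-1", "B3-2", "B2-2"))
  allIdx <- unlist(lapply(found, function(b) b@markerIndices))
  expect_equal(anyDuplicated(allIdx), 0L)
})

test_that("mutually independent markers produce no blocks", {
  geno <- makeToyGeno(400, 12, seed = 19)
  expect_length(gabrielBlocks(geno), 0L)
})

test_that("gabrielBlocks matches exhaustive window evaluation on small maps", {
  for (seed in c(101, 202, 303)) {
    cfg <- simConfig(nIndividuals = 150, nBlocks = 4,
                     snpsPerBlock = c(2L, 3L, 2L, 3L), blockLd = 0.92,
                     interBlockSpacingBp = 5000L, seed = seed)
    geno <- simulateGenotypes(cfg)
    expect_lte(nMarkers(geno), 10L)
    got <- gabrielBlocks(geno, maxWindow = nMarkers(geno))
    want <- bruteGabriel(geno)
    expect_length(got, length(want))
    for (k in seq_along(got))
      expect_equal(got[[k]]@markerIndices, as.integer(want[[k]]))
  }
})

test_that("oversized strong-LD runs are split into chunks of at most four", {
  # 6-marker perfect-LD run: expect a 4-SNP block then a 2-SNP block
  set.seed(55)
  n <- 300
  f <- 0.35
  hap <- rbinom(2 * n, 1, f)
  A <- matrix(rep(hap, 6), ncol = 6)
  geno <- PhasedGenotypes(A[1:n, ], A[n + 1:n, ], chrom = rep("1", 6),
                          pos = seq(1000L, by = 500L, length.out = 6),
                          ref = rep("A", 6), alt = rep("C", 6))
  found <- gabrielBlocks(geno)
  expect_equal(lapply(found, function(b) as.integer(b@markerIndices)),
               list(1:4, 5:6))
})
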