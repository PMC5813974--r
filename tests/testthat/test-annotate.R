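.toyGenes <- function() {
  GenomicRanges::GRanges(
    seqnames = c("1", "1", "1", "2"),
    ranges = IRanges::IRanges(start = c(20000, 40000, 90000, 1000),
                              end = c(30000, 44000, 95000, 4000)),
    gene_name = c("GENE_A", "GENE_B", "GENE_C", "GENE_D"))
}

test_that("nearest gene reports Within, gaps and out-of-window misses", {
  genes <- .toyGenes()
  snps <- data.frame(chrom = c("1", "1", "1", "1", "3"),
                     pos = c(25000, 10000, 160000, 41000, 100))
  expect_message(ann <- nearestGene(snps, genes), "chromosome 3")
  expect_equal(ann$gene[1], "GENE_A")
  expect_equal(ann$distance[1], 0)
  expect_true(ann$within[1])
  expect_equal(ann$gene[2], "GENE_A")     # gap arithmetic: 20000 - 10000
  expect_equal(ann$distance[2], 10000)
  expect_true(is.na(ann$gene[3]))          # nothing within 50 kb
  expect_equal(ann$distance[4], 0)         # inside GENE_B
  expect_true(is.na(ann$gene[5]))          # unknown chromosome
})

test_that("distance ties break toward the smaller gene start", {
  genes <- GenomicRanges::GRanges(
    seqnames = c("1", "1"),
    ranges = IRanges::IRanges(start = c(1000, 9000), end = c(3000, 11000)),
    gene_name = c("LEFT", "RIGHT"))
  ann <- nearestGene(data.frame(chrom = "1", pos = 6000), genes)
  expect_equal(ann$distance, 3000)
  expect_equal(ann$gene, "LEFT")
})

test_that("nearest gene agrees with an exhaustive scan on random toys", {
  set.seed(20)
  genes <- GenomicRanges::GRanges(
    seqnames = sample(c("1", "2"), 30, TRUE),
    ranges = {
      s <- sort(sample(seq(1000, 900000, by = 1500), 30))
      IRanges::IRanges(start = s, end = s + sample(500:20000, 30, TRUE))
    },
    gene_name = paste0("G", 1:30))
  snps <- data.frame(chrom = sample(c("1", "2"), 100, TRUE),
                     pos = sample(1000:950000, 100))
  ann <- nearestGene(snps, genes, window = 50000)
  gchrom <- as.character(GenomeInfoDb::seqnames(genes))
  for (i in seq_len(100)) {
    d <- ifelse(gchrom != snps$chrom[i], Inf,
                pmax(GenomicRanges::start(genes) - snps$pos[i],
                     snps$pos[i] - GenomicRanges::end(genes), 0))
    if (min(d) > 50000) {
      expect_true(is.na(ann$gene[i]))
    } else {
      expect_equal(ann$distance[i], min(d))
      expect_lte(ann$distance[i], 50000)
      best <- which(d == min(d))
      best <- best[order(GenomicRanges::start(genes)[best])][1]
      expect_equal(ann$gene[i], paste0("G", best))
    }
  }
})

test_that("QTL overlap is a closed-interval intersection on one chromosome", {
  qtls <- data.frame(trait = c("milk zinc", "milk fat", "protein"),
                     chrom = c("1", "1", "2"),
                     start_bp = c(1000, 50000, 1000),
                     end_bp = c(40000, 60000, 90000))
  blk <- list(chrom = "1", startBp = 10000, endBp = 20000)
  expect_equal(qtlOverlap(blk, qtls)$trait, "milk zinc")   # containment
  blk2 <- list(chrom = "3", startBp = 10000, endBp = 20000)
  expect_equal(nrow(qtlOverlap(blk2, qtls)), 0L)           # other chromosome
  blk3 <- list(chrom = "1", startBp = 40000, endBp = 50000)
  expect_equal(qtlOverlap(blk3, qtls)$trait, c("milk zinc", "milk fat"))
  # brute-force pairwise oracle on random intervals, order-invariant
  set.seed(8)
  rq <- data.frame(trait = paste0("t", 1:40),
                   chrom = sample(c("1", "2"), 40, TRUE),
                   start_bp = sample(1:5000, 40))
  rq$end_bp <- rq$start_bp + sample(1:2000, 40)
  for (rep in 1:20) {
    s <- sample(1:6000, 1)
    b <- list(chrom = sample(c("1", "2"), 1), startBp = s, endBp = s + 500)
    got <- qtlOverlap(b, rq)$trait
    want <- rq$trait[sapply(seq_len(40), function(k)
      rq$chrom[k] == b$chrom &&
        max(rq$start_bp[k], b$startBp) <= min(rq$end_bp[k], b$endBp))]
    expect_equal(got, want)
    perm <- sample(40)
    expect_setequal(qtlOverlap(b, rq[perm, ])$trait, want)
  }
})

test_that("gene annotation reads GFF3 and BED through one interface", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("1", "src", "gene", "100", "500", ".", "+", ".",
                     "ID=g1;Name=ALPHA", sep = "\t"),
               paste("1", "src", "mRNA", "100", "500", ".", "+", ".",
                     "ID=t1;Parent=g1", sep = "\t"),
               paste("2", "src", "gene", "900", "1200", ".", "-", ".",
                     "ID=g2;Name=BETA", sep = "\t")), gff)
  g <- readGeneAnnotation(gff)
  expect_equal(sort(g$gene_name), c("ALPHA", "BETA"))
  expect_equal(length(g), 2L)  # mRNA feature dropped
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t99\t500\tALPHA", "2\t899\t1200\tBETA"), bed)
  gb <- readGeneAnnotation(bed)
  expect_equal(GenomicRanges::start(gb), c(100, 900))  # BED is 0-based
  expect_equal(gb$gene_name, c("ALPHA", "BETA"))
})

test_that("favorite alleles follow the substitution-effect sign", {
  # strong positive ALT effect with ALT frequency ~0.7
  set.seed(41)
  n <- 400
  h1 <- cbind(rbinom(n, 1, 0.7), rbinom(n, 1, 0.4))
  h2 <- cbind(rbinom(n, 1, 0.7), rbinom(n, 1, 0.4))
  geno <- PhasedGenotypes(h1, h2, chrom = c("1", "1"), pos = c(100L, 200L),
                          ref = c("A", "A"), alt = c("C", "C"))
  dose <- dosage(geno)
  y <- stats::setNames(0.8 * dose[, 1] - 0.6 * dose[, 2] + rnorm(n, 0, 0.5),
                       individualIds(geno))
  dir <- alleleDirection(geno, y)
  expect_equal(dir$favoriteAllele, c("C", "A"))
  expect_true(dir$favoriteIsMajor[1])   # ALT is major at freq 0.7
  expect_true(dir$favoriteIsMajor[2])   # REF is major at ALT freq 0.4
  # kinship-free oracle: the sign matches ordinary least squares
  ols <- coef(lm(y ~ dose[, 1] + dose[, 2]))[-1]
  expect_equal(sign(dir$altEffect), unname(sign(ols)))
  # the exact-zero tie goes to the major allele
  expect_equal(hapblockEB:::.favoriteAllele(0, "A", "C", "A"), "A")
  expect_equal(hapblockEB:::.favoriteAllele(1e-9, "A", "C", "A"), "C")
  expect_equal(hapblockEB:::.favoriteAllele(-1e-9, "A", "C", "A"), "A")
})
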