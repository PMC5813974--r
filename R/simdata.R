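#' Configure the synthetic population generator
#'
#' Builds a validated \linkS4class{SimConfig}. The generator emulates the
#' statistical structure the block scan assumes: phased biallelic genotypes
#' organized in LD blocks of 2--4 SNPs with MAF >= 0.05, a polygenic
#' covariance induced through genome-wide marker effects (so the realized
#' genomic relationship matrix is exactly the covariance of the polygenic
#' term), additive haplotype effects for a chosen number of causal blocks,
#' and Gaussian residuals. It does not emulate pedigree structure,
#' recombination maps, or the smoothness of EBV phenotypes.
#'
#' @param nIndividuals population size (default 1092, the scale of a
#'   medium dairy cohort).
#' @param nBlocks number of LD blocks to emit.
#' @param snpsPerBlock block sizes. A vector of values in \{2, 3, 4\}: if its
#'   length equals \code{nBlocks} it is used as the exact plan, otherwise
#'   sizes are sampled uniformly from it.
#' @param interBlockSpacingBp,intraBlockSpacingBp bp spacing between blocks
#'   and between markers inside a block.
#' @param mafRange target minor-allele-frequency range; the lower bound must
#'   be at least 0.05 and realized MAFs are enforced by rejection sampling.
#' @param blockLd within-block haplotype coherence in [0, 1]: each allele is
#'   copied from the chromosome's pool haplotype with this probability and
#'   redrawn independently from its marginal frequency otherwise. 1 gives
#'   complete LD (|D'| = 1 within blocks), 0 gives independent markers.
#' @param nCausalBlocks,h2Block number of causal blocks and the phenotypic
#'   variance fraction contributed by each.
#' @param h2Polygenic phenotypic variance fraction of the polygenic term.
#' @param haplotypePool \code{"ladder"} (default): s+1 perfect-phylogeny
#'   haplotypes per s-SNP block, Dirichlet frequencies -- blocks carry
#'   several haplotypes with distinct marker MAFs. \code{"pair"}: two
#'   complementary haplotypes, giving exactly two haplotypes per block.
#' @param seed mandatory integer; all randomness flows from it.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nIndividuals = 1092L, nBlocks = 100L,
                      snpsPerBlock = 2:4,
                      interBlockSpacingBp = 50000L,
                      intraBlockSpacingBp = 500L,
                      mafRange = c(0.05, 0.5), blockLd = 0.9,
                      nCausalBlocks = 3L, h2Block = 0.05,
                      h2Polygenic = 0.3,
                      haplotypePool = c("ladder", "pair"),
                      seed) {
  if (missing(seed)) stop("simConfig: 'seed' is mandatory")
  new("SimConfig",
      nIndividuals = as.integer(nIndividuals),
      nBlocks = as.integer(nBlocks),
      snpsPerBlock = as.integer(snpsPerBlock),
      interBlockSpacingBp = as.integer(interBlockSpacingBp),
      intraBlockSpacingBp = as.integer(intraBlockSpacingBp),
      mafRange = as.numeric(mafRange), blockLd = as.numeric(blockLd),
      nCausalBlocks = as.integer(nCausalBlocks),
      h2Block = as.numeric(h2Block), h2Polygenic = as.numeric(h2Polygenic),
      haplotypePool = match.arg(haplotypePool),
      seed = as.integer(seed))
}

## Pool haplotypes for one block: rows are haplotypes, columns markers.
## "ladder": s+1 haplotypes 000.., 100.., 110.., ... (perfect phylogeny, so
## every marker pair shows at most 3 of the 4 allele combinations and
## |D'| = 1 when blockLd = 1). "pair": complementary all-0/all-1 haplotypes.
.blockPool <- function(s, pool, mafRange, maxTries = 10000L) {
  if (pool == "pair") {
    maf <- runif(1L, mafRange[1], mafRange[2])
    f1 <- if (runif(1L) < 0.5) maf else 1 - maf
    list(haps = rbind(rep(0L, s), rep(1L, s)), freqs = c(1 - f1, f1))
  } else {
    haps <- matrix(0L, s + 1L, s)
    for (i in seq_len(s)) haps[(i + 1L):(s + 1L), i] <- 1L
    for (tries in seq_len(maxTries)) {
      f <- rgamma(s + 1L, 1)
      f <- f / sum(f)
      marg <- as.vector(crossprod(haps, f))
      maf <- pmin(marg, 1 - marg)
      if (all(maf >= mafRange[1] & maf <= mafRange[2]))
        return(list(haps = haps, freqs = f))
    }
    stop("could not draw pool frequencies inside the MAF range")
  }
}

#' Simulate phased genotypes organized in LD blocks
#'
#' Draws, for each block, a pool of ancestral haplotypes and assigns every
#' chromosome an independent pool draw; with probability \code{1 - blockLd}
#' each allele is then redrawn from its marginal frequency, which decays
#' within-block LD. Blocks are mutually independent; there is no pedigree,
#' so relatedness enters downstream analyses only through the realized
#' genomic relationship matrix. Map positions are strictly increasing on a
#' single chromosome \code{"1"}. Realized MAFs below the configured lower
#' bound trigger rejection and resampling of the whole block.
#'
#' The emitted map carries a \code{simBlock} metadata column recording block
#' membership; \code{\link{plantedBlocks}} reconstitutes the blocks from it.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{PhasedGenotypes}.
#' @export
simulateGenotypes <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nIndividuals
  nb <- config@nBlocks
  sizes <- if (length(config@snpsPerBlock) == nb) config@snpsPerBlock
           else if (length(config@snpsPerBlock) == 1L)
             rep.int(config@snpsPerBlock, nb)
           else config@snpsPerBlock[sample.int(length(config@snpsPerBlock),
                                               nb, replace = TRUE)]
  ld <- config@blockLd
  h1 <- vector("list", nb); h2 <- vector("list", nb)
  pos <- integer(0); blockOf <- integer(0)
  cursor <- 10000L
  for (b in seq_len(nb)) {
    s <- sizes[b]
    for (tries in seq_len(1000L)) {
      pool <- .blockPool(s, config@haplotypePool, config@mafRange)
      idx <- sample.int(nrow(pool$haps), 2L * n, replace = TRUE,
                        prob = pool$freqs)
      hapAll <- pool$haps[idx, , drop = FALSE]
      if (ld < 1) {
        marg <- as.vector(crossprod(pool$haps, pool$freqs))
        mut <- matrix(runif(2L * n * s) > ld, 2L * n, s)
        redraw <- matrix(rbinom(2L * n * s, 1L, rep(marg, each = 2L * n)),
                         2L * n, s)
        hapAll[mut] <- redraw[mut]
      }
      f <- colMeans(hapAll)
      if (all(pmin(f, 1 - f) >= config@mafRange[1])) break
      if (tries == 1000L)
        stop("rejection sampling failed to satisfy the MAF floor")
    }
    h1[[b]] <- hapAll[seq_len(n), , drop = FALSE]
    h2[[b]] <- hapAll[n + seq_len(n), , drop = FALSE]
    pos <- c(pos, cursor + seq(0L, by = config@intraBlockSpacingBp,
                               length.out = s))
    blockOf <- c(blockOf, rep.int(b, s))
    cursor <- cursor + (s - 1L) * config@intraBlockSpacingBp +
      config@interBlockSpacingBp
  }
  geno <- PhasedGenotypes(do.call(cbind, h1), do.call(cbind, h2),
                          chrom = rep("1", length(pos)), pos = pos,
                          ref = rep("A", length(pos)),
                          alt = rep("C", length(pos)))
  mcols(geno@map)$simBlock <- blockOf
  geno
}

#' Reconstitute simulated LD blocks from the marker map
#'
#' Groups markers by the \code{simBlock} metadata column written by
#' [simulateGenotypes()] and enumerates each block's haplotypes. Blocks
#' reduced below two markers (e.g. by [mafFilter()]) are dropped with a
#' message.
#'
#' @param geno simulated \linkS4class{PhasedGenotypes}.
#' @return list of \linkS4class{HaplotypeBlock}.
#' @export
plantedBlocks <- function(geno) {
  sb <- mcols(geno@map)$simBlock
  if (is.null(sb))
    stop("genotypes carry no simBlock metadata; not from simulateGenotypes()?")
  out <- list()
  for (b in unique(sb)) {
    idx <- which(sb == b)
    if (length(idx) < 2L) {
      message(sprintf("plantedBlocks: block %d has <2 markers left; dropped", b))
      next
    }
    out[[length(out) + 1L]] <-
      enumerateHaplotypes(geno, idx, blockId = sprintf("sim%04d", b))
  }
  out
}

#' Simulate a quantitative phenotype with recorded ground truth
#'
#' Builds \code{y = intercept + sum_causal Z_k gamma_k + xi + epsilon}.
#' Haplotype effects are drawn \code{gamma_k ~ N(0, phi_k^2 I)} with
#' \code{phi_k^2} scaled so each causal block contributes \code{h2Block} of
#' the unit phenotypic variance in expectation. The polygenic term is built
#' from genome-wide marker effects, \code{xi = W u} with centered dosages
#' \code{W}, so that \code{xi | W ~ N(0, K phi^2)} for the realized VanRaden
#' kinship \code{K} and \code{phi^2 = h2Polygenic}. Residuals are iid
#' Gaussian with \code{sigma^2 = 1 - h2Polygenic - nCausal * h2Block}.
#'
#' @param geno genotypes from [simulateGenotypes()].
#' @param config the \linkS4class{SimConfig} used to create them.
#' @param seed RNG seed for the phenotype draws; defaults to
#'   \code{config@seed + 1} so a config fully determines the (genotype,
#'   phenotype, truth) triple, while replicate phenotypes on fixed genotypes
#'   can be drawn by varying it.
#' @return list with elements \code{phenotype} (named numeric vector) and
#'   \code{truth} (a \linkS4class{SimTruth}).
#' @export
simulatePhenotypes <- function(geno, config, seed = config@seed + 1L) {
  validObject(config)
  set.seed(as.integer(seed))
  n <- nIndividuals(geno)
  blocks <- plantedBlocks(geno)
  if (length(blocks) < config@nCausalBlocks)
    stop(sprintf("fewer blocks (%d) than causal blocks requested (%d)",
                 length(blocks), config@nCausalBlocks))
  sigma2 <- 1 - config@h2Polygenic - config@nCausalBlocks * config@h2Block
  intercept <- 1
  g <- numeric(n)
  gammaList <- list(); lambdaK <- numeric(0); causalIds <- character(0)
  if (config@nCausalBlocks > 0L) {
    ## only blocks whose Z rows actually vary can carry variance
    trS <- vapply(blocks, function(b) {
      Z <- .hapPairToZ(b@hapPair, length(b@haplotypes))
      sum(apply(Z, 2L, var))
    }, numeric(1))
    eligible <- which(trS > 1e-8)
    if (length(eligible) < config@nCausalBlocks)
      stop("not enough polymorphic blocks to host the causal effects")
    causal <- sort(sample(eligible, config@nCausalBlocks))
    for (ci in causal) {
      b <- blocks[[ci]]
      Z <- .hapPairToZ(b@hapPair, length(b@haplotypes))
      phi2k <- config@h2Block / trS[ci]
      gam <- rnorm(ncol(Z), 0, sqrt(phi2k))
      names(gam) <- paste0("H", b@haplotypes)
      g <- g + as.vector(Z %*% gam)
      gammaList[[b@blockId]] <- gam
      lambdaK <- c(lambdaK, setNames(phi2k / sigma2, b@blockId))
      causalIds <- c(causalIds, b@blockId)
    }
  }
  ## polygenic term through genome-wide marker effects
  xi <- numeric(n)
  lambda <- 0
  if (config@h2Polygenic > 0) {
    X <- dosage(geno)
    p <- colMeans(X) / 2
    Wc <- sweep(X, 2L, 2 * p)
    s2 <- 2 * sum(p * (1 - p))
    u <- rnorm(ncol(X), 0, sqrt(config@h2Polygenic / s2))
    xi <- as.vector(Wc %*% u)
    lambda <- config@h2Polygenic / sigma2
  }
  eps <- rnorm(n, 0, sqrt(sigma2))
  y <- intercept + g + xi + eps
  names(y) <- individualIds(geno)
  truth <- new("SimTruth", causalBlockIds = causalIds, gamma = gammaList,
               lambda = lambda, lambdaK = lambdaK, sigma2 = sigma2,
               intercept = intercept, xi = xi, epsilon = eps)
  list(phenotype = y, truth = truth)
}

#' Write a phenotype TSV (id, value)
#'
#' @param phenotype named numeric vector.
#' @param path output file.
#' @param header write a header line (default TRUE).
#' @export
writePhenotypeTsv <- function(phenotype, path, header = TRUE) {
  df <- data.frame(id = names(phenotype), value = unname(phenotype))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = header)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' Scalar truth (variance ratios, residual variance, causal ids and their
#' haplotype effects) is serialized; the realized per-individual draws stay
#' in the in-memory \linkS4class{SimTruth}.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param path output file.
#' @export
writeTruthJson <- function(truth, path) {
  jsonlite::write_json(list(
    causal_block_ids = truth@causalBlockIds,
    true_gamma = truth@gamma,
    true_lambda = truth@lambda,
    true_lambda_k = as.list(truth@lambdaK),
    true_sigma2 = truth@sigma2,
    intercept = truth@intercept), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
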