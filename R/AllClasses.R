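#' Phased diploid genotypes with a marker map
#'
#' Container for n individuals by m biallelic markers, stored as two
#' haplotype allele-code matrices (codes 0 = REF, 1 = ALT) plus a marker map
#' held as a \link[GenomicRanges]{GRanges} with \code{ref}/\code{alt}
#' metadata columns. Coordinates are 1-based inclusive throughout, matching
#' VCF. Missing genotypes are not representable: loaders reject them.
#'
#' @slot hap1,hap2 integer matrices (individuals x markers) of 0/1 allele
#'   codes; rownames are individual ids, colnames marker ids.
#' @slot map \code{GRanges} of marker positions, one per column, with
#'   metadata columns \code{ref} and \code{alt} (single bases).
#'
#' @seealso [readPhasedVcf()], [simulateGenotypes()], [mafFilter()]
#' @export
setClass("PhasedGenotypes",
  slots = c(hap1 = "matrix", hap2 = "matrix", map = "GRanges"))

setValidity("PhasedGenotypes", function(object) {
  h1 <- object@hap1; h2 <- object@hap2; map <- object@map
  if (!identical(dim(h1), dim(h2)))
    return("hap1 and hap2 must have identical dimensions")
  if (length(map) != ncol(h1))
    return("map length must equal the number of marker columns")
  if (anyNA(h1) || anyNA(h2))
    return("missing allele codes are not allowed")
  if (length(h1) && !all(h1 %in% c(0L, 1L) & h2 %in% c(0L, 1L)))
    return("allele codes must be 0 or 1 (biallelic markers only)")
  if (is.null(rownames(h1)) || !identical(rownames(h1), rownames(h2)))
    return("individual ids (rownames) must be present and identical")
  if (!all(c("ref", "alt") %in% colnames(mcols(map))))
    return("map must carry 'ref' and 'alt' metadata columns")
  chrom <- as.character(seqnames(map))
  pos <- start(map)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    if (any(diff(idx) != 1L))
      return("markers of one chromosome must be contiguous in the map")
    if (any(diff(pos[idx]) <= 0))
      return(sprintf("positions must be strictly increasing on chromosome %s", cc))
  }
  TRUE
})

#' A haplotype block of 2--4 consecutive markers
#'
#' Holds the distinct haplotypes observed in a block, each individual's
#' haplotype pair, and the haplotype frequency table. Haplotype labels are
#' \code{"H"} followed by the concatenated allele codes (e.g. \code{"H011"}),
#' ordered by descending frequency with lexicographic tie-break.
#'
#' @slot blockId character label.
#' @slot chrom chromosome label.
#' @slot markerIndices integer positions of the block's markers in the map
#'   of the genotypes the block was derived from (consecutive, 2--4 entries).
#' @slot startBp,endBp 1-based bp span of the block.
#' @slot haplotypes character vector of allele-code strings (no "H" prefix).
#' @slot hapPair n x 2 integer matrix indexing \code{haplotypes} for each
#'   individual's two chromosomes.
#' @slot frequencies per-haplotype fractions over the 2n chromosomes.
#' @export
setClass("HaplotypeBlock",
  slots = c(blockId = "character", chrom = "character",
            markerIndices = "integer", startBp = "numeric", endBp = "numeric",
            haplotypes = "character", hapPair = "matrix",
            frequencies = "numeric"))

setValidity("HaplotypeBlock", function(object) {
  s <- length(object@markerIndices)
  if (s < 2L || s > 4L) return("blocks must contain 2 to 4 markers")
  if (!identical(object@markerIndices,
                 seq(object@markerIndices[1L], length.out = s)))
    return("marker indices must be consecutive")
  nh <- length(object@haplotypes)
  if (nh > 2^s) return("more haplotypes than 2^s possible")
  if (length(object@frequencies) != nh)
    return("frequencies must align with haplotypes")
  if (abs(sum(object@frequencies) - 1) > 1e-12)
    return("frequencies must sum to 1")
  hp <- object@hapPair
  if (ncol(hp) != 2L) return("hapPair must have two columns")
  if (length(hp) && (min(hp) < 1L || max(hp) > nh))
    return("hapPair indices out of range")
  TRUE
})

#' Kinship matrix with its eigendecomposition
#'
#' The genomic relationship matrix K together with K = U D U' (eigenvalues
#' descending, tiny negative values clamped to zero). The decomposition is
#' computed once and reused for every block fit.
#'
#' @slot K n x n symmetric kinship matrix.
#' @slot U orthonormal eigenvector matrix.
#' @slot values eigenvalues, descending.
#' @seealso [grm()]
#' @export
setClass("KinshipEigen",
  slots = c(K = "matrix", U = "matrix", values = "numeric"))

setValidity("KinshipEigen", function(object) {
  K <- object@K
  if (nrow(K) != ncol(K)) return("K must be square")
  if (max(abs(K - t(K))) > 1e-8) return("K must be symmetric")
  if (length(object@values) != nrow(K) ||
      !identical(dim(object@U), dim(K)))
    return("eigendecomposition dimensions must match K")
  recon <- object@U %*% (object@values * t(object@U))
  if (max(abs(recon - K)) >= 1e-8)
    return("U diag(values) U' must reconstruct K to 1e-8")
  TRUE
})

#' Fit of the per-block random-effect mixed model
#'
#' Variance parameters, fixed effects, empirical Bayes haplotype effects and
#' the Wald test for one haplotype block (or one marker in single-SNP mode).
#'
#' @slot blockId label of the fitted block.
#' @slot lambda,lambdaK,sigma2 variance parameters: polygenic ratio
#'   phi^2/sigma^2, block ratio phi_k^2/sigma^2, and residual variance.
#' @slot betaHat fixed-effect estimates (GLS at the REML optimum).
#' @slot gammaHat empirical Bayes (BLUP) haplotype effects.
#' @slot gammaCov sampling covariance of \code{gammaHat}.
#' @slot W,p Wald statistic and its chi-square p-value.
#' @slot loglik profiled restricted log-likelihood at the optimum.
#' @slot converged,nIter optimizer convergence record.
#' @slot hapLabels labels aligned with \code{gammaHat} columns.
#' @export
setClass("BlockFit",
  slots = c(blockId = "character", lambda = "numeric", lambdaK = "numeric",
            sigma2 = "numeric", betaHat = "numeric", gammaHat = "numeric",
            gammaCov = "matrix", W = "numeric", p = "numeric",
            loglik = "numeric", converged = "logical", nIter = "integer",
            hapLabels = "character"))

setValidity("BlockFit", function(object) {
  if (length(object@W) && object@W < -1e-10) return("W must be nonnegative")
  if (length(object@p) && (object@p <= 0 || object@p > 1))
    return("p must lie in (0, 1]")
  if (length(object@sigma2) && object@sigma2 <= 0)
    return("sigma2 must be positive")
  TRUE
})

#' Genome-scan result table
#'
#' One row per tested block (or marker), the underlying \linkS4class{BlockFit}
#' objects, and, once \code{\link{callSignificant}} has been applied, the
#' threshold set and significance labels.
#'
#' @slot results data.frame of per-block summaries.
#' @slot fits list of \linkS4class{BlockFit}.
#' @slot thresholds a \linkS4class{ThresholdSet}, or NULL before calling.
#' @export
setClass("ScanResult",
  slots = c(results = "data.frame", fits = "list", thresholds = "ANY"),
  prototype = prototype(thresholds = NULL))

#' Multiple-testing thresholds
#'
#' Classical Bonferroni (alpha / number of tests) and modified Bonferroni
#' (alpha / effective number of tests) thresholds.
#'
#' @slot alpha nominal level.
#' @slot nTests number of tested blocks.
#' @slot mEff effective number of independent tests.
#' @slot bon,mbon the two p-value thresholds.
#' @seealso [thresholdSet()], [effectiveTests()]
#' @export
setClass("ThresholdSet",
  slots = c(alpha = "numeric", nTests = "numeric", mEff = "numeric",
            bon = "numeric", mbon = "numeric"))

setValidity("ThresholdSet", function(object) {
  if (object@alpha <= 0 || object@alpha >= 1) return("alpha must lie in (0,1)")
  if (object@nTests < 1) return("nTests must be at least 1")
  if (object@mEff < 1 - 1e-9 || object@mEff > object@nTests + 1e-9)
    return("mEff must lie in [1, nTests]")
  if (object@mbon < object@bon - 1e-15)
    return("mbon threshold cannot be below the Bonferroni threshold")
  TRUE
})

#' Configuration of the synthetic population generator
#'
#' See [simConfig()] for field semantics and defaults.
#' @export
setClass("SimConfig",
  slots = c(nIndividuals = "integer", nBlocks = "integer",
            snpsPerBlock = "integer", interBlockSpacingBp = "integer",
            intraBlockSpacingBp = "integer", mafRange = "numeric",
            blockLd = "numeric", nCausalBlocks = "integer",
            h2Block = "numeric", h2Polygenic = "numeric",
            haplotypePool = "character", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nIndividuals < 2L) return("need at least 2 individuals")
  if (object@nBlocks < 1L) return("need at least 1 block")
  if (!all(object@snpsPerBlock %in% 2:4))
    return("snpsPerBlock values must lie in {2, 3, 4}")
  mr <- object@mafRange
  if (length(mr) != 2L || mr[1] > mr[2]) return("mafRange must be (lo, hi)")
  if (mr[1] <= 0 || mr[2] > 0.5)
    return("mafRange must lie inside (0, 0.5]")
  if (mr[1] < 0.05) return("lower MAF bound must be at least 0.05")
  if (object@blockLd < 0 || object@blockLd > 1)
    return("blockLd must lie in [0, 1]")
  if (object@nCausalBlocks > object@nBlocks)
    return("fewer blocks than causal blocks requested")
  if (object@h2Block < 0 || object@h2Polygenic < 0)
    return("variance fractions must be nonnegative")
  if (object@h2Block * object@nCausalBlocks + object@h2Polygenic >= 1)
    return("h2Block * nCausalBlocks + h2Polygenic must be < 1")
  if (!object@haplotypePool %in% c("ladder", "pair"))
    return("haplotypePool must be 'ladder' or 'pair'")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("a single integer seed is mandatory")
  TRUE
})

#' Ground truth of a simulated phenotype
#'
#' Records every random draw behind a simulated phenotype so recovery tests
#' can compare estimates with truth.
#'
#' @slot causalBlockIds ids of the causal blocks.
#' @slot gamma list of per-causal-block haplotype effect vectors.
#' @slot lambda,lambdaK true variance ratios phi^2/sigma^2 and (per causal
#'   block) phi_k^2/sigma^2.
#' @slot sigma2 true residual variance.
#' @slot intercept fixed intercept added to all phenotypes.
#' @slot xi,epsilon realized polygenic and residual draws (length n).
#' @export
setClass("SimTruth",
  slots = c(causalBlockIds = "character", gamma = "list",
            lambda = "numeric", lambdaK = "numeric", sigma2 = "numeric",
            intercept = "numeric", xi = "numeric", epsilon = "numeric"))

setValidity("SimTruth", function(object) {
  if (object@sigma2 <= 0) return("sigma2 must be positive")
  if (object@lambda < 0 || any(object@lambdaK < 0))
    return("variance ratios must be nonnegative")
  TRUE
})
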