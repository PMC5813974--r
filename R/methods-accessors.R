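#' Construct a PhasedGenotypes object
#'
#' @param hap1,hap2 0/1 matrices, individuals in rows, markers in columns.
#' @param chrom,pos,ref,alt per-marker map vectors (1-based positions).
#' @param individualIds optional ids; default taken from rownames or
#'   \code{ind1..indN}.
#' @param markerIds optional marker names; default \code{<chrom>_<pos>}.
#' @return a validated \linkS4class{PhasedGenotypes}.
#' @export
PhasedGenotypes <- function(hap1, hap2, chrom, pos, ref, alt,
                            individualIds = NULL, markerIds = NULL) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  if (is.null(individualIds))
    individualIds <- rownames(hap1) %||% paste0("ind", seq_len(nrow(hap1)))
  if (is.null(markerIds)) markerIds <- paste(chrom, pos, sep = "_")
  rownames(hap1) <- rownames(hap2) <- individualIds
  colnames(hap1) <- colnames(hap2) <- markerIds
  map <- GRanges(seqnames = as.character(chrom),
                 ranges = IRanges(start = as.integer(pos), width = 1L),
                 ref = as.character(ref), alt = as.character(alt))
  names(map) <- markerIds
  new("PhasedGenotypes", hap1 = hap1, hap2 = hap2, map = map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname PhasedGenotypes-class
#' @export
setMethod("nIndividuals", "PhasedGenotypes", function(x) nrow(x@hap1))

#' @rdname PhasedGenotypes-class
#' @export
setMethod("nMarkers", "PhasedGenotypes", function(x) ncol(x@hap1))

#' @rdname PhasedGenotypes-class
#' @export
setMethod("individualIds", "PhasedGenotypes", function(x) rownames(x@hap1))

#' @rdname PhasedGenotypes-class
#' @export
setMethod("markerMap", "PhasedGenotypes", function(x) x@map)

#' @rdname PhasedGenotypes-class
#' @export
setMethod("hapMatrix", "PhasedGenotypes", function(x, which = 1L) {
  stopifnot(which %in% c(1L, 2L))
  if (which == 1L) x@hap1 else x@hap2
})

#' @rdname PhasedGenotypes-class
#' @export
setMethod("dosage", "PhasedGenotypes", function(x) x@hap1 + x@hap2)

#' Subset phased genotypes by individual (i) and/or marker (j)
#'
#' @param x a \linkS4class{PhasedGenotypes}.
#' @param i,j individual and marker indices.
#' @param ... ignored.
#' @param drop ignored (never drops).
#' @export
setMethod("[", "PhasedGenotypes", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nIndividuals(x))
  if (missing(j)) j <- seq_len(nMarkers(x))
  new("PhasedGenotypes",
      hap1 = x@hap1[i, j, drop = FALSE],
      hap2 = x@hap2[i, j, drop = FALSE],
      map = x@map[j])
})

setMethod("show", "PhasedGenotypes", function(object) {
  cat(sprintf("PhasedGenotypes: %d individuals x %d markers on %d chromosome(s)\n",
              nIndividuals(object), nMarkers(object),
              length(unique(as.character(seqnames(object@map))))))
})

setMethod("show", "HaplotypeBlock", function(object) {
  cat(sprintf("HaplotypeBlock %s: chr %s [%d-%d], %d SNPs, %d haplotypes\n",
              object@blockId, object@chrom, object@startBp, object@endBp,
              length(object@markerIndices), length(object@haplotypes)))
  lab <- paste0("H", object@haplotypes)
  cat("  ", paste(sprintf("%s:%.3f", lab, object@frequencies),
                  collapse = "  "), "\n")
})

#' @rdname KinshipEigen-class
#' @param x a \linkS4class{KinshipEigen}.
#' @export
kinshipMatrix <- function(x) x@K

#' @rdname KinshipEigen-class
#' @export
eigenVectors <- function(x) x@U

#' @rdname KinshipEigen-class
#' @export
eigenValues <- function(x) x@values

setMethod("show", "KinshipEigen", function(object) {
  cat(sprintf("KinshipEigen: %d x %d, eigenvalues in [%.4g, %.4g], mean diag %.4f\n",
              nrow(object@K), ncol(object@K),
              min(object@values), max(object@values),
              mean(diag(object@K))))
})

setMethod("show", "BlockFit", function(object) {
  cat(sprintf("BlockFit %s: lambda=%.4g lambda_k=%.4g sigma2=%.4g W=%.4g p=%.3g %s\n",
              object@blockId, object@lambda, object@lambdaK, object@sigma2,
              object@W, object@p,
              if (object@converged) "(converged)" else "(NOT converged)"))
})

#' @rdname ScanResult-class
#' @export
setMethod("results", "ScanResult", function(x) x@results)

#' @rdname ScanResult-class
#' @export
setMethod("thresholds", "ScanResult", function(x) x@thresholds)

setMethod("show", "ScanResult", function(object) {
  res <- object@results
  cat(sprintf("ScanResult: %d tests (%d converged)\n",
              nrow(res), sum(res$converged)))
  if (!is.null(object@thresholds)) {
    ts <- object@thresholds
    cat(sprintf("  thresholds: Bon %.3g, mBon %.3g (m_eff %.2f of %d)\n",
                ts@bon, ts@mbon, ts@mEff, as.integer(ts@nTests)))
  }
  if (nrow(res)) print(head(res, 5L))
})

setMethod("show", "ThresholdSet", function(object) {
  cat(sprintf(
    "ThresholdSet: alpha %.3g, %d tests, m_eff %.2f -> Bon %.3g, mBon %.3g\n",
    object@alpha, as.integer(object@nTests), object@mEff,
    object@bon, object@mbon))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: n=%d, %d blocks (%s SNPs, pool=%s, LD=%.2f), MAF [%.2f, %.2f]\n",
    object@nIndividuals, object@nBlocks,
    paste(sort(unique(object@snpsPerBlock)), collapse = "/"),
    object@haplotypePool, object@blockLd,
    object@mafRange[1], object@mafRange[2]))
  cat(sprintf("  causal blocks: %d x h2 %.3f, polygenic h2 %.3f, seed %d\n",
              object@nCausalBlocks, object@h2Block, object@h2Polygenic,
              object@seed))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: %d causal block(s), lambda=%.4g, sigma2=%.4g, intercept=%.3g\n",
    length(object@causalBlockIds), object@lambda, object@sigma2,
    object@intercept))
})
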