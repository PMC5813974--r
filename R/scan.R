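#' Haplotype-inheritance design matrix of a block
#'
#' Column j of Z counts the copies of haplotype j carried by each
#' individual: a carrier of haplotypes 1 and 2 (of four) gets the row
#' \code{[1 1 0 0]}, a homozygote for haplotype 3 the row \code{[0 0 2 0]}.
#' Every row has at most two nonzero entries and sums to exactly 2.
#'
#' Haplotypes seen on fewer than \code{minHapCount} chromosomes are pooled
#' into a single \code{"rare"} column (rather than dropped, which would
#' break the row-sum invariant). A block with fewer than two haplotypes at
#' or above the count floor is not testable and raises a condition of class
#' \code{blockSkipped}, which [scanBlocks()] catches and logs.
#'
#' @param block a \linkS4class{HaplotypeBlock}.
#' @param minHapCount chromosome-count floor for a haplotype to keep its
#'   own column (default 5).
#' @return numeric matrix n x h with haplotype labels as colnames.
#' @export
buildZ <- function(block, minHapCount = 5L) {
  counts <- round(block@frequencies * 2 * nrow(block@hapPair))
  retained <- which(counts >= minHapCount)
  if (length(retained) < 2L) {
    cond <- structure(
      class = c("blockSkipped", "error", "condition"),
      list(message = sprintf(
        "block %s: fewer than 2 haplotypes with chromosome count >= %d",
        block@blockId, minHapCount), call = NULL))
    stop(cond)
  }
  dropped <- setdiff(seq_along(counts), retained)
  h <- length(retained) + (length(dropped) > 0L)
  colMap <- integer(length(counts))
  colMap[retained] <- seq_along(retained)
  if (length(dropped)) colMap[dropped] <- h
  n <- nrow(block@hapPair)
  Z <- matrix(0, n, h)
  for (c in 1:2) {
    ix <- cbind(seq_len(n), colMap[block@hapPair[, c]])
    Z[ix] <- Z[ix] + 1
  }
  labels <- paste0("H", block@haplotypes[retained])
  if (length(dropped)) labels <- c(labels, "rare")
  dimnames(Z) <- list(rownames(block@hapPair), labels)
  Z
}

.alignPhenotype <- function(geno, phenotype, stage = "scan") {
  ids <- individualIds(geno)
  if (is.null(names(phenotype)))
    stop(sprintf("%s: phenotype vector must be named by individual id", stage))
  missing <- setdiff(ids, names(phenotype))
  extra <- setdiff(names(phenotype), ids)
  if (length(missing) || length(extra))
    stop(sprintf(
      "%s: phenotype/genotype id mismatch; missing [%s], unmatched [%s]",
      stage,
      paste(head(missing, 5L), collapse = ", "),
      paste(head(extra, 5L), collapse = ", ")))
  phenotype[ids]
}

.fitRow <- function(fit, chrom, start, end, nSnps) {
  data.frame(block_id = fit@blockId, chrom = chrom,
             start_bp = start, end_bp = end, n_snps = nSnps,
             h = length(fit@gammaHat),
             lambda = fit@lambda, lambda_k = fit@lambdaK,
             sigma2 = fit@sigma2, W = fit@W, p = fit@p,
             converged = fit@converged, n_iter = fit@nIter,
             loglik = fit@loglik, stringsAsFactors = FALSE)
}

#' Scan haplotype blocks with the empirical Bayes mixed model
#'
#' Rotates the phenotype and fixed effects into the kinship eigenbasis once,
#' then fits every block's random-effect model (per-block \code{Z*}) by
#' profiled REML and computes its Wald test. Deterministic given inputs.
#' Blocks whose design collapses below two retained haplotypes are skipped
#' with a message; non-converged fits are kept but flagged.
#'
#' @param geno phased genotypes.
#' @param phenotype named numeric vector (any quantitative trait, e.g.
#'   EBVs); ids must match the genotypes, order free.
#' @param blocks list of \linkS4class{HaplotypeBlock} (from
#'   [gabrielBlocks()] or [plantedBlocks()]).
#' @param kinship optional precomputed \linkS4class{KinshipEigen}; default
#'   builds the VanRaden GRM from all markers of \code{geno}.
#' @param X optional fixed-effect covariate matrix (rows aligned with
#'   individuals); an intercept column is always prepended.
#' @param minHapCount rare-haplotype pooling floor, see [buildZ()].
#' @param control optimizer settings, see [remlControl()].
#' @return a \linkS4class{ScanResult}.
#' @export
scanBlocks <- function(geno, phenotype, blocks, kinship = NULL, X = NULL,
                       minHapCount = 5L, control = remlControl()) {
  y <- .alignPhenotype(geno, phenotype)
  if (is.null(kinship)) kinship <- grm(geno)
  n <- nIndividuals(geno)
  Xfull <- cbind(intercept = rep(1, n), X)
  td <- eigenTransform(kinship, y, Xfull)
  rows <- list(); fits <- list()
  for (b in blocks) {
    Z <- tryCatch(buildZ(b, minHapCount), blockSkipped = function(e) {
      message("scanBlocks: skipped ", conditionMessage(e))
      NULL
    })
    if (is.null(Z)) next
    ZStar <- crossprod(kinship@U, Z)
    colnames(ZStar) <- colnames(Z)
    fit <- fitBlock(td$yStar, td$XStar, ZStar, td$d, control = control,
                    blockId = b@blockId, hapLabels = colnames(Z))
    rows[[length(rows) + 1L]] <-
      .fitRow(fit, b@chrom, b@startBp, b@endBp, length(b@markerIndices))
    fits[[fit@blockId]] <- fit
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    .fitRow(new("BlockFit", blockId = "x", lambda = 0, lambdaK = 0,
                sigma2 = 1, betaHat = 0, gammaHat = numeric(0),
                gammaCov = matrix(0, 0, 0), W = 0, p = 1, loglik = 0,
                converged = TRUE, nIter = 0L,
                hapLabels = character(0)), "", 0, 0, 0)[0, ]
  rownames(res) <- NULL
  new("ScanResult", results = res, fits = fits)
}

#' Single-locus scan with the same mixed-model machinery
#'
#' Each marker is treated as a one-column random effect (Z = ALT-dosage
#' vector) and sent through the identical likelihood and Wald code path as
#' the blocks, so haplotype-based and single-SNP results are directly
#' comparable. Monomorphic markers must be filtered upstream.
#'
#' @inheritParams scanBlocks
#' @param markers optional marker indices (default all).
#' @return a \linkS4class{ScanResult}; \code{block_id} holds marker ids and
#'   \code{n_snps} is 1.
#' @export
singleSnpScan <- function(geno, phenotype, kinship = NULL, X = NULL,
                          markers = NULL, control = remlControl()) {
  y <- .alignPhenotype(geno, phenotype)
  if (is.null(kinship)) kinship <- grm(geno)
  n <- nIndividuals(geno)
  Xfull <- cbind(intercept = rep(1, n), X)
  td <- eigenTransform(kinship, y, Xfull)
  if (is.null(markers)) markers <- seq_len(nMarkers(geno))
  D <- dosage(geno)
  map <- geno@map
  rows <- list(); fits <- list()
  for (j in markers) {
    z <- D[, j, drop = FALSE]
    if (var(z[, 1L]) == 0)
      stop(sprintf("marker %s is monomorphic; filter before scanning",
                   names(map)[j]))
    ZStar <- crossprod(kinship@U, z)
    fit <- fitBlock(td$yStar, td$XStar, ZStar, td$d, control = control,
                    blockId = names(map)[j], hapLabels = "dosage")
    rows[[length(rows) + 1L]] <-
      .fitRow(fit, as.character(seqnames(map))[j], start(map)[j],
              start(map)[j], 1L)
    fits[[fit@blockId]] <- fit
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  new("ScanResult", results = res, fits = fits)
}

#' Write a scan results table as TSV
#'
#' @param scan a \linkS4class{ScanResult}.
#' @param path output file.
#' @export
writeResultsTsv <- function(scan, path) {
  write.table(scan@results, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
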