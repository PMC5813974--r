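#' Effective number of independent tests
#'
#' Li & Ji (2005) estimator (default): with eigenvalues \eqn{e_i} of the
#' test-score correlation matrix, \eqn{M_{eff} = \sum_i [I(|e_i| \ge 1) +
#' (|e_i| - \lfloor |e_i| \rfloor)]}, clamped to \code{[1, M]}. The
#' \code{"simpleM"} alternative (Gao et al.) counts the leading eigenvalues
#' holding 99.5\% of the total variance. Both are invariant to simultaneous
#' row/column permutation.
#'
#' @param corMat symmetric correlation matrix with unit diagonal, one
#'   row/column per test (e.g. from [leadSnpCorrelation()]).
#' @param method \code{"liJi"} (default) or \code{"simpleM"}.
#' @param evFraction eigenvalue mass for simpleM (default 0.995).
#' @return scalar effective number of tests.
#' @export
effectiveTests <- function(corMat, method = c("liJi", "simpleM"),
                           evFraction = 0.995) {
  method <- match.arg(method)
  corMat <- as.matrix(corMat)
  M <- nrow(corMat)
  if (M != ncol(corMat) || max(abs(corMat - t(corMat))) > 1e-8)
    stop("effectiveTests: input must be a symmetric matrix")
  if (max(abs(diag(corMat) - 1)) > 1e-8)
    stop("effectiveTests: input must have unit diagonal")
  ev <- eigen(corMat, symmetric = TRUE, only.values = TRUE)$values
  meff <- if (method == "liJi") {
    ## rounding guards floor() against eigenvalues like 2 - 1e-15
    ae <- round(abs(ev), 9)
    sum((ae >= 1) + (ae - floor(ae)))
  } else {
    cum <- cumsum(sort(ev, decreasing = TRUE)) / sum(ev)
    which(cum >= evFraction)[1L]
  }
  min(max(meff, 1), M)
}

#' Correlation matrix of block lead-SNP dosages
#'
#' One score per block: the dosage of its lead SNP (highest MAF, ties to
#' the first marker). The resulting correlation matrix feeds
#' [effectiveTests()].
#'
#' @param geno phased genotypes the blocks index into.
#' @param blocks list of \linkS4class{HaplotypeBlock}.
#' @return M x M correlation matrix (unit diagonal).
#' @export
leadSnpCorrelation <- function(geno, blocks) {
  maf <- computeMaf(geno)$maf
  lead <- vapply(blocks, function(b) {
    ix <- b@markerIndices
    ix[which.max(maf[ix])]
  }, integer(1))
  D <- dosage(geno)[, lead, drop = FALSE]
  C <- cor(D)
  dimnames(C) <- list(vapply(blocks, function(b) b@blockId, character(1)),
                      vapply(blocks, function(b) b@blockId, character(1)))
  C
}

#' Classical and modified Bonferroni thresholds
#'
#' \code{bon = alpha / nTests} and \code{mbon = alpha / mEff}; using the
#' effective number of tests rather than the total number of blocks relaxes
#' the threshold when tests are correlated.
#'
#' @param alpha nominal level in (0, 1), default 0.05.
#' @param nTests number of tested blocks.
#' @param mEff effective number of tests, in \code{[1, nTests]}.
#' @return a \linkS4class{ThresholdSet}.
#' @export
thresholdSet <- function(alpha = 0.05, nTests, mEff = nTests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (nTests < 1) stop("nTests must be at least 1")
  if (mEff > nTests + 1e-9)
    stop("mEff cannot exceed the number of tests")
  new("ThresholdSet", alpha = alpha, nTests = as.numeric(nTests),
      mEff = as.numeric(mEff), bon = alpha / nTests, mbon = alpha / mEff)
}

#' Call block significance against both thresholds
#'
#' Labels every block \code{"Both Bon& mBon"} (p <= bon), \code{"Only
#' mBon"} (bon < p <= mbon) or \code{"none"}; comparisons use <= at the
#' thresholds and non-converged fits are always \code{"none"}. The labels
#' partition the blocks.
#'
#' @param scan a \linkS4class{ScanResult}.
#' @param ts a \linkS4class{ThresholdSet}.
#' @return the scan with a \code{significance} column and the thresholds
#'   attached.
#' @export
callSignificant <- function(scan, ts) {
  res <- scan@results
  sig <- rep("none", nrow(res))
  ok <- res$converged
  sig[ok & res$p <= ts@bon] <- "Both Bon& mBon"
  sig[ok & res$p <= ts@mbon & res$p > ts@bon] <- "Only mBon"
  res$significance <- sig
  new("ScanResult", results = res, fits = scan@fits, thresholds = ts)
}

#' Write a threshold set as JSON
#'
#' @param ts a \linkS4class{ThresholdSet}.
#' @param path output file.
#' @export
writeThresholdJson <- function(ts, path) {
  jsonlite::write_json(list(alpha = ts@alpha, n_tests = ts@nTests,
                            m_eff = ts@mEff, bon_threshold = ts@bon,
                            mbon_threshold = ts@mbon),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
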