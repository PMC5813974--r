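#' Genomic relationship matrix with attached eigendecomposition
#'
#' VanRaden method-1 GRM: \eqn{K = W W^T / (2 \sum_j p_j (1 - p_j))} with
#' \code{W} the column-centered dosage matrix (dosage minus twice the ALT
#' frequency). Monomorphic markers contribute nothing and are tolerated,
#' but an all-monomorphic panel is an error. The eigendecomposition
#' \eqn{K = U D U^T} is computed once here (tiny negative eigenvalues from
#' numerical noise are clamped to zero) and reused by every block fit --
#' this is what makes the per-block REML cost linear in n.
#'
#' @param geno a \linkS4class{PhasedGenotypes}, normally MAF-filtered.
#' @return a \linkS4class{KinshipEigen}.
#' @export
grm <- function(geno) {
  X <- dosage(geno)
  if (ncol(X) < 2L) stop("need at least 2 markers to build a GRM")
  p <- colMeans(X) / 2
  s2 <- 2 * sum(p * (1 - p))
  if (s2 <= 0) stop("all markers are monomorphic; GRM undefined")
  W <- sweep(X, 2L, 2 * p)
  K <- tcrossprod(W) / s2
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(X), rownames(X))
  e <- eigen(K, symmetric = TRUE)
  new("KinshipEigen", K = K, U = e$vectors, values = pmax(e$values, 0))
}

#' Rotate data into the kinship eigenbasis
#'
#' Computes \eqn{y^* = U^T y}, \eqn{X^* = U^T X} (and optionally \eqn{Z^*})
#' so the polygenic covariance becomes the diagonal \code{D lambda + I}.
#' Done once per scan; only \code{Z*} is recomputed per block.
#'
#' @param kin a \linkS4class{KinshipEigen}.
#' @param y phenotype vector.
#' @param X fixed-effect design matrix (default intercept-only).
#' @param Z optional random-effect design.
#' @return list with \code{yStar}, \code{XStar}, \code{d} (eigenvalues) and,
#'   if \code{Z} was given, \code{ZStar}.
#' @export
eigenTransform <- function(kin, y, X = NULL, Z = NULL) {
  n <- length(kin@values)
  stopifnot(length(y) == n)
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank-deficient")
  out <- list(yStar = as.vector(crossprod(kin@U, y)),
              XStar = crossprod(kin@U, X),
              d = kin@values)
  if (!is.null(Z)) out$ZStar <- crossprod(kin@U, as.matrix(Z))
  out
}

#' Export / import a kinship matrix as square TSV
#'
#' @param kin a \linkS4class{KinshipEigen}.
#' @param path file path.
#' @export
writeKinshipTsv <- function(kin, path) {
  df <- data.frame(id = rownames(kin@K), kin@K, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKinshipTsv
#' @return \code{readKinshipTsv}: a \linkS4class{KinshipEigen} rebuilt from
#'   the stored matrix (eigendecomposition recomputed).
#' @export
readKinshipTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  K <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(K) <- list(df[[1L]], df[[1L]])
  K <- (K + t(K)) / 2
  e <- eigen(K, symmetric = TRUE)
  new("KinshipEigen", K = K, U = e$vectors, values = pmax(e$values, 0))
}
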