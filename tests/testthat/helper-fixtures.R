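# Fixtures and independent oracles, all built in code at test time.

# random phased genotypes with iid markers (no LD)
makeToyGeno <- function(n, m, seed, pmin = 0.2, pmax = 0.5) {
  set.seed(seed)
  f <- runif(m, pmin, pmax)
  h1 <- sapply(f, function(p) rbinom(n, 1L, p))
  h2 <- sapply(f, function(p) rbinom(n, 1L, p))
  PhasedGenotypes(h1, h2, chrom = rep("1", m),
                  pos = seq(1000L, by = 1000L, length.out = m),
                  ref = rep("A", m), alt = rep("C", m))
}

# chromosome of perfect-LD ladder blocks separated by independent spacer
# markers; returns the genotypes and the planted marker-index sets
plantedChromosome <- function(sizes, n, seed, mafFloor = 0.2) {
  set.seed(seed)
  mkLadder <- function(s) {
    haps <- matrix(0L, s + 1L, s)
    for (i in seq_len(s)) haps[(i + 1L):(s + 1L), i] <- 1L
    repeat {
      f <- rgamma(s + 1L, 1); f <- f / sum(f)
      marg <- as.vector(crossprod(haps, f))
      if (all(pmin(marg, 1 - marg) >= mafFloor)) break
    }
    haps[sample.int(s + 1L, 2L * n, TRUE, prob = f), , drop = FALSE]
  }
  mkSpacer <- function() matrix(rbinom(2L * n, 1L, runif(1, 0.25, 0.5)))
  cols <- list(); truth <- list(); posv <- integer(0)
  cursor <- 1000L; mi <- 0L
  for (k in seq_along(sizes)) {
    cols[[length(cols) + 1L]] <- mkSpacer()
    posv <- c(posv, cursor); cursor <- cursor + 20000L; mi <- mi + 1L
    cols[[length(cols) + 1L]] <- mkLadder(sizes[k])
    truth[[k]] <- mi + seq_len(sizes[k])
    posv <- c(posv, cursor + seq(0L, by = 500L, length.out = sizes[k]))
    cursor <- cursor + sizes[k] * 500L + 20000L
    mi <- mi + sizes[k]
  }
  cols[[length(cols) + 1L]] <- mkSpacer()
  posv <- c(posv, cursor)
  A <- do.call(cbind, cols)
  geno <- PhasedGenotypes(A[seq_len(n), , drop = FALSE],
                          A[n + seq_len(n), , drop = FALSE],
                          chrom = rep("1", ncol(A)), pos = posv,
                          ref = rep("A", ncol(A)), alt = rep("C", ncol(A)))
  list(geno = geno, truth = truth)
}

randomPDKinship <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * 2L * n), n, 2L * n)
  tcrossprod(A) / (2 * n) + diag(0.3, n)
}

# random haplotype-inheritance design: each row two draws from h classes
randomZ <- function(n, h, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(0, n, h)
  for (i in seq_len(n)) {
    ix <- sample.int(h, 2L, replace = TRUE)
    Z[i, ix[1L]] <- Z[i, ix[1L]] + 1
    Z[i, ix[2L]] <- Z[i, ix[2L]] + 1
  }
  Z
}

# dense-covariance evaluation of the profiled restricted log-likelihood and
# the EB quantities, using V = ZZ' lambda_k + K lambda + I directly
denseBlockStats <- function(y, X, Z, K, lambdaK, lambda) {
  n <- length(y); r <- ncol(X)
  V <- tcrossprod(Z) * lambdaK + K * lambda + diag(n)
  Vi <- solve(V)
  XVX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XVX, crossprod(X, Vi))
  ypy <- drop(t(y) %*% P %*% y)
  ll <- -0.5 * as.numeric(determinant(V)$modulus) -
    0.5 * as.numeric(determinant(XVX)$modulus) - (n - r) / 2 * log(ypy)
  beta <- solve(XVX, crossprod(X, Vi %*% y))
  gamma <- lambdaK * crossprod(Z, Vi %*% (y - X %*% beta))
  sigma2 <- ypy / (n - r)
  V0 <- K * lambda + diag(n)
  V0i <- solve(V0)
  XV0X <- crossprod(X, V0i %*% X)
  P0 <- V0i - V0i %*% X %*% solve(XV0X, crossprod(X, V0i))
  S <- crossprod(Z, P0 %*% Z)
  M <- solve(diag(ncol(Z)) + lambdaK * S)
  gcov <- sigma2 * lambdaK^2 * (M %*% S %*% t(M))
  list(loglik = ll, beta = drop(beta), gamma = drop(gamma),
       sigma2 = sigma2, gammaCov = (gcov + t(gcov)) / 2)
}

# Henderson's mixed-model equations: independent route to the BLUP of gamma
hendersonGamma <- function(y, X, Z, K, lambdaK, lambda) {
  n <- length(y); r <- ncol(X); h <- ncol(Z)
  Ki <- solve(K)
  C <- rbind(
    cbind(crossprod(X), crossprod(X, Z), t(X)),
    cbind(crossprod(Z, X), crossprod(Z) + diag(h) / lambdaK, t(Z)),
    cbind(X, Z, diag(n) + Ki / lambda))
  sol <- solve(C, c(crossprod(X, y), crossprod(Z, y), y))
  list(beta = sol[seq_len(r)], gamma = sol[r + seq_len(h)])
}

# exhaustive evaluation of the Gabriel rules over all contiguous windows,
# with the same largest-first overlap resolution and <=4-SNP splitting
bruteGabriel <- function(geno, maxSnps = 4L, ciLower = 0.70, ciUpper = 0.98,
                         recombUpper = 0.90, strongFrac = 0.95) {
  A <- rbind(hapMatrix(geno, 1L), hapMatrix(geno, 2L))
  m <- ncol(A)
  cand <- list()
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    ns <- 0L; nr <- 0L
    for (a in i:(j - 1L)) for (b in (a + 1L):j) {
      mono <- all(A[, a] == A[1L, a]) || all(A[, b] == A[1L, b])
      if (mono) next
      ci <- dprimeCI(A[, a], A[, b])
      if (ci$lower > ciLower && ci$upper >= ciUpper) ns <- ns + 1L
      else if (ci$upper < recombUpper) nr <- nr + 1L
    }
    inf <- ns + nr
    if (inf > 0L && ns / inf >= strongFrac && nr / inf < 1 - strongFrac)
      cand[[length(cand) + 1L]] <- c(i, j)
  }
  sizes <- vapply(cand, function(w) w[2L] - w[1L] + 1L, integer(1))
  lefts <- vapply(cand, `[`, integer(1), 1L)
  taken <- rep(FALSE, m)
  out <- list()
  for (k in order(-sizes, lefts)) {
    w <- cand[[k]]
    if (any(taken[w[1L]:w[2L]])) next
    taken[w[1L]:w[2L]] <- TRUE
    for (st in seq(w[1L], w[2L], by = maxSnps)) {
      en <- min(st + maxSnps - 1L, w[2L])
      if (en - st + 1L >= 2L) out[[length(out) + 1L]] <- st:en
    }
  }
  out[order(vapply(out, `[`, integer(1), 1L))]
}
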