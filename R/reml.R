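## Core REML machinery in the kinship eigenbasis.
##
## After the one-time rotation, the covariance of y* is
##   H = Z* Z*' lambda_k + R,   R = D lambda + I (diagonal),
## and every likelihood evaluation uses the Woodbury identity and the
## matrix determinant lemma on the rank-h update, so the per-evaluation
## cost is O(n h^2) and no n x n matrix is ever inverted.

## All H-dependent quantities needed by the likelihood, the GLS fixed
## effects and the EB block effects, from one pass.
.remlParts <- function(yStar, XStar, ZStar, d, lambdaK, lambda) {
  if (lambdaK < 0 || lambda < 0)
    stop("variance ratios must be nonnegative")
  yStar <- as.vector(yStar)
  XStar <- as.matrix(XStar)
  ZStar <- as.matrix(ZStar)
  n <- length(yStar); r <- ncol(XStar); h <- ncol(ZStar)
  if (n <= r) stop("need n > rank(X)")
  rdiag <- d * lambda + 1
  Zr <- ZStar / rdiag
  A <- crossprod(ZStar, Zr)                      # Z*' R^-1 Z*
  B <- diag(h) + lambdaK * A
  cB <- chol(B)
  logdetH <- sum(log(rdiag)) + 2 * sum(log(diag(cB)))
  Bi <- chol2inv(cB)
  M <- cbind(XStar, yStar)
  Mr <- M / rdiag
  ZtM <- crossprod(ZStar, Mr)                    # Z*' R^-1 M
  C <- crossprod(M, Mr) - lambdaK * crossprod(ZtM, Bi %*% ZtM)  # M' H^-1 M
  Cxx <- C[seq_len(r), seq_len(r), drop = FALSE]
  cxy <- C[seq_len(r), r + 1L]
  cyy <- C[r + 1L, r + 1L]
  cX <- tryCatch(chol(Cxx), error = function(e)
    stop("X*' H^-1 X* not positive definite at theta = (",
         lambdaK, ", ", lambda, ")"))
  logdetC <- 2 * sum(log(diag(cX)))
  beta <- backsolve(cX, forwardsolve(t(cX), cxy))
  ypy <- cyy - sum(cxy * beta)
  if (!is.finite(ypy) || ypy <= 0)
    stop("nonpositive residual quadratic form at theta = (",
         lambdaK, ", ", lambda, ")")
  loglik <- -0.5 * logdetH - 0.5 * logdetC - (n - r) / 2 * log(ypy)
  if (!is.finite(loglik))
    stop("nonfinite restricted log-likelihood at theta = (",
         lambdaK, ", ", lambda, ")")
  list(loglik = loglik, beta = as.vector(beta), ypy = ypy,
       sigma2 = ypy / (n - r), n = n, r = r, h = h,
       rdiag = rdiag, Zr = Zr, A = A, Bi = Bi, ZtM = ZtM, Cxx = Cxx, cX = cX)
}

#' Profiled restricted log-likelihood of a block model
#'
#' Evaluates, in the kinship eigenbasis,
#' \deqn{L(\lambda_k, \lambda) = -\tfrac12 \ln|H_k|
#'   - \tfrac12 \ln|X^{*T} H_k^{-1} X^*|
#'   - \tfrac{n-r}{2} \ln(y^{*T} P_k y^*)}
#' with \eqn{R = D\lambda + I}, \eqn{H_k = Z^* Z^{*T}\lambda_k + R} and
#' \eqn{P_k} the REML projection. Fixed effects and the residual variance
#' are profiled out, leaving only \eqn{\theta = (\lambda_k, \lambda)}.
#' Evaluation is O(n h^2) via the Woodbury identity on the diagonal R plus
#' the rank-h update; no n x n inverse is formed.
#'
#' @param yStar,XStar,ZStar transformed data from [eigenTransform()].
#' @param d kinship eigenvalues.
#' @param lambdaK,lambda nonnegative variance ratios.
#' @return the scalar log-likelihood (errors on nonfinite results, echoing
#'   theta).
#' @export
profiledRemlLoglik <- function(yStar, XStar, ZStar, d, lambdaK, lambda) {
  .remlParts(yStar, XStar, ZStar, d, lambdaK, lambda)$loglik
}

#' Fixed and empirical Bayes effects at a given theta
#'
#' GLS fixed effects, residual variance \eqn{\hat\sigma^2 = y^{*T} P_k
#' y^*/(n-r)}, the empirical Bayes (BLUP) haplotype effects
#' \eqn{\hat\gamma_k = \lambda_k Z^{*T} H_k^{-1}(y^* - X^*\hat\beta)} and
#' their sampling covariance under the null hypothesis of no block effect.
#' Writing \eqn{S = Z^{*T} P_0 Z^*} and \eqn{s = Z^{*T} P_0 y^*} with
#' \eqn{P_0} the REML projection of the reduced model (\eqn{H_0 = R}, block
#' term removed), the EB estimate is the shrunken score
#' \eqn{\hat\gamma_k = \lambda_k (I + \lambda_k S)^{-1} s}, so its null
#' covariance is \eqn{\widehat{var}_0(\hat\gamma_k) = \hat\sigma^2
#' \lambda_k^2 (I + \lambda_k S)^{-1} S (I + \lambda_k S)^{-1}}. The Wald
#' quadratic form built from this pair is algebraically the
#' kinship-adjusted score statistic \eqn{s^T \mathrm{pinv}(\hat\sigma^2 S)
#' s} -- the shrinkage cancels, which is what gives the test a chi-square
#' null. (The full-model \eqn{P_k} covariance would degenerate at interior
#' REML optima, and the posterior covariance has no chi-square null.)
#' Because Z rows sum to 2 and X contains an intercept the covariance has
#' rank at most h - 1.
#'
#' @inheritParams profiledRemlLoglik
#' @return list with \code{loglik}, \code{betaHat}, \code{sigma2},
#'   \code{gammaHat}, \code{gammaCov}.
#' @export
blockEffects <- function(yStar, XStar, ZStar, d, lambdaK, lambda) {
  parts <- .remlParts(yStar, XStar, ZStar, d, lambdaK, lambda)
  ZStar <- as.matrix(ZStar); XStar <- as.matrix(XStar)
  e <- as.vector(yStar) - as.vector(XStar %*% parts$beta)
  er <- e / parts$rdiag
  ZtRe <- crossprod(ZStar, er)
  Hie <- er - lambdaK * as.vector(parts$Zr %*% (parts$Bi %*% ZtRe))
  gammaHat <- lambdaK * as.vector(crossprod(ZStar, Hie))
  ## null-model projection: H_0 = R, so Z*' P_0 Z* needs only R^-1 products
  ZtRX <- crossprod(ZStar, XStar / parts$rdiag)
  Cxx0 <- crossprod(XStar, XStar / parts$rdiag)
  ZP0Z <- parts$A - ZtRX %*% solve(Cxx0, t(ZtRX))
  ZP0Z <- (ZP0Z + t(ZP0Z)) / 2
  ## gamma_hat = lambda_k (I + lambda_k S)^-1 s with s = Z*' P_0 y*, so its
  ## null covariance carries the same shrinkage factor on both sides
  M <- solve(diag(parts$h) + lambdaK * ZP0Z)
  gammaCov <- parts$sigma2 * lambdaK^2 * (M %*% ZP0Z %*% t(M))
  gammaCov <- (gammaCov + t(gammaCov)) / 2
  list(loglik = parts$loglik, betaHat = parts$beta, sigma2 = parts$sigma2,
       gammaHat = gammaHat, gammaCov = gammaCov)
}

#' Optimizer settings for the per-block REML fit
#'
#' @param gradTol convergence tolerance on the max-norm of the
#'   log-parameter gradient (default 1e-6).
#' @param maxIter Newton-Raphson iteration cap (default 100).
#' @param fdStep,hessStep central-difference steps for the gradient and
#'   Hessian of the log-parameterized likelihood.
#' @param logLower,logUpper clamps on log(lambda_k), log(lambda);
#'   \code{exp(logLower)} is numerically a zero boundary estimate.
#' @param lambdaGrid null-model grid initializing lambda.
#' @param lambdaKInit starting value for lambda_k.
#' @param df \code{"one"} (default): the Wald statistic is referred to
#'   chi-square with 1 df. \code{"rank"}: df = rank of the effect
#'   covariance.
#' @param pinvTol relative rank tolerance of the pseudo-inverse in the Wald
#'   statistic.
#' @return list of settings for [fitBlock()].
#' @export
remlControl <- function(gradTol = 1e-6, maxIter = 100L, fdStep = 1e-5,
                        hessStep = 1e-3, logLower = -30, logUpper = 10,
                        lambdaGrid = c(0.01, 0.1, 1, 10),
                        lambdaKInit = 0.01, df = c("one", "rank"),
                        pinvTol = 1e-8) {
  list(gradTol = gradTol, maxIter = as.integer(maxIter), fdStep = fdStep,
       hessStep = hessStep, logLower = logLower, logUpper = logUpper,
       lambdaGrid = lambdaGrid, lambdaKInit = lambdaKInit,
       df = match.arg(df), pinvTol = pinvTol)
}

.fdGrad <- function(f, u, h) {
  vapply(seq_along(u), function(i) {
    e <- numeric(length(u)); e[i] <- h
    (f(u + e) - f(u - e)) / (2 * h)
  }, numeric(1))
}

## Convergence test on the finite-difference gradient. Near an optimum the
## small-step estimate is dominated by cancellation noise (~eps|f|/h), so
## the check retries with larger steps; any estimate below tol certifies
## the gradient bound within numerical resolution.
.gradConverged <- function(f, u, ctl) {
  g <- NULL
  for (h in unique(c(ctl$fdStep, 1e-4, 1e-3))) {
    g <- .fdGrad(f, u, h)
    if (max(abs(g)) < ctl$gradTol) return(list(ok = TRUE, grad = g))
  }
  list(ok = FALSE, grad = g)
}

.fdHess <- function(f, u, h) {
  k <- length(u)
  H <- matrix(0, k, k)
  f0 <- f(u)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h
    H[i, i] <- (f(u + ei) - 2 * f0 + f(u - ei)) / h^2
    if (i < k) for (j in (i + 1L):k) {
      ej <- numeric(k); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(u + ei + ej) - f(u + ei - ej) - f(u - ei + ej) + f(u - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

## Newton-Raphson on u = (log lambda_k, log lambda) with finite-difference
## derivatives, eigenvalue-floored Hessian and step halving. Flat
## directions (a variance ratio drifting to its boundary leaves the
## likelihood flat to machine precision) are finished off by cyclic 1-D
## golden-section polishing; a bounded Nelder-Mead is the last resort.
## Minimizes negll.
.optimizeTheta <- function(negll, u0, ctl) {
  clamp <- function(u) pmin(pmax(u, ctl$logLower), ctl$logUpper)
  u <- clamp(u0)
  f <- negll(u)
  g <- .fdGrad(negll, u, ctl$fdStep)
  iter <- 0L
  stalls <- 0L
  converged <- max(abs(g)) < ctl$gradTol
  while (!converged && iter < ctl$maxIter) {
    iter <- iter + 1L
    Hm <- .fdHess(negll, u, ctl$hessStep)
    ev <- eigen(Hm, symmetric = TRUE)
    floorv <- pmax(ev$values, 1e-4 * max(abs(ev$values), 1e-8))
    step <- -as.vector(ev$vectors %*% (crossprod(ev$vectors, g) / floorv))
    improved <- FALSE
    fold <- f
    for (half in 0:30) {
      unew <- clamp(u + step / 2^half)
      fnew <- negll(unew)
      if (is.finite(fnew) && fnew < f) {
        u <- unew; f <- fnew; improved <- TRUE; break
      }
    }
    g <- .fdGrad(negll, u, ctl$fdStep)
    converged <- max(abs(g)) < ctl$gradTol
    if (!improved) break
    ## two consecutive sub-noise improvements: hand over to the polisher
    stalls <- if (fold - f < 1e-10 * max(1, abs(f))) stalls + 1L else 0L
    if (stalls >= 2L) break
  }
  if (!converged) {
    ## coordinate polish: exact 1-D line minimizations nail the flat tails
    ## (moves are accepted even when the improvement is below the noise
    ## floor of |f|, where step-halving cannot see it)
    for (pass in 1:3) {
      for (i in seq_along(u)) {
        fi <- function(v) { uu <- u; uu[i] <- v; negll(uu) }
        o <- optimize(fi, lower = max(ctl$logLower, u[i] - 4),
                      upper = min(ctl$logUpper, u[i] + 4), tol = 1e-10)
        if (is.finite(o$objective) &&
            o$objective <= f + 1e-11 * max(1, abs(f))) {
          u[i] <- o$minimum; f <- min(f, o$objective)
        }
      }
      gc <- .gradConverged(negll, u, ctl)
      g <- gc$grad; converged <- gc$ok
      if (converged) break
    }
  }
  if (!converged) {
    nm <- optim(u, negll, method = "Nelder-Mead",
                control = list(maxit = 1000L, reltol = 1e-14))
    if (is.finite(nm$value) && nm$value <= f) {
      u <- clamp(nm$par); f <- negll(u)
    }
    gc <- .gradConverged(negll, u, ctl)
    g <- gc$grad; converged <- gc$ok
  }
  list(u = u, value = f, grad = g, converged = converged, nIter = iter)
}

#' Fit the per-block mixed model by profiled REML
#'
#' Maximizes the profiled restricted log-likelihood over
#' \eqn{\theta = (\lambda_k, \lambda)} by Newton-Raphson on the
#' log-transformed parameters (which enforces nonnegativity; boundary
#' estimates surface as \code{exp(logLower)}, numerically zero), with
#' finite-difference derivatives, step-halving and a Nelder-Mead fallback;
#' near the optimum, where small-step difference quotients drown in
#' floating-point cancellation, convergence is certified by re-measuring
#' the gradient at progressively larger steps.
#' \eqn{\lambda} is initialized from a null-model grid search and
#' \eqn{\lambda_k} at \code{lambdaKInit}. At the optimum the GLS fixed
#' effects, \eqn{\hat\sigma^2}, the EB haplotype effects, their covariance
#' and the Wald test are assembled.
#'
#' @inheritParams profiledRemlLoglik
#' @param theta optional fixed \code{c(lambdaK, lambda)}: skip optimization
#'   and evaluate there (used by oracles and fixed-theta scans).
#' @param control see [remlControl()].
#' @param blockId,hapLabels labels carried into the result.
#' @return a \linkS4class{BlockFit}. Non-convergence is flagged, not an
#'   error; flagged fits are excluded from significance calls downstream.
#' @export
fitBlock <- function(yStar, XStar, ZStar, d, theta = NULL,
                     control = remlControl(), blockId = NA_character_,
                     hapLabels = character(0)) {
  XStar <- as.matrix(XStar); ZStar <- as.matrix(ZStar)
  if (is.null(theta)) {
    negll <- function(u) {
      tryCatch(-profiledRemlLoglik(yStar, XStar, ZStar, d,
                                   exp(u[1L]), exp(u[2L])),
               error = function(e) Inf)
    }
    lk0 <- exp(control$logLower)
    nullLL <- vapply(control$lambdaGrid, function(l)
      tryCatch(profiledRemlLoglik(yStar, XStar, ZStar, d, lk0, l),
               error = function(e) -Inf), numeric(1))
    u0 <- c(log(control$lambdaKInit),
            log(control$lambdaGrid[which.max(nullLL)]))
    opt <- .optimizeTheta(negll, u0, control)
    lambdaK <- exp(opt$u[1L]); lambda <- exp(opt$u[2L])
    converged <- opt$converged; nIter <- opt$nIter
  } else {
    lambdaK <- theta[1L]; lambda <- theta[2L]
    converged <- TRUE; nIter <- 0L
  }
  eff <- blockEffects(yStar, XStar, ZStar, d, lambdaK, lambda)
  wt <- .waldFromEffects(eff$gammaHat, eff$gammaCov, control)
  if (!length(hapLabels)) hapLabels <- colnames(ZStar) %||% character(0)
  new("BlockFit", blockId = blockId, lambda = lambda, lambdaK = lambdaK,
      sigma2 = eff$sigma2, betaHat = eff$betaHat, gammaHat = eff$gammaHat,
      gammaCov = eff$gammaCov, W = wt$W, p = wt$p, loglik = eff$loglik,
      converged = converged, nIter = as.integer(nIter),
      hapLabels = as.character(hapLabels))
}

.pseudoInverse <- function(A, rtol = 1e-8) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- abs(e$values) > rtol * max(abs(e$values), .Machine$double.xmin)
  rank <- sum(keep)
  if (rank == 0L) return(list(inv = matrix(0, nrow(A), ncol(A)), rank = 0L))
  inv <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  list(inv = inv, rank = rank)
}

.waldFromEffects <- function(gammaHat, gammaCov, control = remlControl()) {
  if (!any(is.finite(gammaCov)) || all(abs(gammaCov) < .Machine$double.xmin))
    return(list(W = 0, p = 1, rank = 0L))
  pi <- .pseudoInverse(gammaCov, control$pinvTol)
  W <- max(0, as.vector(t(gammaHat) %*% pi$inv %*% gammaHat))
  df <- if (identical(control$df, "rank")) max(1L, pi$rank) else 1L
  p <- pchisq(W, df = df, lower.tail = FALSE)
  list(W = W, p = max(p, .Machine$double.xmin), rank = pi$rank)
}

#' Wald test of the block haplotype effects
#'
#' \eqn{W_k = \hat\gamma^T \, \mathrm{pinv}(\widehat{var}(\hat\gamma)) \,
#' \hat\gamma} with a pseudo-inverse at relative rank tolerance
#' \code{pinvTol}, referred to a chi-square distribution with one degree of
#' freedom: \eqn{p_k = \Pr(\chi^2_1 > W_k)}. A covariance that is entirely
#' zero yields \code{W = 0, p = 1}.
#'
#' @param fit a converged \linkS4class{BlockFit}.
#' @param control see [remlControl()]; \code{df = "rank"} replaces the 1-df
#'   reference by the rank of the effect covariance.
#' @return list with \code{W} and \code{p}.
#' @export
waldTest <- function(fit, control = remlControl()) {
  wt <- .waldFromEffects(fit@gammaHat, fit@gammaCov, control)
  list(W = wt$W, p = wt$p)
}
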