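#' NIPALS PLS2 reference implementation
#'
#' Classical score-space NIPALS iteration with explicit deflation of the
#' predictor and response matrices, kept as an independent reference
#' against which the cross-product kernel algorithm is validated. Same
#' contract and sign convention as [fitKernelPLS()]; agreement to 1e-8 on
#' weights, scores, loadings and coefficients is asserted in the test
#' suite. Not intended for routine fitting.
#'
#' @inheritParams fitKernelPLS
#' @param maxIter,tol inner-iteration budget and relative convergence
#'   tolerance on the score vector.
#' @return a [PLSModel-class].
#' @export
nipalsPLS <- function(X, U, l, maxIter = 500L, tol = 1e-12) {
  X <- .asMatrix(X); U <- .asMatrix(U)
  if (nrow(X) != nrow(U)) stop("X and U must have the same number of rows")
  if (nrow(X) < 3L) stop("need n >= 3")
  l <- as.integer(l)
  rk <- qr(X)$rank
  if (l < 1L || l > rk) stop("l must be in 1..rank(X)")
  n <- nrow(X); p <- ncol(X); m <- ncol(U)
  Xc <- X; Uc <- U
  W <- P <- matrix(0, p, l)
  Q <- matrix(0, m, l)
  TT <- matrix(0, n, l)
  tt <- numeric(l)
  for (b in seq_len(l)) {
    if (sqrt(sum(crossprod(Xc, Uc)^2)) < 1e-12) {
      stop("no remaining covariance between X and U at component ", b)
    }
    if (m == 1L) {
      w <- as.numeric(crossprod(Xc, Uc))
      w <- w / sqrt(sum(w^2))
      tb <- as.numeric(Xc %*% w)
    } else {
      u <- Uc[, which.max(colSums(Uc^2))]
      tb <- rep(0, n)
      converged <- FALSE
      for (it in seq_len(maxIter)) {
        w <- as.numeric(crossprod(Xc, u))
        w <- w / sqrt(sum(w^2))
        tNew <- as.numeric(Xc %*% w)
        qb <- as.numeric(crossprod(Uc, tNew)) / sum(tNew^2)
        u <- as.numeric(Uc %*% qb) / sum(qb^2)
        if (sqrt(sum((tNew - tb)^2)) <= tol * max(1, sqrt(sum(tNew^2)))) {
          tb <- tNew
          converged <- TRUE
          break
        }
        tb <- tNew
      }
      if (!converged) {
        stop("NIPALS inner loop did not converge in ", maxIter,
             " iterations at component ", b)
      }
    }
    s <- if (w[which.max(abs(w))] < 0) -1 else 1   # same orientation rule
    w <- s * w; tb <- s * tb
    ttb <- sum(tb^2)
    pb <- as.numeric(crossprod(Xc, tb)) / ttb
    qb <- as.numeric(crossprod(Uc, tb)) / ttb
    Xc <- Xc - tcrossprod(tb, pb)
    Uc <- Uc - tcrossprod(tb, qb)
    W[, b] <- w; P[, b] <- pb; Q[, b] <- qb; TT[, b] <- tb; tt[b] <- ttb
  }
  ## rotations: weights with respect to the undeflated X, so that T = X R
  R <- W %*% solve(crossprod(P, W))
  fit <- .plsDimnames(list(W = W, R = R, P = P, Q = Q, TT = TT, tt = tt,
                           B = R %*% t(Q)), X, U)
  methods::new("PLSModel", nComponents = l, weights = fit$W,
               rotations = fit$R, xLoadings = fit$P, uLoadings = fit$Q,
               scores = fit$TT, scoreNorms = fit$tt, coefficients = fit$B)
}
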