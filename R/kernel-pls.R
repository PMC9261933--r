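## Multivariate kernel PLS (cross-product algorithm).
##
## Per component b on the deflated cross-product M_b = (X'U)_b:
##   q_b : dominant unit right-singular vector of M_b
##         (eigenvector of the largest eigenvalue of M_b'M_b)
##   w_b = M_b q_b, rescaled to unit norm
##   r_1 = w_1;  r_b = w_b - sum_{a<b} (p_a' w_b) r_a
##   t_b = X r_b,  p_b = X' t_b / (t_b' t_b),  q_b' = r_b' M_b / (t_b' t_b)
##   M_{b+1} = M_b - p_b q_b' (t_b' t_b)
## Coefficients B = R Q'.  The "kernel" property: the whole iteration can
## run on X'X and X'U alone, never forming the n-vector scores.

.asMatrix <- function(x) {
  if (methods::is(x, "StandardizedMatrix")) return(x@values)
  if (is.data.frame(x)) return(as.matrix(x))
  if (is.null(dim(x))) return(matrix(x, ncol = 1L))
  x
}

## orient v so its largest-magnitude entry is positive (ties: lowest index)
.signFix <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

## dominant right singular vector of M (p x m), via the smaller cross-product
.domRightSV <- function(M) {
  p <- nrow(M); m <- ncol(M)
  if (m == 1L) return(1)
  if (m <= p) {
    eigen(crossprod(M), symmetric = TRUE)$vectors[, 1L]
  } else {
    u <- eigen(tcrossprod(M), symmetric = TRUE)$vectors[, 1L]
    q <- crossprod(M, u)
    as.numeric(q) / sqrt(sum(q^2))
  }
}

.plsCore <- function(X, U, l, useCrossprod = FALSE) {
  n <- nrow(X); p <- ncol(X); m <- ncol(U)
  M <- crossprod(X, U)                      # p x m
  XtX <- if (useCrossprod) crossprod(X) else NULL
  W <- R <- P <- matrix(0, p, l)
  Q <- matrix(0, m, l)
  TT <- if (useCrossprod) NULL else matrix(0, n, l)
  tt <- numeric(l)
  for (b in seq_len(l)) {
    if (sqrt(sum(M^2)) < 1e-12) {
      stop("no remaining covariance between X and U at component ", b)
    }
    q0 <- .domRightSV(M)
    w <- as.numeric(M %*% q0)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) stop("no remaining covariance between X and U at component ", b)
    w <- .signFix(w / nw)
    r <- if (b == 1L) w else {
      w - R[, seq_len(b - 1L), drop = FALSE] %*%
        crossprod(P[, seq_len(b - 1L), drop = FALSE], w)
    }
    r <- as.numeric(r)
    if (useCrossprod) {
      Sr <- as.numeric(XtX %*% r)
      ttb <- sum(r * Sr)
      if (ttb <= 0) stop("degenerate component ", b, ": zero score norm")
      pb <- Sr / ttb
    } else {
      tb <- as.numeric(X %*% r)
      ttb <- sum(tb^2)
      if (ttb <= 0) stop("degenerate component ", b, ": zero score norm")
      pb <- as.numeric(crossprod(X, tb)) / ttb
      TT[, b] <- tb
    }
    qb <- as.numeric(crossprod(M, r)) / ttb
    M <- M - outer(pb, qb) * ttb
    W[, b] <- w; R[, b] <- r; P[, b] <- pb; Q[, b] <- qb; tt[b] <- ttb
  }
  if (useCrossprod) TT <- X %*% R
  list(W = W, R = R, P = P, Q = Q, TT = TT, tt = tt,
       B = R %*% t(Q), residualCrossprod = M)
}

.plsDimnames <- function(fit, X, U) {
  cn <- paste0("comp", seq_len(ncol(fit$W)))
  dimnames(fit$W) <- list(colnames(X), cn)
  dimnames(fit$R) <- list(colnames(X), cn)
  dimnames(fit$P) <- list(colnames(X), cn)
  dimnames(fit$Q) <- list(colnames(U), cn)
  dimnames(fit$TT) <- list(rownames(X), cn)
  dimnames(fit$B) <- list(colnames(X), colnames(U))
  fit
}

#' Fit a multivariate kernel PLS model
#'
#' Extracts `l` partial least squares components of a standardized
#' multivariate response `U` on standardized predictors `X` using the
#' cross-product (kernel) algorithm: all deflation happens on the p x m
#' matrix X'U, X itself is never deflated. Each component's weight vector
#' is oriented so its largest-magnitude entry is positive, making fits
#' reproducible despite eigenvector sign ambiguity.
#'
#' @param X n x p standardized predictor matrix (or
#'   [StandardizedMatrix-class]).
#' @param U n x m standardized response matrix (or
#'   [StandardizedMatrix-class]); a vector is treated as one column.
#' @param l number of components, `1 <= l <= rank(X)`.
#' @param method `"scores"` forms the n-vector scores during iteration;
#'   `"crossprod"` runs entirely on X'X and X'U (the kernel property) and
#'   reconstructs scores at the end. Both return identical fits.
#' @return a [PLSModel-class].
#' @examples
#' X <- stdValues(standardize(matrix(rnorm(80), 20, 4)))
#' U <- stdValues(standardize(matrix(rnorm(60), 20, 3)))
#' fit <- fitKernelPLS(X, U, l = 2)
#' max(abs(plsScores(fit) - X %*% plsRotations(fit)))  # 0: T = X R
#' @export
fitKernelPLS <- function(X, U, l, method = c("scores", "crossprod")) {
  method <- match.arg(method)
  X <- .asMatrix(X); U <- .asMatrix(U)
  if (nrow(X) != nrow(U)) stop("X and U must have the same number of rows")
  if (nrow(X) < 3L) stop("need n >= 3")
  l <- as.integer(l)
  if (l < 1L) stop("l must be >= 1")
  rk <- qr(X)$rank
  if (l > rk) stop("l = ", l, " exceeds rank(X) = ", rk)
  fit <- .plsCore(X, U, l, useCrossprod = (method == "crossprod"))
  fit <- .plsDimnames(fit, X, U)
  methods::new("PLSModel", nComponents = l, weights = fit$W,
               rotations = fit$R, xLoadings = fit$P, uLoadings = fit$Q,
               scores = fit$TT, scoreNorms = fit$tt, coefficients = fit$B)
}

#' Dominant eigenvector of a symmetric matrix
#'
#' Unit eigenvector of the largest eigenvalue, computed by a full symmetric
#' eigendecomposition, with the sign fixed so the largest-magnitude entry
#' is positive (ties resolved to the lowest index). When the top eigenvalue
#' is (numerically) degenerate the returned vector carries attribute
#' `degenerate = TRUE` and the choice among the tied directions is
#' whatever the decomposition returns, sign-fixed.
#'
#' @param S symmetric positive semidefinite matrix (symmetry enforced to
#'   1e-10 relative).
#' @return unit numeric vector with attribute `eigenvalue`.
#' @examples
#' dominantEigenvector(diag(c(3, 1)))  # c(1, 0)
#' @export
dominantEigenvector <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("S must be square")
  if (max(abs(S - t(S))) > 1e-10 * max(1, max(abs(S)))) {
    stop("S must be symmetric")
  }
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- .signFix(e$vectors[, 1L])
  attr(v, "eigenvalue") <- e$values[1L]
  if (length(e$values) > 1L &&
      (e$values[1L] - e$values[2L]) <= 1e-10 * max(1, abs(e$values[1L]))) {
    attr(v, "degenerate") <- TRUE
  }
  v
}

#' Write a PLS fit to tab-separated files for inspection
#'
#' Dumps W, R, P, Q, T and B as TSV files `<prefix>_<name>.tsv`.
#'
#' @param model a [PLSModel-class].
#' @param prefix path prefix for the output files.
#' @return invisibly, the written file paths.
#' @export
dumpPLSModel <- function(model, prefix) {
  parts <- list(W = model@weights, R = model@rotations, P = model@xLoadings,
                Q = model@uLoadings, T = model@scores, B = model@coefficients)
  paths <- character(0)
  for (nm in names(parts)) {
    f <- paste0(prefix, "_", nm, ".tsv")
    utils::write.table(parts[[nm]], f, sep = "\t", quote = FALSE,
                       col.names = NA)
    paths <- c(paths, f)
  }
  invisible(paths)
}
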