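## Stone-Brooks continuum regression directions.

#' Continuum-regression direction
#'
#' Unit direction maximizing the continuum-regression criterion
#' \deqn{T_\alpha(\beta) = \mathrm{Cov}(y, X\beta)^2 \,
#'   \mathrm{Var}(X\beta)^{\alpha/(1-\alpha) - 1}}
#' over unit vectors, the one-parameter family that interpolates ordinary
#' least squares (`alpha = 0`), the first PLS weight direction
#' (`alpha = 1/2`, proportional to X'y) and the first principal component
#' of X (`alpha = 1`). The three anchor values use their closed forms; in
#' between, the maximizer is found on the regularization path
#' \eqn{(X'X + \kappa I)^{-1} X'y} (for \eqn{\alpha < 1/2}) or
#' \eqn{(\lambda I - X'X)^{-1} X'y}, \eqn{\lambda > \lambda_{max}} (for
#' \eqn{\alpha > 1/2}), scalarized on the eigenbasis of X'X and maximized
#' to tolerance 1e-10.
#'
#' An alternative `criterion = "varSq"` form,
#' \eqn{\mathrm{Var}(X\beta)^2 |\mathrm{Cov}(y, X\beta)|^{\alpha/(1-\alpha)-1}},
#' with the roles of variance and covariance exchanged, is also exposed;
#' it does not reproduce the OLS/PLS/PCR anchor correspondence and exists
#' for comparison only.
#'
#' @param X n x p matrix (columns will be centered).
#' @param y length-n response (centered internally).
#' @param alpha number in \[0, 1\].
#' @param criterion `"standard"` (default) or `"varSq"`.
#' @param method `"auto"` uses the closed forms at the three anchor values
#'   and the numeric path elsewhere; `"numeric"` forces the path
#'   maximization everywhere (useful for checking that the path reproduces
#'   the anchors).
#' @return list with elements `alpha`, `direction` (unit length-p vector)
#'   and `criterion`.
#' @examples
#' X <- matrix(rnorm(60), 20, 3); y <- rnorm(20)
#' d <- continuumDirection(X, y, 0.5)$direction
#' s <- crossprod(scale(X, scale = FALSE), y - mean(y))
#' abs(sum(d * s / sqrt(sum(s^2))))  # 1: alpha = 1/2 is the PLS direction
#' @export
continuumDirection <- function(X, y, alpha, criterion = c("standard", "varSq"),
                               method = c("auto", "numeric")) {
  criterion <- match.arg(criterion)
  method <- match.arg(method)
  X <- .asMatrix(X)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (ncol(X) > nrow(X)) stop("continuumDirection requires p <= n")
  X <- sweep(X, 2L, colMeans(X), "-")
  y <- as.numeric(y) - mean(y)
  s <- as.numeric(crossprod(X, y))
  S <- crossprod(X)

  unit <- function(v) as.numeric(v) / sqrt(sum(v^2))
  alignToS <- function(v) if (sum(v * s) < 0) -v else v

  if (criterion == "standard" && method == "auto") {
    if (alpha == 0.5) {
      return(list(alpha = alpha, direction = alignToS(unit(s)),
                  criterion = criterion))
    }
    if (alpha == 0) {
      b <- tryCatch(solve(S, s),
                    error = function(e) stop("X'X is singular at alpha = 0"))
      return(list(alpha = alpha, direction = alignToS(unit(b)),
                  criterion = criterion))
    }
    if (alpha == 1) {
      v <- dominantEigenvector(S)
      attributes(v) <- NULL
      return(list(alpha = alpha, direction = .signFix(v),
                  criterion = criterion))
    }
  }

  ## numeric maximization on the eigenbasis of X'X
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  cvec <- as.numeric(crossprod(e$vectors, s))
  ## alpha = 1 makes the exponent infinite; a large finite cap preserves the
  ## limit (variance dominates, covariance only breaks ties)
  gam <- if (alpha >= 1) 1e8 else alpha / (1 - alpha) - 1
  objective <- function(d) {
    d <- unit(d)
    cv <- sum(cvec * d)
    vr <- sum(lam * d^2)
    if (vr <= 0) return(-Inf)
    if (criterion == "standard") 2 * log(abs(cv)) + gam * log(vr)
    else 2 * log(vr) + gam * log(abs(cv))
  }
  cand <- list()
  ## ridge leg: OLS (kappa = 0) -> PLS (kappa -> Inf)
  ridgeDir <- function(t) {
    kap <- if (t >= 1) Inf else max(lam) * t / (1 - t)
    if (is.infinite(kap)) return(cvec)
    d <- cvec / (lam + kap)
    if (all(is.finite(d))) d else cvec / (lam + kap + 1e-12 * max(lam))
  }
  opt1 <- stats::optimize(function(t) objective(ridgeDir(t)),
                          interval = c(0, 1), maximum = TRUE, tol = 1e-10)
  cand[[1L]] <- ridgeDir(opt1$maximum)
  ## negative-ridge leg: PLS (lambda -> Inf) -> PCR (lambda -> lambda_max)
  negDir <- function(u) {
    lamStar <- max(lam) * (1 + 1e-12 + u / (1 - u + 1e-300))
    cvec / (lamStar - lam)
  }
  opt2 <- stats::optimize(function(u) objective(negDir(u)),
                          interval = c(1e-12, 1 - 1e-12), maximum = TRUE,
                          tol = 1e-10)
  cand[[2L]] <- negDir(opt2$maximum)
  cand[[3L]] <- cvec                         # PLS endpoint (kappa -> Inf)
  cand[[4L]] <- ridgeDir(0)                  # OLS endpoint (kappa = 0)
  cand[[5L]] <- negDir(1e-14)                # PCR endpoint (lambda -> max)
  vals <- vapply(cand, objective, numeric(1L))
  d <- unit(cand[[which.max(vals)]])
  beta <- as.numeric(e$vectors %*% d)
  list(alpha = alpha, direction = alignToS(unit(beta)), criterion = criterion)
}
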