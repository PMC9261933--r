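#' First-principal-component regression baseline
#'
#' The comparison model: project the standardized features on the dominant
#' eigenvector of their covariance (PC1, sign fixed as in
#' [dominantEigenvector()]) and fit ordinary least squares of the outcome
#' on the intercept, PC1 and the confounder columns, with the usual OLS
#' standard errors. Unlike the latent-treatment estimator, PC1 ignores the
#' confounders when building the score, so the two fits can disagree in
#' sign and magnitude.
#'
#' @param U standardized feature matrix or [StandardizedMatrix-class].
#' @param confounders numeric confounder matrix (encoded; raw scale is
#'   fine).
#' @param y numeric outcome or [WorkingResponse-class].
#' @return a [PCABaselineFit-class].
#' @export
pcaBaseline <- function(U, confounders, y) {
  U <- .asMatrix(U)
  confounders <- .asMatrix(confounders)
  if (methods::is(y, "WorkingResponse")) y <- y@y
  n <- nrow(U)
  p <- ncol(confounders)
  if (n != nrow(confounders) || n != length(y)) stop("row counts differ")
  if (n <= p + 2L) stop("need n > p + 2")
  sv <- svd(U, nu = 0L, nv = 1L)
  v1 <- .signFix(sv$v[, 1L])
  pc1 <- as.numeric(U %*% v1)
  cn <- colnames(confounders)
  if (is.null(cn)) cn <- paste0("X", seq_len(p))
  df <- data.frame(y = y, PC1 = pc1, confounders, check.names = FALSE)
  colnames(df) <- c("y", "PC1", cn)
  mm <- stats::model.matrix(~ ., df[, -1L, drop = FALSE])
  if (qr(mm)$rank < ncol(mm)) stop("rank-deficient design")
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  coefs <- sm[, 1L]
  ses <- sm[, 2L]
  names(coefs) <- names(ses) <- c("(Intercept)", "PC1", cn)
  methods::new("PCABaselineFit", coefficients = coefs, standardErrors = ses,
               pc1Scores = pc1, pc1Loading = as.numeric(v1))
}
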