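#' @title S4 classes for latent-treatment causal PLS
#' @name causalPLS-classes
#' @description Container classes for the standardization transform, the
#'   kernel PLS fit, the inferred latent treatment, the causal-effect
#'   estimate, the PCA regression baseline, the null-model cumulative
#'   hazard, the working outcome, and simulated datasets.
NULL

#' Standardized matrix with stored affine transform
#'
#' Result of [standardize()]: a column-wise centered and scaled matrix along
#' with the means and scales that produced it, so the identical transform can
#' be applied to resampled or new data. Columns with zero sample variance are
#' removed before scaling and listed in `droppedColumns`.
#'
#' @slot values numeric matrix, each retained column has mean 0 and sample
#'   standard deviation 1 (n-1 denominator).
#' @slot colMeans,colScales numeric vectors of the training means and
#'   standard deviations of the retained columns (`colScales` all positive).
#' @slot droppedColumns character, names of removed zero-variance columns.
#' @exportClass StandardizedMatrix
setClass("StandardizedMatrix",
  representation(
    values = "matrix",
    colMeans = "numeric",
    colScales = "numeric",
    droppedColumns = "character"
  )
)

setValidity("StandardizedMatrix", function(object) {
  v <- object@values
  if (ncol(v) != length(object@colMeans) ||
      ncol(v) != length(object@colScales)) {
    return("colMeans/colScales length must equal ncol(values)")
  }
  if (any(object@colScales <= 0)) return("colScales must all be > 0")
  if (nrow(v) >= 2 && ncol(v) >= 1) {
    m <- colMeans(v)
    s <- apply(v, 2L, stats::sd)
    if (max(abs(m)) > 1e-10) return("columns not centered to |mean| < 1e-10")
    if (max(abs(s - 1)) > 1e-10) return("columns not scaled to |sd - 1| < 1e-10")
  }
  TRUE
})

#' Multivariate kernel PLS fit
#'
#' Fitted partial least squares decomposition of a standardized predictor
#' matrix X (n x p) against a standardized multivariate response U (n x m):
#' X = T P' + E, U = T Q' + F, with per-component weights w_b (unit norm),
#' rotations r_b (scores are linear in the *original* X: T = X R), predictor
#' loadings p_b, response loadings q_b, and regression coefficients
#' B = R Q'.
#'
#' @slot nComponents integer, number of extracted components l.
#' @slot weights p x l matrix W of unit-norm weight vectors.
#' @slot rotations p x l matrix R with T = X R.
#' @slot xLoadings p x l matrix P.
#' @slot uLoadings m x l matrix Q.
#' @slot scores n x l score matrix T with mutually orthogonal columns.
#' @slot scoreNorms numeric length l, the inner products t_b' t_b.
#' @slot coefficients p x m coefficient matrix B = R Q'.
#' @exportClass PLSModel
setClass("PLSModel",
  representation(
    nComponents = "integer",
    weights = "matrix",
    rotations = "matrix",
    xLoadings = "matrix",
    uLoadings = "matrix",
    scores = "matrix",
    scoreNorms = "numeric",
    coefficients = "matrix"
  )
)

setValidity("PLSModel", function(object) {
  l <- object@nComponents
  W <- object@weights
  if (ncol(W) != l || ncol(object@rotations) != l ||
      ncol(object@scores) != l || length(object@scoreNorms) != l) {
    return("component dimensions inconsistent with nComponents")
  }
  wn <- sqrt(colSums(W^2))
  if (max(abs(wn - 1)) > 1e-10) return("weight columns must have unit norm")
  ## score orthogonality, relative to the column norms
  TT <- object@scores
  if (l > 1) {
    G <- crossprod(TT)
    nrm <- sqrt(diag(G))
    off <- abs(G / outer(nrm, nrm))
    diag(off) <- 0
    if (max(off) > 1e-8) return("score columns are not mutually orthogonal")
  }
  B <- object@rotations %*% t(object@uLoadings)
  if (max(abs(B - object@coefficients)) >
      1e-10 * max(1, max(abs(B)))) {
    return("coefficients must equal rotations %*% t(uLoadings)")
  }
  TRUE
})

#' Inferred latent treatment scores
#'
#' The first-component X-side PLS score, rescaled to unit sample variance,
#' used as the inferred latent treatment. `orientationAnchor` stores the
#' first rotation vector r_1 so bootstrap refits can be sign-aligned to the
#' original fit.
#'
#' @slot zHat numeric length n, mean 0 and sample variance 1.
#' @slot scores n x l matrix of all component scores, each standardized to
#'   unit variance (first column equals `zHat`).
#' @slot componentsUsed integer l.
#' @slot orientationAnchor numeric length p, reference rotation r_1.
#' @exportClass LatentScores
setClass("LatentScores",
  representation(
    zHat = "numeric",
    scores = "matrix",
    componentsUsed = "integer",
    orientationAnchor = "numeric"
  )
)

setValidity("LatentScores", function(object) {
  z <- object@zHat
  if (length(z) >= 3) {
    if (abs(mean(z)) > 1e-10) return("zHat must have mean 0")
    if (abs(stats::var(z) - 1) > 1e-10) return("zHat must have unit variance")
  }
  TRUE
})

#' Latent causal effect estimate
#'
#' Point estimate of the local causal effect (per 1 SD of the inferred
#' latent treatment) with a nonparametric bootstrap percentile confidence
#' interval and the full replicate record.
#'
#' @slot lce numeric, slope of the working outcome on the unit-variance
#'   latent score (first component).
#' @slot componentEffects numeric length l, per-component slopes.
#' @slot ciLower,ciUpper,ciLevel numeric, percentile interval bounds and
#'   nominal level.
#' @slot nBoot integer, bootstrap replicates requested.
#' @slot bootReplicates numeric, successful replicate estimates.
#' @slot nUsed integer, analysis sample size after complete-case filtering.
#' @slot seed integer RNG seed used for resampling.
#' @slot droppedSubjects,droppedFeatures integer counts removed in
#'   preprocessing.
#' @slot outcomeKind character, one of continuous/binary/survival.
#' @slot latentScores the [LatentScores-class] of the original fit.
#' @exportClass CausalEstimate
setClass("CausalEstimate",
  representation(
    lce = "numeric",
    componentEffects = "numeric",
    ciLower = "numeric",
    ciUpper = "numeric",
    ciLevel = "numeric",
    nBoot = "integer",
    bootReplicates = "numeric",
    nUsed = "integer",
    seed = "integer",
    droppedSubjects = "integer",
    droppedFeatures = "integer",
    outcomeKind = "character",
    latentScores = "LatentScores"
  )
)

setValidity("CausalEstimate", function(object) {
  if (object@ciLevel <= 0 || object@ciLevel >= 1) {
    return("ciLevel must be in (0, 1)")
  }
  if (object@nBoot < 1L) return("nBoot must be >= 1")
  TRUE
})

#' First-principal-component regression baseline
#'
#' Ordinary least-squares fit of the outcome on the first principal
#' component of the standardized feature matrix plus the confounder
#' columns, the comparison model for the latent-treatment estimator.
#'
#' @slot coefficients named numeric: intercept, PC1, then confounders.
#' @slot standardErrors named numeric, same order.
#' @slot pc1Scores numeric length n projection on the dominant eigenvector.
#' @slot pc1Loading numeric length K, the dominant eigenvector itself.
#' @exportClass PCABaselineFit
setClass("PCABaselineFit",
  representation(
    coefficients = "numeric",
    standardErrors = "numeric",
    pc1Scores = "numeric",
    pc1Loading = "numeric"
  )
)

#' Null-model cumulative hazard
#'
#' Nelson-Aalen estimate of the cumulative hazard of a covariate-free
#' proportional hazards model, stored at the distinct event times.
#'
#' @slot eventTimes sorted distinct times with at least one event.
#' @slot hazard nondecreasing cumulative hazard at those times.
#' @exportClass CumulativeHazard
setClass("CumulativeHazard",
  representation(eventTimes = "numeric", hazard = "numeric")
)

setValidity("CumulativeHazard", function(object) {
  if (length(object@eventTimes) != length(object@hazard)) {
    return("eventTimes and hazard must have equal length")
  }
  if (is.unsorted(object@eventTimes, strictly = TRUE)) {
    return("eventTimes must be strictly increasing")
  }
  if (length(object@hazard) && (any(diff(object@hazard) < 0) ||
      object@hazard[1L] < 0)) {
    return("hazard must be nonnegative and nondecreasing")
  }
  TRUE
})

#' Working outcome for the causal regression
#'
#' The single continuous response regressed on the latent score:
#' a continuous outcome unchanged, a binary outcome on the 0/1 scale, or
#' null-model martingale residuals for right-censored survival.
#'
#' @slot y numeric working response.
#' @slot kind one of "continuous", "binary", "survival".
#' @slot provenance character, human-readable transformation record.
#' @exportClass WorkingResponse
setClass("WorkingResponse",
  representation(y = "numeric", kind = "character", provenance = "character")
)

setValidity("WorkingResponse", function(object) {
  if (!object@kind %in% c("continuous", "binary", "survival")) {
    return("kind must be continuous, binary or survival")
  }
  if (any(!is.finite(object@y))) return("working response must be finite")
  if (object@kind == "survival" && length(object@y) &&
      abs(sum(object@y)) > 1e-8 * max(1, length(object@y))) {
    return("survival working response (martingale residuals) must sum to 0")
  }
  TRUE
})

#' Simulated latent-treatment dataset
#'
#' One draw from the latent-treatment causal diagram: multivariate normal
#' confounders X, latent treatment Z = X gamma + sigma_z eps, features
#' U_k = g_k(a_k Z) + noise loading on Z (conditionally independent given
#' Z), and an outcome depending on X only through Z (unless a direct
#' X-to-outcome violation term is requested).
#'
#' @slot X n x p confounder matrix.
#' @slot zTrue numeric length n latent treatment.
#' @slot U n x K feature matrix.
#' @slot y numeric outcome (continuous or 0/1 binary); length 0 for
#'   survival datasets.
#' @slot times,events numeric survival columns; length 0 otherwise.
#' @slot config the generating [simConfig()] list (seed included).
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
  representation(
    X = "matrix",
    zTrue = "numeric",
    U = "matrix",
    y = "numeric",
    times = "numeric",
    events = "numeric",
    config = "list"
  )
)
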