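## Two-stage latent-treatment estimator:
##   stage 1 - kernel PLS of standardized features U on standardized
##             confounders X; the first X-side score (unit variance) is the
##             inferred latent treatment;
##   stage 2 - OLS of the working outcome on the score; nonparametric
##             bootstrap (subjects resampled, the whole pipeline re-run,
##             replicates sign-aligned through the rotation vector) gives
##             percentile intervals.

## lean column standardization for the bootstrap hot loop (no S4, no checks)
.fastStd <- function(m, dropZero = TRUE) {
  mu <- colMeans(m)
  v <- sweep(m, 2L, mu, "-")
  sdv <- sqrt(colSums(v^2) / (nrow(m) - 1L))
  zero <- sdv < .Machine$double.eps^0.5 * pmax(1, abs(mu))
  if (any(zero)) {
    if (!dropZero) stop("zero-variance confounder column in resample")
    if (all(zero)) stop("all feature columns constant in resample")
    v <- v[, !zero, drop = FALSE]
    sdv <- sdv[!zero]
  }
  sweep(v, 2L, sdv, "/")
}

## slopes of y on each unit-variance score column + first rotation
.lceFit <- function(U, X, y, l) {
  Us <- .fastStd(U, dropZero = TRUE)
  Xs <- .fastStd(X, dropZero = FALSE)
  fit <- .plsCore(Xs, Us, l)
  n <- nrow(Xs)
  yc <- y - mean(y)
  slopes <- numeric(l)
  z1 <- NULL
  for (j in seq_len(l)) {
    tj <- fit$TT[, j]
    sdt <- sqrt(sum(tj^2) / (n - 1L))
    zj <- tj / sdt
    if (j == 1L) z1 <- zj
    slopes[j] <- sum(zj * yc) / (n - 1L)
  }
  list(slopes = slopes, r1 = fit$R[, 1L], z1 = z1, TT = fit$TT)
}

#' Infer the latent treatment from standardized matrices
#'
#' Fits [fitKernelPLS()] with the confounders as predictors and the
#' radiomics features as the multivariate response, and returns the
#' X-side scores rescaled to unit sample variance. The first component is
#' the inferred latent treatment; its rotation vector r_1 is kept as the
#' orientation anchor for sign-aligning bootstrap refits.
#'
#' @param U standardized feature matrix (n x K) or
#'   [StandardizedMatrix-class].
#' @param X standardized confounder matrix (n x p) or
#'   [StandardizedMatrix-class].
#' @param l number of components (default 1, a scalar latent treatment).
#' @return a [LatentScores-class].
#' @export
inferLatentTreatment <- function(U, X, l = 1L) {
  U <- .asMatrix(U); X <- .asMatrix(X)
  if (nrow(U) != nrow(X)) stop("U and X must have the same number of rows")
  model <- fitKernelPLS(X, U, l = l)
  TT <- model@scores
  n <- nrow(TT)
  Z <- sweep(TT, 2L, sqrt(colSums(TT^2) / (n - 1L)), "/")
  z <- Z[, 1L]
  names(z) <- rownames(X)
  methods::new("LatentScores", zHat = z, scores = Z,
               componentsUsed = as.integer(l),
               orientationAnchor = model@rotations[, 1L])
}

#' Regress the working outcome on the latent score
#'
#' Ordinary least squares of y on (1, z). The slope is the local causal
#' effect per 1 SD of the inferred latent treatment.
#'
#' @param y numeric response or [WorkingResponse-class].
#' @param z numeric score or [LatentScores-class].
#' @return list with `slope` (the LCE), `intercept`, `residualSD`, `n`.
#' @export
fitOutcomeRegression <- function(y, z) {
  if (methods::is(y, "WorkingResponse")) y <- y@y
  if (methods::is(z, "LatentScores")) z <- z@zHat
  n <- length(y)
  if (n != length(z)) stop("y and z lengths differ")
  if (n < 3L) stop("need n >= 3")
  zc <- z - mean(z)
  vz <- sum(zc^2)
  slope <- if (vz <= 0) 0 else sum(zc * (y - mean(y))) / vz
  intercept <- mean(y) - slope * mean(z)
  res <- y - intercept - slope * z
  list(slope = slope, intercept = intercept,
       residualSD = sqrt(sum(res^2) / max(1L, n - 2L)), n = n)
}

## outcome columns as plain vectors so bootstrap replicates can rebuild the
## working response (martingale residuals included) from a row index
.outcomeData <- function(clinical, spec) {
  if (spec$kind == "survival") {
    list(kind = "survival",
         times = as.numeric(clinical[[spec$timeColumn]]),
         events = as.numeric(clinical[[spec$eventColumn]]))
  } else if (spec$kind == "binary") {
    x <- as.character(clinical[[spec$valueColumn]])
    lev <- unique(x)
    if (length(lev) > 2L) {
      stop("binary outcome column '", spec$valueColumn, "' has ",
           length(lev), " observed values")
    }
    list(kind = "binary", y = as.numeric(x == spec$positiveLabel))
  } else {
    list(kind = "continuous", y = as.numeric(clinical[[spec$valueColumn]]))
  }
}

.workingY <- function(od, idx) {
  if (od$kind == "survival") {
    martingaleResiduals(od$times[idx], od$events[idx])@y
  } else {
    od$y[idx]
  }
}

#' @rdname estimateLCE
setMethod("estimateLCE", signature(features = "matrix", clinical = "data.frame"),
  function(features, clinical, confounders, outcome, nComponents = 1L,
           nBoot = 1000L, ciLevel = 0.95, seed = 1L, ...) {
    stopifnot(inherits(outcome, "outcomeSpec"))
    l <- as.integer(nComponents)
    nBoot <- as.integer(nBoot)
    seed <- as.integer(seed)
    if (nBoot < 1L) stop("nBoot must be >= 1")
    if (nBoot < 50L) warning("nBoot < 50: percentile interval is unreliable")

    enc <- tryCatch(encodeConfounders(clinical, confounders),
                    error = function(e) stop("confounder encoding: ",
                                             conditionMessage(e), call. = FALSE))
    cc <- tryCatch(completeCases(features, enc, clinical,
                                 outcomeColumns(outcome)),
                   error = function(e) stop("complete cases: ",
                                            conditionMessage(e), call. = FALSE))
    U <- cc$features
    X <- cc$confounders
    od <- .outcomeData(cc$clinical, outcome)
    n <- nrow(U)
    idx0 <- seq_len(n)

    ## dropped feature count + rank/l validation via the user-facing path
    Us <- withCallingHandlers(standardize(U, onConstant = "drop"),
                              warning = function(w) invokeRestart("muffleWarning"))
    droppedFeatures <- length(Us@droppedColumns)
    Xs <- standardize(X, onConstant = "error")
    rk <- qr(Xs@values)$rank
    if (l > rk) stop("nComponents = ", l, " exceeds rank of the confounder design (", rk, ")")

    fit0 <- .lceFit(U, X, .workingY(od, idx0), l)
    anchor <- fit0$r1

    set.seed(seed)
    reps <- numeric(nBoot)
    ok <- logical(nBoot)
    for (b in seq_len(nBoot)) {
      idx <- sample.int(n, n, replace = TRUE)
      reps[b] <- tryCatch({
        fb <- .lceFit(U[idx, , drop = FALSE], X[idx, , drop = FALSE],
                      .workingY(od, idx), l)
        s <- sum(fb$r1 * anchor)
        sgn <- if (s < 0) -1 else 1
        ok[b] <- TRUE
        sgn * fb$slopes[1L]
      }, error = function(e) NA_real_)
    }
    nFail <- sum(!ok)
    if (nFail > 0.2 * nBoot) {
      stop("bootstrap: ", nFail, " of ", nBoot, " replicates failed")
    }
    if (nFail > 0) warning("bootstrap: ", nFail, " replicate(s) failed and were skipped")
    good <- reps[ok]
    a <- (1 - ciLevel) / 2
    ci <- unname(stats::quantile(good, c(a, 1 - a), type = 7))

    zH <- fit0$z1
    names(zH) <- rownames(U)
    Zm <- sweep(fit0$TT, 2L,
                sqrt(colSums(fit0$TT^2) / (n - 1L)), "/")
    scores <- methods::new("LatentScores", zHat = zH, scores = Zm,
                           componentsUsed = l, orientationAnchor = anchor)
    methods::new("CausalEstimate",
                 lce = fit0$slopes[1L], componentEffects = fit0$slopes,
                 ciLower = ci[1L], ciUpper = ci[2L], ciLevel = ciLevel,
                 nBoot = nBoot, bootReplicates = good,
                 nUsed = as.integer(n), seed = seed,
                 droppedSubjects = as.integer(cc$droppedCount),
                 droppedFeatures = as.integer(droppedFeatures),
                 outcomeKind = od$kind, latentScores = scores)
  })

#' @rdname estimateLCE
setMethod("estimateLCE",
  signature(features = "SummarizedExperiment", clinical = "missing"),
  function(features, clinical, confounders, outcome, ...) {
    U <- t(SummarizedExperiment::assay(features))
    cd <- as.data.frame(SummarizedExperiment::colData(features))
    rownames(cd) <- colnames(features)
    estimateLCE(U, cd, confounders = confounders, outcome = outcome, ...)
  })

#' Write a causal estimate to disk
#'
#' Writes `results.json` (estimate, interval, bookkeeping) and
#' `scores.tsv` (subject_id, z_hat) under `dir`.
#'
#' @param estimate a [CausalEstimate-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writeResults <- function(estimate, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonPath <- file.path(dir, "results.json")
  out <- list(lce = estimate@lce, ci_lower = estimate@ciLower,
              ci_upper = estimate@ciUpper, ci_level = estimate@ciLevel,
              n_boot = estimate@nBoot, n_used = estimate@nUsed,
              seed = estimate@seed,
              dropped_subjects = estimate@droppedSubjects,
              dropped_features = estimate@droppedFeatures,
              components_used = estimate@latentScores@componentsUsed,
              outcome_kind = estimate@outcomeKind)
  jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA)
  z <- estimate@latentScores@zHat
  tsvPath <- file.path(dir, "scores.tsv")
  utils::write.table(
    data.frame(subject_id = if (is.null(names(z))) seq_along(z) else names(z),
               z_hat = as.numeric(z)),
    tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(jsonPath, tsvPath))
}
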