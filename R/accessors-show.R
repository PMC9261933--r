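#' Accessors for PLS fits
#'
#' @param object a [PLSModel-class].
#' @return the requested component matrix or vector.
#' @name plsAccessors
NULL

#' @rdname plsAccessors
setMethod("nComponents", "PLSModel", function(object) object@nComponents)
#' @rdname plsAccessors
setMethod("plsWeights", "PLSModel", function(object) object@weights)
#' @rdname plsAccessors
setMethod("plsRotations", "PLSModel", function(object) object@rotations)
#' @rdname plsAccessors
setMethod("xLoadings", "PLSModel", function(object) object@xLoadings)
#' @rdname plsAccessors
setMethod("uLoadings", "PLSModel", function(object) object@uLoadings)
#' @rdname plsAccessors
setMethod("scoreNorms", "PLSModel", function(object) object@scoreNorms)
#' @rdname plsAccessors
setMethod("plsCoefficients", "PLSModel", function(object) object@coefficients)

setMethod("plsScores", signature("PLSModel", "missing"),
  function(object, newdata) object@scores)

setMethod("plsScores", signature("PLSModel", "matrix"),
  function(object, newdata) {
    if (ncol(newdata) != nrow(object@rotations)) {
      stop("newdata has ", ncol(newdata), " columns; model expects ",
           nrow(object@rotations))
    }
    newdata %*% object@rotations
  })

setMethod("plsPredict", signature("PLSModel", "matrix"),
  function(object, newdata) {
    if (ncol(newdata) != nrow(object@coefficients)) {
      stop("newdata has ", ncol(newdata), " columns; model expects ",
           nrow(object@coefficients))
    }
    newdata %*% object@coefficients
  })

setMethod("plsPredict", signature("PLSModel", "missing"),
  function(object, newdata) object@scores %*% t(object@uLoadings))

setMethod("show", "PLSModel", function(object) {
  cat("PLSModel (multivariate kernel partial least squares)\n")
  cat("  components:", object@nComponents, "\n")
  cat("  predictors:", nrow(object@rotations),
      " responses:", nrow(object@uLoadings),
      " samples:", nrow(object@scores), "\n")
  cat("  score norms:",
      paste(signif(object@scoreNorms, 4), collapse = ", "), "\n")
})

#' Accessors for standardized matrices
#'
#' @param object a [StandardizedMatrix-class].
#' @name stdAccessors
NULL

#' @rdname stdAccessors
setMethod("stdValues", "StandardizedMatrix", function(object) object@values)
#' @rdname stdAccessors
setMethod("stdCenters", "StandardizedMatrix", function(object) object@colMeans)
#' @rdname stdAccessors
setMethod("stdScales", "StandardizedMatrix", function(object) object@colScales)
#' @rdname stdAccessors
setMethod("droppedColumns", "StandardizedMatrix",
  function(object) object@droppedColumns)

setMethod("show", "StandardizedMatrix", function(object) {
  cat("StandardizedMatrix:", nrow(object@values), "x", ncol(object@values),
      "(centered, unit sample sd)\n")
  if (length(object@droppedColumns)) {
    cat("  dropped zero-variance columns:",
        paste(object@droppedColumns, collapse = ", "), "\n")
  }
})

#' Accessors for latent scores
#'
#' @param object a [LatentScores-class] or [CausalEstimate-class].
#' @name latentAccessors
NULL

#' @rdname latentAccessors
setMethod("latentScores", "LatentScores", function(object) object@zHat)
#' @rdname latentAccessors
setMethod("latentScores", "CausalEstimate",
  function(object) object@latentScores@zHat)

setMethod("show", "LatentScores", function(object) {
  cat("LatentScores: n =", length(object@zHat),
      " components =", object@componentsUsed, "\n")
  cat("  (first-component PLS score, unit variance)\n")
})

#' Accessors for causal estimates
#'
#' @param object a [CausalEstimate-class].
#' @param parm,level ignored (interval level is fixed at fit time).
#' @name causalAccessors
NULL

#' @rdname causalAccessors
setMethod("lce", "CausalEstimate", function(object) object@lce)
#' @rdname causalAccessors
setMethod("bootReplicates", "CausalEstimate",
  function(object) object@bootReplicates)

#' @rdname causalAccessors
#' @param object a [CausalEstimate-class].
#' @export
setMethod("confint", "CausalEstimate", function(object, parm, level) {
  out <- matrix(c(object@ciLower, object@ciUpper), 1L, 2L)
  a <- (1 - object@ciLevel) / 2
  colnames(out) <- sprintf("%.1f %%", 100 * c(a, 1 - a))
  rownames(out) <- "lce"
  out
})

setMethod("show", "CausalEstimate", function(object) {
  cat("CausalEstimate (latent-treatment local causal effect)\n")
  cat(sprintf("  LCE: %.4g per SD of inferred latent treatment\n", object@lce))
  cat(sprintf("  %g%% bootstrap percentile CI: (%.4g, %.4g)  [B = %d, %d ok]\n",
              100 * object@ciLevel, object@ciLower, object@ciUpper,
              object@nBoot, length(object@bootReplicates)))
  cat("  outcome:", object@outcomeKind,
      " n used:", object@nUsed,
      " dropped subjects:", object@droppedSubjects,
      " dropped features:", object@droppedFeatures, "\n")
  if (length(object@componentEffects) > 1L) {
    cat("  per-component slopes:",
        paste(signif(object@componentEffects, 4), collapse = ", "), "\n")
  }
})

setMethod("show", "PCABaselineFit", function(object) {
  cat("PCABaselineFit (outcome ~ PC1 + confounders)\n")
  tab <- cbind(estimate = object@coefficients, se = object@standardErrors)
  print(signif(tab, 4))
})

setMethod("show", "CumulativeHazard", function(object) {
  cat("CumulativeHazard (Nelson-Aalen, null model):",
      length(object@eventTimes), "event times\n")
  if (length(object@eventTimes)) {
    cat(sprintf("  Lambda(%g) = %.4g at the last event time\n",
                max(object@eventTimes), max(object@hazard)))
  }
})

setMethod("show", "WorkingResponse", function(object) {
  cat("WorkingResponse:", object@kind, "| n =", length(object@y), "\n")
  cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "SimulatedDataset", function(object) {
  cat("SimulatedDataset: n =", nrow(object@X),
      " p =", ncol(object@X), " K =", ncol(object@U), "\n")
  cat("  outcome:", object@config$outcomeKind,
      " theta =", object@config$theta,
      " seed =", object@config$seed, "\n")
})
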