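#' @rdname plsAccessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname plsAccessors
#' @export
setGeneric("plsWeights", function(object) standardGeneric("plsWeights"))

#' @rdname plsAccessors
#' @export
setGeneric("plsRotations", function(object) standardGeneric("plsRotations"))

#' @rdname plsAccessors
#' @export
setGeneric("xLoadings", function(object) standardGeneric("xLoadings"))

#' @rdname plsAccessors
#' @export
setGeneric("uLoadings", function(object) standardGeneric("uLoadings"))

#' @rdname plsAccessors
#' @export
setGeneric("scoreNorms", function(object) standardGeneric("scoreNorms"))

#' @rdname plsAccessors
#' @export
setGeneric("plsCoefficients", function(object) standardGeneric("plsCoefficients"))

#' Compute PLS scores for new data
#'
#' Projects a matrix (standardized with the training parameters) onto the
#' fitted rotations: `scores = X_new %*% R`. With `newdata` missing the
#' training scores are returned.
#'
#' @param object a [PLSModel-class].
#' @param newdata optional matrix with p columns on the training
#'   standardized scale.
#' @return numeric matrix of scores, one column per component.
#' @export
setGeneric("plsScores", function(object, newdata) standardGeneric("plsScores"))

#' Predict the multivariate response from a PLS fit
#'
#' Returns `X_new %*% B` on the standardized response scale.
#'
#' @param object a [PLSModel-class].
#' @param newdata matrix with p columns on the training standardized scale;
#'   defaults to the training scores reconstruction.
#' @return numeric matrix of fitted standardized responses.
#' @export
setGeneric("plsPredict", function(object, newdata) standardGeneric("plsPredict"))

#' Column-standardize a matrix, keeping the transform
#'
#' Centers each column to mean 0 and scales to unit sample standard
#' deviation (n-1 denominator). Columns with zero variance are either
#' dropped with a warning (`onConstant = "drop"`, appropriate for
#' high-dimensional feature tables where constant features occur) or raise
#' an error (`onConstant = "error"`, appropriate for confounder designs
#' where a constant column is a user mistake).
#'
#' @param x numeric matrix with at least 3 rows, or an object coercible to
#'   one.
#' @param onConstant what to do with zero-variance columns.
#' @return a [StandardizedMatrix-class].
#' @examples
#' s <- standardize(matrix(rnorm(30), 10, 3))
#' colMeans(stdValues(s))  # ~0
#' @export
setGeneric("standardize",
  function(x, onConstant = c("drop", "error")) standardGeneric("standardize"))

#' @rdname stdAccessors
#' @export
setGeneric("stdValues", function(object) standardGeneric("stdValues"))

#' @rdname stdAccessors
#' @export
setGeneric("stdCenters", function(object) standardGeneric("stdCenters"))

#' @rdname stdAccessors
#' @export
setGeneric("stdScales", function(object) standardGeneric("stdScales"))

#' @rdname stdAccessors
#' @export
setGeneric("droppedColumns", function(object) standardGeneric("droppedColumns"))

#' @rdname latentAccessors
#' @export
setGeneric("latentScores", function(object) standardGeneric("latentScores"))

#' @rdname causalAccessors
#' @export
setGeneric("lce", function(object) standardGeneric("lce"))

#' @rdname causalAccessors
#' @export
setGeneric("bootReplicates", function(object) standardGeneric("bootReplicates"))

#' Estimate the latent-treatment local causal effect
#'
#' End-to-end two-stage estimator: encode confounders, take complete cases,
#' build the working outcome, standardize features and confounders, infer
#' the latent treatment as the first-component kernel PLS score of features
#' on confounders, regress the working outcome on the unit-variance score,
#' and attach a nonparametric bootstrap percentile confidence interval in
#' which the whole pipeline (standardization included) is re-run on every
#' resample.
#'
#' @param features subject-by-feature numeric matrix with subject ids as
#'   row names, or a `SummarizedExperiment` (features in rows, subjects in
#'   columns, clinical variables in `colData`).
#' @param clinical data.frame of clinical covariates keyed by a
#'   `subject_id` column (or row names); ignored for the
#'   `SummarizedExperiment` method.
#' @param confounders covariate schema: named character vector mapping
#'   column name to kind in `numeric`, `binary`, `categorical`.
#' @param outcome an [outcomeSpec()].
#' @param nComponents number of PLS components (default 1: a scalar latent
#'   treatment); with more components a slope is reported per component and
#'   the interval refers to the first.
#' @param nBoot bootstrap replicates (default 1000).
#' @param ciLevel nominal interval level (default 0.95).
#' @param seed integer seed for the bootstrap resampling.
#' @param ... passed to methods.
#' @return a [CausalEstimate-class].
#' @export
setGeneric("estimateLCE", function(features, clinical, ...) {
  standardGeneric("estimateLCE")
})
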