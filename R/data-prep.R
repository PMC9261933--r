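## Reading, aligning, encoding and standardizing subject-level tables.

.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a subject-by-feature radiomics table
#'
#' CSV or TSV (separator auto-detected), first column `subject_id`,
#' remaining columns numeric features, header required. Missing values may
#' be empty cells or `NA`.
#'
#' @param path file path.
#' @return numeric matrix with subject ids as row names.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sniffSep(path),
                          colClasses = NA, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), check.names = FALSE)
  if (ncol(df) < 2L) stop("feature table needs subject_id plus >= 1 feature")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate subject_id in feature table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("feature columns must be numeric")
  rownames(m) <- ids
  m
}

#' Read a subject-level clinical table
#'
#' CSV or TSV with a `subject_id` first column; covariates and outcome
#' columns are addressed by name downstream.
#'
#' @param path file path.
#' @return data.frame with row names set to subject_id (the id column is
#'   retained as `subject_id`).
#' @export
readClinicalTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sniffSep(path),
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), check.names = FALSE)
  names(df)[1L] <- "subject_id"
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in clinical table")
  rownames(df) <- df$subject_id
  df
}

#' Bundle features and clinical data in a SummarizedExperiment
#'
#' Stores the feature matrix as an assay (features in rows, subjects in
#' columns, the Bioconductor orientation) with the clinical table as
#' `colData`.
#'
#' @param features subject-by-feature numeric matrix, subject ids as row
#'   names.
#' @param clinical data.frame keyed by `subject_id` column or row names.
#' @return a `SummarizedExperiment`.
#' @export
RadiomicsSE <- function(features, clinical) {
  clinical <- .keyClinical(clinical)
  ids <- intersect(rownames(features), rownames(clinical))
  if (!length(ids)) stop("no shared subject ids between features and clinical")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(radiomics = t(features[ids, , drop = FALSE])),
    colData = S4Vectors::DataFrame(clinical[ids, , drop = FALSE])
  )
}

.keyClinical <- function(clinical) {
  clinical <- as.data.frame(clinical)
  if ("subject_id" %in% names(clinical)) {
    rownames(clinical) <- as.character(clinical$subject_id)
  } else if (is.null(rownames(clinical))) {
    stop("clinical table needs a subject_id column or row names")
  }
  clinical
}

#' Encode clinical covariates into a numeric design matrix
#'
#' Numeric covariates pass through; binary covariates become one 0/1
#' column (reference = first level in lexicographic sort); categorical
#' covariates with L observed levels become L-1 dummy columns against the
#' first sorted level. The level-to-column map is recorded in the
#' `"encodingMap"` attribute for reproducibility.
#'
#' @param clinical data.frame keyed by `subject_id` column or row names.
#' @param schema named character vector, covariate name -> kind in
#'   `"numeric"`, `"binary"`, `"categorical"`.
#' @return numeric matrix (rows = subjects, possibly containing NA for
#'   missing covariate values) with attribute `encodingMap`.
#' @examples
#' cl <- data.frame(subject_id = c("a", "b", "c"),
#'                  sex = c("F", "M", "F"), age = c(61, 45, 70))
#' encodeConfounders(cl, c(sex = "binary", age = "numeric"))
#' @export
encodeConfounders <- function(clinical, schema) {
  clinical <- .keyClinical(clinical)
  if (is.list(schema)) schema <- unlist(schema)
  kinds <- as.character(schema)
  nms <- names(schema)
  if (is.null(nms) || any(!nzchar(nms))) stop("schema must be named")
  missingCols <- setdiff(nms, names(clinical))
  if (length(missingCols)) {
    stop("covariates not in clinical table: ", paste(missingCols, collapse = ", "))
  }
  bad <- setdiff(kinds, c("numeric", "binary", "categorical"))
  if (length(bad)) stop("unknown covariate kind: ", paste(bad, collapse = ", "))

  cols <- list()
  emap <- list()
  for (i in seq_along(nms)) {
    nm <- nms[i]
    x <- clinical[[nm]]
    if (kinds[i] == "numeric") {
      cols[[nm]] <- as.numeric(x)
      emap[[nm]] <- list(kind = "numeric")
    } else {
      lev <- sort(unique(as.character(x[!is.na(x)])))
      if (length(lev) < 2L) {
        stop("covariate '", nm, "' has a single observed level")
      }
      if (kinds[i] == "binary" && length(lev) != 2L) {
        stop("covariate '", nm, "' declared binary but has ",
             length(lev), " levels")
      }
      xc <- as.character(x)
      for (l in lev[-1L]) {
        cn <- paste0(nm, l)
        cols[[cn]] <- ifelse(is.na(xc), NA_real_, as.numeric(xc == l))
      }
      emap[[nm]] <- list(kind = kinds[i], reference = lev[1L],
                         levels = lev,
                         columns = paste0(nm, lev[-1L]))
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(clinical)
  attr(out, "encodingMap") <- emap
  out
}

#' Align tables and drop incomplete subjects
#'
#' Takes the intersection of subject ids across the feature matrix, the
#' encoded confounder matrix and the clinical table, then removes every
#' subject with a missing value in any feature, confounder, or outcome
#' column. All three outputs share the same subject order (order of the
#' feature table).
#'
#' @param features subject-by-feature matrix, ids as row names.
#' @param confounders encoded design matrix from [encodeConfounders()].
#' @param clinical clinical data.frame.
#' @param outcomeColumns character, outcome column names checked for
#'   missingness.
#' @return list with elements `features`, `confounders`, `clinical`,
#'   `droppedCount`, `droppedIds`.
#' @export
completeCases <- function(features, confounders, clinical,
                          outcomeColumns = character()) {
  clinical <- .keyClinical(clinical)
  allIds <- unique(c(rownames(features), rownames(confounders),
                     rownames(clinical)))
  ids <- rownames(features)
  ids <- ids[ids %in% rownames(confounders) & ids %in% rownames(clinical)]
  if (length(outcomeColumns)) {
    miss <- setdiff(outcomeColumns, names(clinical))
    if (length(miss)) stop("outcome columns missing: ", paste(miss, collapse = ", "))
  }
  keep <- vapply(ids, function(id) {
    !anyNA(features[id, ]) && !anyNA(confounders[id, ]) &&
      (!length(outcomeColumns) || !anyNA(clinical[id, outcomeColumns]))
  }, logical(1L))
  kept <- ids[keep]
  if (!length(kept)) stop("no complete cases remain")
  dropped <- setdiff(allIds, kept)
  list(
    features = features[kept, , drop = FALSE],
    confounders = confounders[kept, , drop = FALSE],
    clinical = clinical[kept, , drop = FALSE],
    droppedCount = length(dropped),
    droppedIds = dropped
  )
}

#' @rdname standardize
setMethod("standardize", "matrix", function(x, onConstant = c("drop", "error")) {
  onConstant <- match.arg(onConstant)
  if (nrow(x) < 3L) stop("standardize needs n >= 3 rows")
  if (any(!is.finite(x))) stop("matrix must be finite (run completeCases first)")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  zero <- sdv < .Machine$double.eps^0.5 * pmax(1, abs(mu))
  dropped <- colnames(x)[zero]
  if (all(zero)) stop("all columns have zero variance")
  if (length(dropped)) {
    if (onConstant == "error") {
      stop("zero-variance column(s): ", paste(dropped, collapse = ", "))
    }
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
  }
  keep <- !zero
  v <- sweep(x[, keep, drop = FALSE], 2L, mu[keep], "-")
  v <- sweep(v, 2L, sdv[keep], "/")
  methods::new("StandardizedMatrix", values = v,
               colMeans = mu[keep], colScales = sdv[keep],
               droppedColumns = dropped)
})

#' @rdname standardize
setMethod("standardize", "data.frame", function(x, onConstant = c("drop", "error")) {
  standardize(as.matrix(x), onConstant = onConstant)
})

#' Apply a stored standardization to new data
#'
#' Applies the affine transform learned by [standardize()] (dropping the
#' same zero-variance columns) so resampled or held-out rows live on the
#' training scale.
#'
#' @param object a [StandardizedMatrix-class].
#' @param newdata matrix whose columns include the retained training
#'   columns (matched by name when present, by position otherwise).
#' @return numeric matrix on the standardized scale.
#' @export
applyStandardization <- function(object, newdata) {
  stopifnot(methods::is(object, "StandardizedMatrix"))
  nm <- names(object@colMeans)
  if (!is.null(colnames(newdata)) && !is.null(nm) && all(nm %in% colnames(newdata))) {
    newdata <- newdata[, nm, drop = FALSE]
  } else if (ncol(newdata) != length(object@colMeans)) {
    stop("newdata columns do not match the stored transform")
  }
  v <- sweep(newdata, 2L, object@colMeans, "-")
  sweep(v, 2L, object@colScales, "/")
}
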