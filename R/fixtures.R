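## Small on-disk CSV fixtures matching the reader interfaces.

.fixtureConfig <- function(kind, seed) {
  switch(kind,
    tiny = simConfig(n = 40L, p = 2L, K = 10L, outcomeKind = "continuous",
                     seed = seed),
    binary = simConfig(n = 60L, p = 2L, K = 15L, outcomeKind = "binary",
                       seed = seed),
    survival = simConfig(n = 60L, p = 2L, K = 12L, gamma = rep(1, 2),
                         theta = 0.5, outcomeKind = "survival",
                         censorRate = 0.25, seed = seed),
    stop("unknown fixture kind: ", kind)
  )
}

#' Write a small fixture dataset to disk
#'
#' Generates a seeded dataset from the latent-treatment diagram and writes
#' `features.csv` (subject_id + numeric features), `clinical.csv`
#' (subject_id, a numeric `age` and a binary `group` confounder derived
#' from the generating confounders, plus outcome columns) and
#' `config.txt` (key: value echo of the generating configuration).
#' Regenerating with the same seed is byte-identical.
#'
#' @param kind `"tiny"` (n=40, K=10, continuous outcome), `"binary"`
#'   (n=60, K=15, effective/ineffective response) or `"survival"` (n=60,
#'   K=12, time + 0/1 event, ~25\% censoring).
#' @param dir output directory (created if needed).
#' @param seed RNG seed (a fixed per-kind default keeps committed fixtures
#'   stable).
#' @return invisibly, named character vector of the three file paths.
#' @export
makeFixture <- function(kind = c("tiny", "binary", "survival"), dir,
                        seed = NULL) {
  kind <- match.arg(kind)
  if (is.null(seed)) {
    seed <- c(tiny = 101L, binary = 202L, survival = 303L)[[kind]]
  }
  cfg <- .fixtureConfig(kind, as.integer(seed))
  d <- simulateDataset(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- rownames(d@U)

  featPath <- file.path(dir, "features.csv")
  utils::write.csv(data.frame(subject_id = ids, round(d@U, 6),
                              check.names = FALSE),
                   featPath, row.names = FALSE, quote = FALSE)

  clin <- data.frame(
    subject_id = ids,
    age = round(55 + 2 * d@X[, 1L], 1),
    group = ifelse(d@X[, 2L] > 0, "B", "A")
  )
  if (kind == "tiny") {
    clin$y <- round(d@y, 6)
  } else if (kind == "binary") {
    clin$response <- ifelse(d@y == 1, "effective", "ineffective")
  } else {
    clin$time <- round(d@times, 6)
    clin$event <- as.integer(d@events)
  }
  clinPath <- file.path(dir, "clinical.csv")
  utils::write.csv(clin, clinPath, row.names = FALSE, quote = FALSE)

  cfgPath <- file.path(dir, "config.txt")
  scalar <- vapply(cfg, function(x) length(x) == 1L && !is.matrix(x),
                   logical(1L))
  lines <- c(
    paste0("kind: ", kind),
    vapply(names(cfg)[scalar],
           function(nm) paste0(nm, ": ", format(cfg[[nm]])), character(1L)),
    paste0("gamma: ", paste(format(cfg$gamma), collapse = ",")),
    paste0("links: ", paste(unique(cfg$links), collapse = ","))
  )
  writeLines(lines, cfgPath)
  invisible(c(features = featPath, clinical = clinPath, config = cfgPath))
}

#' Outcome specification matching a fixture kind
#'
#' @param kind fixture kind as in [makeFixture()].
#' @return the [outcomeSpec()] that reads the fixture's outcome columns.
#' @export
fixtureOutcomeSpec <- function(kind = c("tiny", "binary", "survival")) {
  kind <- match.arg(kind)
  switch(kind,
    tiny = outcomeSpec("continuous", valueColumn = "y"),
    binary = outcomeSpec("binary", valueColumn = "response",
                         positiveLabel = "effective"),
    survival = outcomeSpec("survival", timeColumn = "time",
                           eventColumn = "event")
  )
}
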