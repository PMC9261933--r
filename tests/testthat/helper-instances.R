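## Shared helpers: random standardized instances and sign alignment.

randInstance <- function(n, p, m, seed) {
  set.seed(seed)
  list(
    X = stdValues(standardize(matrix(rnorm(n * p), n, p))),
    U = stdValues(standardize(matrix(rnorm(n * m), n, m)))
  )
}

## flip columns of B so each is positively correlated with the matching
## column of A (fits are defined up to per-component sign)
alignSigns <- function(A, B) {
  s <- sign(colSums(A * B))
  s[s == 0] <- 1
  sweep(B, 2L, s, "*")
}

## angle between the spans of two vectors (radians)
vecAngle <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))))
}

## random right-censored survival sample
randSurvival <- function(n, seed) {
  set.seed(seed)
  ev <- rexp(n, rate = 1)
  cn <- rexp(n, rate = 0.5)
  list(times = pmin(ev, cn), events = as.numeric(ev <= cn))
}

## small clinical/feature pair with ids, for data-prep tests
toyTables <- function(seed = 1) {
  set.seed(seed)
  ids <- paste0("s", 1:8)
  features <- matrix(rnorm(8 * 4), 8, 4,
                     dimnames = list(ids, paste0("f", 1:4)))
  clinical <- data.frame(
    subject_id = ids,
    gender = rep(c("F", "M"), 4),
    grade = as.character(rep(c(2, 3, 4, 3), 2)),
    age = round(rnorm(8, 60, 8), 1),
    y = rnorm(8),
    stringsAsFactors = FALSE
  )
  list(features = features, clinical = clinical)
}
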