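## helper: small complete dataset with tables, for pipeline tests
pipelineData <- function(n = 120, K = 12, seed = 1, kind = "continuous") {
  cfgArgs <- list(n = n, p = 2L, K = K, outcomeKind = kind, seed = seed)
  if (kind == "survival") {
    cfgArgs$gamma <- rep(1, 2)
    cfgArgs$theta <- 0.5
    cfgArgs$censorRate <- 0.25
  }
  d <- simulateDataset(do.call(simConfig, cfgArgs))
  clinical <- data.frame(subject_id = rownames(d@X),
                         x1 = d@X[, 1], x2 = d@X[, 2])
  if (kind == "continuous") clinical$y <- d@y
  if (kind == "binary") {
    clinical$resp <- ifelse(d@y == 1, "effective", "ineffective")
  }
  if (kind == "survival") {
    clinical$time <- d@times
    clinical$event <- d@events
  }
  list(d = d, features = d@U, clinical = clinical,
       schema = c(x1 = "numeric", x2 = "numeric"))
}

test_that("latent scores are deterministic, unit variance, and span X", {
  set.seed(2)
  X <- stdValues(standardize(matrix(rnorm(200), 100, 2)))
  U <- stdValues(standardize(matrix(X %*% c(1, 1) + rnorm(100), 100, 1)[, rep(1, 5)] +
                               matrix(rnorm(500, sd = 0.5), 100, 5)))
  z1 <- inferLatentTreatment(U, X)
  z2 <- inferLatentTreatment(U, X)
  expect_identical(z1@zHat, z2@zHat)          # bitwise determinism
  expect_lt(abs(mean(z1@zHat)), 1e-10)
  expect_equal(var(z1@zHat), 1, tolerance = 1e-10)
  ## one-dimensional X: the score is the standardized confounder itself
  x1 <- X[, 1, drop = FALSE]
  zp <- inferLatentTreatment(U, x1)
  expect_equal(abs(cor(zp@zHat, x1[, 1])), 1, tolerance = 1e-12)
})

test_that("strong feature loadings recover the confounder-driven latent", {
  set.seed(4)
  n <- 2000
  X <- matrix(rnorm(n * 3), n, 3)
  xg <- as.numeric(X %*% c(1, 2, -1))
  U <- sapply(runif(20, 0.5, 2), function(a) a * xg + rnorm(n))
  z <- inferLatentTreatment(stdValues(standardize(U)),
                            stdValues(standardize(X)))
  expect_gt(abs(cor(z@zHat, xg)), 0.99)
})

test_that("the outcome regression matches its closed form", {
  set.seed(6)
  z <- rnorm(50)
  expect_equal(fitOutcomeRegression(2 * z, z)$slope, 2, tolerance = 1e-12)
  expect_equal(fitOutcomeRegression(rep(1.3, 50), z)$slope, 0)
  y <- rnorm(50)
  fit <- fitOutcomeRegression(y, z)
  expect_equal(fit$slope, cov(y, z) / var(z), tolerance = 1e-12)
  lmfit <- lm(y ~ z)
  expect_equal(fit$intercept, unname(coef(lmfit)[1]), tolerance = 1e-12)
  expect_equal(fit$residualSD, summary(lmfit)$sigma, tolerance = 1e-12)
  expect_error(fitOutcomeRegression(y[1:2], z[1:2]), "n >= 3")
})

test_that("the estimate is invariant to feature scaling and sign flips", {
  pd <- pipelineData(seed = 21)
  spec <- outcomeSpec("continuous", valueColumn = "y")
  base <- estimateLCE(pd$features, pd$clinical, confounders = pd$schema,
                      outcome = spec, nBoot = 60, seed = 7)
  ## positive rescaling of raw feature columns changes nothing
  scaled <- sweep(pd$features, 2, runif(ncol(pd$features), 0.2, 8), "*")
  est2 <- estimateLCE(scaled, pd$clinical, confounders = pd$schema,
                      outcome = spec, nBoot = 60, seed = 7)
  expect_equal(lce(est2), lce(base), tolerance = 1e-10)
  expect_equal(latentScores(est2), latentScores(base), tolerance = 1e-10)
  ## flipping the sign of every feature flips neither |lce| nor CI width
  est3 <- estimateLCE(-pd$features, pd$clinical, confounders = pd$schema,
                      outcome = spec, nBoot = 60, seed = 7)
  expect_equal(abs(lce(est3)), abs(lce(base)), tolerance = 1e-10)
  ciw <- function(e) diff(as.numeric(confint(e)))
  expect_equal(ciw(est3), ciw(base), tolerance = 1e-10)
})

test_that("bootstrap intervals are seeded and degenerate outcomes collapse to zero", {
  pd <- pipelineData(seed = 31)
  spec <- outcomeSpec("continuous", valueColumn = "y")
  a <- estimateLCE(pd$features, pd$clinical, confounders = pd$schema,
                   outcome = spec, nBoot = 80, seed = 99)
  b <- estimateLCE(pd$features, pd$clinical, confounders = pd$schema,
                   outcome = spec, nBoot = 80, seed = 99)
  expect_identical(confint(a), confint(b))
  expect_identical(bootReplicates(a), bootReplicates(b))
  ## constant outcome: slope and interval are exactly zero
  cl0 <- pd$clinical
  cl0$y <- 5
  e0 <- estimateLCE(pd$features, cl0, confounders = pd$schema,
                    outcome = spec, nBoot = 60, seed = 1)
  expect_equal(lce(e0), 0)
  expect_equal(as.numeric(confint(e0)), c(0, 0))
  ## small bootstrap warns
  expect_warning(estimateLCE(pd$features, pd$clinical, confounders = pd$schema,
                             outcome = spec, nBoot = 20, seed = 1),
                 "nBoot < 50")
})

test_that("the SummarizedExperiment interface agrees with the matrix interface", {
  pd <- pipelineData(n = 80, K = 8, seed = 41)
  spec <- outcomeSpec("continuous", valueColumn = "y")
  se <- RadiomicsSE(pd$features, pd$clinical)
  e1 <- estimateLCE(se, confounders = pd$schema, outcome = spec,
                    nBoot = 60, seed = 3)
  e2 <- estimateLCE(pd$features, pd$clinical, confounders = pd$schema,
                    outcome = spec, nBoot = 60, seed = 3)
  expect_equal(lce(e1), lce(e2))
  expect_equal(confint(e1), confint(e2))
})

test_that("survival outcomes run end to end on martingale residuals", {
  pd <- pipelineData(n = 100, K = 8, seed = 51, kind = "survival")
  spec <- outcomeSpec("survival", timeColumn = "time", eventColumn = "event")
  est <- estimateLCE(pd$features, pd$clinical, confounders = pd$schema,
                     outcome = spec, nBoot = 60, seed = 5)
  expect_equal(est@outcomeKind, "survival")
  expect_true(is.finite(lce(est)))
  ## the point estimate equals the two-stage fit done by hand
  y <- martingaleResiduals(pd$clinical$time, pd$clinical$event)
  Us <- standardize(pd$features)
  Xs <- standardize(as.matrix(pd$clinical[, c("x1", "x2")]))
  z <- inferLatentTreatment(Us, Xs)
  expect_equal(lce(est), fitOutcomeRegression(y, z)$slope, tolerance = 1e-10)
})

test_that("results serialize to JSON and TSV", {
  pd <- pipelineData(n = 60, K = 6, seed = 61)
  est <- estimateLCE(pd$features, pd$clinical, confounders = pd$schema,
                     outcome = outcomeSpec("continuous", valueColumn = "y"),
                     nBoot = 60, seed = 2)
  outDir <- file.path(tempdir(), "lce-out")
  paths <- writeResults(est, outDir)
  js <- jsonlite::read_json(file.path(outDir, "results.json"))
  expect_equal(js$lce, lce(est))
  expect_equal(js$n_used, 60L)
  expect_equal(js$outcome_kind, "continuous")
  sc <- read.delim(file.path(outDir, "scores.tsv"))
  expect_equal(nrow(sc), 60)
  expect_equal(sc$z_hat, unname(latentScores(est)), tolerance = 1e-10)
})

test_that("a permuted outcome yields a null effect on average", {
  pd <- pipelineData(n = 150, K = 10, seed = 71)
  spec <- outcomeSpec("continuous", valueColumn = "y")
  ests <- sapply(1:20, function(i) {
    cl <- pd$clinical
    set.seed(7000 + i)
    cl$y <- sample(cl$y)
    suppressWarnings(
      lce(estimateLCE(pd$features, cl, confounders = pd$schema,
                      outcome = spec, nBoot = 1, seed = i)))
  })
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(length(ests)))
})

test_that("interval width shrinks with sample size on fixed-signal data", {
  widths <- sapply(c(200, 800), function(n) {
    r <- suppressWarnings(
      recoveryExperiment(simConfig(n = n), nReps = 8, nBoot = 100,
                         seed = 321))
    median(r$replicates$ciUpper - r$replicates$ciLower)
  })
  expect_lt(widths[2], widths[1])
})

test_that("PCA baseline matches SVD and least-squares oracles", {
  set.seed(81)
  n <- 20
  U <- stdValues(standardize(matrix(rnorm(n * 5), n, 5)))
  conf <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("c1", "c2")))
  y <- rnorm(n)
  fit <- pcaBaseline(U, conf, y)
  ## PC1 against an eigendecomposition of the covariance (independent
  ## route; the acos metric itself bottoms out near sqrt(machine eps))
  ev <- eigen(cov(U), symmetric = TRUE)$vectors[, 1]
  expect_lt(vecAngle(fit@pc1Loading, ev), 1e-6)
  expect_equal(abs(fit@pc1Scores), abs(as.numeric(U %*% ev)), tolerance = 1e-8)
  ## coefficients and SEs against a direct solve
  mm <- cbind(1, fit@pc1Scores, conf)
  bhat <- solve(crossprod(mm), crossprod(mm, y))
  expect_equal(unname(fit@coefficients), as.numeric(bhat), tolerance = 1e-10)
  resid <- y - mm %*% bhat
  s2 <- sum(resid^2) / (n - ncol(mm))
  ses <- sqrt(diag(s2 * solve(crossprod(mm))))
  expect_equal(unname(fit@standardErrors), unname(ses), tolerance = 1e-10)
  ## rank-1 features: PC1 reproduces the single direction up to sign
  u1 <- matrix(rnorm(n), n, 1)
  Ur1 <- u1 %*% t(c(1, 2, 3))
  fit1 <- pcaBaseline(Ur1, conf, y)
  expect_equal(abs(cor(fit1@pc1Scores, u1[, 1])), 1, tolerance = 1e-10)
  ## rank-deficient design errors
  confBad <- cbind(conf, c1dup = conf[, 1])
  expect_error(pcaBaseline(U, confBad, y), "rank-deficient")
})
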