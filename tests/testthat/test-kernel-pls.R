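test_that("full-component PLS of a matrix on itself is the identity", {
  inst <- randInstance(15, 4, 4, seed = 11)
  fit <- fitKernelPLS(inst$X, inst$X, l = 4)
  expect_lt(max(abs(plsCoefficients(fit) - diag(4))), 1e-8)
})

test_that("single-predictor single-response PLS is the OLS slope", {
  set.seed(3)
  x <- stdValues(standardize(matrix(rnorm(30), ncol = 1)))
  u <- stdValues(standardize(matrix(rnorm(30) + 0.5 * x, ncol = 1)))
  fit <- fitKernelPLS(x, u, l = 1)
  ## both standardized, so the coefficient is the sample correlation
  expect_equal(as.numeric(plsCoefficients(fit)), cor(x, u)[1, 1],
               tolerance = 1e-12)
})

test_that("kernel fit matches the NIPALS reference on a fixed instance", {
  inst <- randInstance(8, 3, 2, seed = 42)
  k <- fitKernelPLS(inst$X, inst$U, l = 2)
  n <- nipalsPLS(inst$X, inst$U, l = 2)
  expect_lt(max(abs(plsWeights(k) - alignSigns(plsWeights(k), plsWeights(n)))), 1e-8)
  expect_lt(max(abs(plsScores(k) - alignSigns(plsScores(k), plsScores(n)))), 1e-8)
  expect_lt(max(abs(uLoadings(k) - alignSigns(uLoadings(k), uLoadings(n)))), 1e-8)
  expect_lt(max(abs(plsCoefficients(k) - plsCoefficients(n))), 1e-8)
  expect_equal(scoreNorms(k), scoreNorms(n), tolerance = 1e-8)
})

test_that("full-rank fits with l = p reproduce least squares", {
  inst <- randInstance(25, 5, 3, seed = 9)
  fit <- fitKernelPLS(inst$X, inst$U, l = 5)
  bols <- qr.solve(inst$X, inst$U)
  expect_lt(max(abs(plsCoefficients(fit) - bols)), 1e-6)
})

test_that("score orthogonality, T = XR, and the crossprod variant hold on random instances", {
  for (seed in 1:20) {
    n <- sample(10:40, 1)
    p <- sample(2:8, 1)
    m <- sample(1:4, 1)
    l <- min(p, sample(1:3, 1))
    inst <- randInstance(n, p, m, seed = 1000 + seed)
    fit <- fitKernelPLS(inst$X, inst$U, l = l)
    TT <- plsScores(fit)
    expect_lt(max(abs(TT - inst$X %*% plsRotations(fit))), 1e-10)
    if (l > 1) {
      G <- crossprod(TT)
      off <- abs(G / outer(sqrt(diag(G)), sqrt(diag(G))))
      diag(off) <- 0
      expect_lt(max(off), 1e-8)
    }
    ## the kernel property: iteration on X'X and X'U alone gives the same fit
    fitC <- fitKernelPLS(inst$X, inst$U, l = l, method = "crossprod")
    expect_lt(max(abs(plsCoefficients(fit) - plsCoefficients(fitC))), 1e-10)
    expect_lt(max(abs(plsScores(fit) - plsScores(fitC))), 1e-10)
  }
})

test_that("dominant eigenvector follows its closed forms and sign convention", {
  expect_equal(as.numeric(dominantEigenvector(diag(c(3, 1)))), c(1, 0))
  ## degenerate top eigenvalue: deterministic output, flagged
  vI <- dominantEigenvector(diag(2))
  expect_true(isTRUE(attr(vI, "degenerate")))
  expect_equal(sqrt(sum(vI^2)), 1, tolerance = 1e-12)
  expect_gt(vI[which.max(abs(vI))], 0)
  ## random symmetric 4x4 vs full eigendecomposition
  set.seed(5)
  A <- crossprod(matrix(rnorm(16), 4))
  v <- dominantEigenvector(A)
  e <- eigen(A, symmetric = TRUE)
  expect_lt(vecAngle(v, e$vectors[, 1]), 1e-10)
  expect_lt(abs(attr(v, "eigenvalue") - e$values[1]), 1e-10)
  expect_error(dominantEigenvector(matrix(1:4, 2)), "symmetric")
})

test_that("score projection is linear and consistent with training scores", {
  inst <- randInstance(12, 4, 2, seed = 21)
  fit <- fitKernelPLS(inst$X, inst$U, l = 2)
  expect_equal(plsScores(fit, inst$X), plsScores(fit),
               tolerance = 1e-12, ignore_attr = TRUE)
  zrow <- matrix(0, 1, 4)
  expect_equal(as.numeric(plsScores(fit, zrow)), c(0, 0))
  expect_equal(plsScores(fit, 2 * inst$X), 2 * plsScores(fit, inst$X),
               tolerance = 1e-12)
  expect_error(plsScores(fit, matrix(0, 1, 3)), "columns")
})

test_that("prediction at full rank equals least-squares fitted values", {
  inst <- randInstance(20, 4, 2, seed = 31)
  fit <- fitKernelPLS(inst$X, inst$U, l = 4)
  fitted <- inst$X %*% qr.solve(inst$X, inst$U)
  expect_lt(max(abs(plsPredict(fit, inst$X) - fitted)), 1e-6)
  expect_equal(as.numeric(plsPredict(fit, matrix(0, 1, 4))), c(0, 0))
  ## first-component sign convention: fitted values positively covary with u
  set.seed(8)
  x1 <- stdValues(standardize(matrix(rnorm(60), 20, 3)))
  u1 <- stdValues(standardize(matrix(rnorm(20) + x1[, 1], ncol = 1)))
  f1 <- fitKernelPLS(x1, u1, l = 1)
  expect_gte(cov(as.numeric(plsPredict(f1, x1)), as.numeric(u1)), 0)
})

test_that("degenerate inputs raise informative errors", {
  inst <- randInstance(10, 3, 2, seed = 51)
  expect_error(fitKernelPLS(inst$X, inst$U, l = 4), "rank")
  expect_error(fitKernelPLS(inst$X, inst$U, l = 0), ">= 1")
  ## response orthogonal to the predictors: no covariance to extract
  Uorth <- qr.resid(qr(inst$X), inst$U)
  expect_error(fitKernelPLS(inst$X, Uorth, l = 1), "no remaining covariance")
  expect_error(fitKernelPLS(inst$X[1:5, ], inst$U, l = 1), "same number of rows")
})

test_that("NIPALS converges in one pass for a univariate response", {
  set.seed(61)
  X <- stdValues(standardize(matrix(rnorm(60), 20, 3)))
  u <- stdValues(standardize(matrix(rnorm(20) + X %*% c(1, -1, 0), ncol = 1)))
  n1 <- nipalsPLS(X, u, l = 2)
  k1 <- fitKernelPLS(X, u, l = 2)
  expect_lt(max(abs(plsCoefficients(n1) - plsCoefficients(k1))), 1e-8)
})

test_that("a PLS fit can be dumped as TSV for inspection", {
  inst <- randInstance(10, 3, 2, seed = 71)
  fit <- fitKernelPLS(inst$X, inst$U, l = 2)
  paths <- dumpPLSModel(fit, file.path(tempdir(), "plsdump"))
  expect_true(all(file.exists(paths)))
  W <- as.matrix(read.delim(paths[1], row.names = 1))
  expect_equal(unname(W), unname(plsWeights(fit)), tolerance = 1e-6)
})
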