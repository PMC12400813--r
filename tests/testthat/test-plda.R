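test_that("pooledCovariance returns class means and the ML pooled estimator", {
  X <- rbind(c(0, 0), c(0, 2), c(4, 0), c(4, 2))
  y <- factor(c("A", "A", "B", "B"))
  pc <- pooledCovariance(X, y)
  expect_equal(unname(pc$means), rbind(c(0, 1), c(4, 1)))
  expect_equal(pc$S, matrix(c(0, 0, 0, 1), 2), ignore_attr = TRUE)

  # all points identical within class -> zero matrix
  X2 <- rbind(c(1, 2), c(1, 2), c(5, 0), c(5, 0))
  expect_equal(pooledCovariance(X2, y)$S, matrix(0, 2, 2),
               ignore_attr = TRUE)

  # duplicated feature column -> rank-deficient S
  set.seed(2)
  X3 <- cbind(rnorm(20), rnorm(20))
  X3 <- cbind(X3, X3[, 1])
  S3 <- pooledCovariance(X3, factor(rep(c("A", "B"), 10)))$S
  ev <- eigen(S3, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev), 1e-12)

  # a class absent from the subset is fatal
  yAbs <- factor(c("A", "A", "A", "A"), levels = c("A", "B"))
  expect_error(pooledCovariance(X, yAbs), "no cells")
})

test_that("shrinkCovariance interpolates to the trace-matched identity", {
  S <- matrix(c(4, 2, 2, 2), 2)
  expect_equal(shrinkCovariance(S, 0), S)
  expect_equal(shrinkCovariance(S, 1), diag(3, 2))
  expect_equal(shrinkCovariance(S, 0.5), matrix(c(3.5, 1, 1, 2.5), 2))
  expect_error(shrinkCovariance(S, 1.5), "\\[0, 1\\]")
  expect_error(shrinkCovariance(matrix(0, 2, 2), 0.5), "degenerate")
})

test_that("trace is conserved by shrinkage for any beta (machine precision)", {
  set.seed(6)
  for (i in 1:25) {
    S <- randomPSD(sample(3:12, 1))
    for (beta in c(0, 0.25, 0.5, 0.99, 1)) {
      expect_equal(sum(diag(shrinkCovariance(S, beta))), sum(diag(S)),
                   tolerance = 1e-13)
    }
  }
})

test_that("tikhonovCovariance adds beta to the diagonal", {
  S <- matrix(c(4, 2, 2, 2), 2)
  expect_equal(tikhonovCovariance(S, 0), S)
  expect_equal(tikhonovCovariance(matrix(0, 2, 2), 1), diag(2))
  expect_equal(tikhonovCovariance(S, 0.5), matrix(c(4.5, 2, 2, 2.5), 2))
  expect_error(tikhonovCovariance(S, -0.1), ">= 0")
})

test_that("fitPLDA computes priors as specified", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  yBal <- factor(rep(c("A", "B"), each = 10))
  expect_equal(fitPLDA(X, yBal)@logPriors, log(c(0.5, 0.5)))

  ySkew <- factor(rep(c("A", "B"), c(18, 2)))
  expect_equal(fitPLDA(X, ySkew)@logPriors, log(c(0.9, 0.1)))
  expect_equal(fitPLDA(X, ySkew, priors = "uniform")@logPriors,
               log(c(0.5, 0.5)))
  # explicit full-reference proportions override the subset's
  expect_equal(fitPLDA(X, yBal,
                       priorWeights = c(A = 0.9, B = 0.1))@logPriors,
               log(c(0.9, 0.1)))
})

test_that("discriminant scores follow the closed form in one dimension", {
  # class means -1 / +1, regularized covariance 1, equal priors
  X <- matrix(c(-2, 0, 0, 2), 4, 1)
  y <- factor(c("A", "A", "B", "B"))
  m <- fitPLDA(X, y, beta = 0)
  expect_equal(unname(m@means[, 1]), c(-1, 1))
  expect_equal(unname(m@sigmaChol[1, 1]), 1)

  sc0 <- discriminantScores(m, matrix(0, 1, 1))
  # decision boundary at the midpoint between the class means
  expect_equal(unname(sc0[1, "A"]), unname(sc0[1, "B"]))

  sc1 <- discriminantScores(m, matrix(1, 1, 1))
  expect_equal(unname(sc1[1, "B"] - sc1[1, "A"]), 2)

  mP <- fitPLDA(X, y, beta = 0, priorWeights = c(A = 0.9, B = 0.1))
  scP <- discriminantScores(mP, matrix(0, 1, 1))
  expect_equal(unname(scP[1, "A"] - scP[1, "B"]), log(9))
})

test_that("beta = 0 reproduces vanilla LDA decisions (MASS oracle)", {
  sim <- simulateGaussian(n = 200, p = 5, K = 3, sep = 2.5, seed = 12)
  m <- fitPLDA(sim$X, sim$labels, beta = 0)
  mine <- m@classLevels[max.col(discriminantScores(m, sim$X),
                                ties.method = "first")]
  oracle <- as.character(
    predict(MASS::lda(sim$X, sim$labels), sim$X)$class)
  expect_identical(mine, oracle)
})

test_that("factorization-based scores equal explicit-inverse brute force", {
  set.seed(14)
  for (i in 1:5) {
    sim <- simulateGaussian(n = 150, p = 20, K = 3, sep = 2, seed = 14 + i)
    m <- fitPLDA(sim$X, sim$labels, beta = 1e-4)
    sc <- discriminantScores(m, sim$X)
    Sreg <- crossprod(m@sigmaChol)
    Sinv <- solve(Sreg)
    brute <- sim$X %*% Sinv %*% t(m@means)
    for (k in 1:3) {
      brute[, k] <- brute[, k] -
        0.5 * drop(m@means[k, ] %*% Sinv %*% m@means[k, ]) +
        m@logPriors[k]
    }
    expect_lt(max(abs(sc - brute)) / max(abs(brute)), 1e-8)
  }
})

test_that("beta = 1 with uniform priors is the nearest-centroid rule", {
  sim <- simulateGaussian(n = 300, p = 10, K = 4, sep = 1.5, seed = 15)
  m <- fitPLDA(sim$X, sim$labels, beta = 1, priors = "uniform")
  mine <- max.col(discriminantScores(m, sim$X), ties.method = "first")
  centroids <- rowsum(sim$X, sim$labels) /
    as.numeric(table(sim$labels))
  d2 <- outer(rowSums(sim$X^2), rep(1, 4)) -
    2 * sim$X %*% t(centroids) +
    outer(rep(1, 300), rowSums(centroids^2))
  expect_identical(mine, max.col(-d2, ties.method = "first"))
})

test_that("score differences are invariant to translating the feature space", {
  sim <- simulateGaussian(n = 100, p = 6, K = 3, sep = 2, seed = 16)
  m <- fitPLDA(sim$X, sim$labels, beta = 1e-3)
  set.seed(17)
  shift <- rnorm(6)
  Xs <- sweep(sim$X, 2L, shift, "+")
  ms <- fitPLDA(Xs, sim$labels, beta = 1e-3)
  d1 <- discriminantScores(m, sim$X)
  d2 <- discriminantScores(ms, Xs)
  expect_equal(d1 - d1[, 1], d2 - d2[, 1], tolerance = 1e-8)
})

test_that("regularization monotonically improves conditioning", {
  set.seed(18)
  for (i in 1:10) {
    S <- randomPSD(8, rank = 6)  # singular sample covariance
    kappas <- vapply(c(0.01, 0.1, 0.3, 0.6, 1), function(b) {
      ev <- eigen(shrinkCovariance(S, b), symmetric = TRUE,
                  only.values = TRUE)$values
      max(ev) / min(ev)
    }, numeric(1))
    expect_true(all(diff(kappas) <= 1e-8))
  }
})

test_that("numerically singular regularized covariance is fatal with guidance", {
  X <- cbind(rep(c(0, 1), 5), rep(c(0, 1), 5))  # perfectly collinear
  y <- factor(rep(c("A", "B"), each = 5))
  expect_error(fitPLDA(X, y, beta = 0), "raise beta")
})
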