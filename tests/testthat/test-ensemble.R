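test_that("proportionalProbs maps scores to the simplex with shift invariance", {
  expect_equal(proportionalProbs(c(5, 5)), c(0.5, 0.5))
  expect_equal(proportionalProbs(c(-3, -3)), c(0.5, 0.5))
  expect_equal(proportionalProbs(c(0, log(3))), c(0.25, 0.75))
  s <- c(1.3, -0.2, 4)
  expect_equal(proportionalProbs(s), proportionalProbs(s + 100))
  m <- proportionalProbs(rbind(s, s))
  expect_equal(unname(rowSums(m)), c(1, 1))
})

test_that("prelimForward returns deterministic simplex rows", {
  set.seed(21)
  net <- initPrelimNet(K = 4)
  sc <- matrix(rnorm(40, sd = 5), 10, 4)
  p <- prelimForward(net, sc)
  expect_equal(rowSums(p), rep(1, 10))
  expect_true(all(p >= 0))
  expect_equal(prelimForward(net, sc), p)
  # identical input rows give identical output rows
  p2 <- prelimForward(net, rbind(sc[1, ], sc[1, ]))
  expect_equal(p2[1, ], p2[2, ])
  expect_error(prelimForward(net, matrix(c(1, NA, 0, 1), 1)), "finite")
})

test_that("aggregateVote is the weighted per-class average", {
  p1 <- rbind(c(0.2, 0.8))
  p2 <- rbind(c(0.6, 0.4))
  eq <- matrix(0.5, 2, 2)
  expect_equal(aggregateVote(list(p1, p2), eq), rbind(c(0.4, 0.6)))

  # degenerate weights reproduce model 1 exactly
  w <- rbind(c(1, 1), c(0, 0))
  expect_equal(aggregateVote(list(p1, p2), w), p1)

  # identical member predictions are a fixed point for any valid weights
  set.seed(22)
  wr <- scSwarmLDA:::softmaxColumns(matrix(rnorm(4), 2, 2))
  expect_equal(aggregateVote(list(p1, p1), wr), p1)

  expect_error(aggregateVote(list(p1, cbind(p2, 0.5)), eq), "shape")
})

test_that("ensembleLoss matches its endpoints and hand arithmetic", {
  set.seed(23)
  n <- 12; K <- 3; M <- 2
  prelim <- lapply(1:M, function(m) {
    x <- matrix(abs(rnorm(n * K)) + 0.05, n, K); x / rowSums(x)
  })
  final <- matrix(abs(rnorm(n * K)) + 0.05, n, K)
  final <- final / rowSums(final)
  y <- sample(1:K, n, replace = TRUE)

  ceFinal <- -mean(log(final[cbind(1:n, y)]))
  cePer <- sapply(prelim, function(p) -mean(log(p[cbind(1:n, y)])))
  expect_equal(ensembleLoss(final, prelim, y, alpha = 1), ceFinal,
               tolerance = 1e-8)
  expect_equal(ensembleLoss(final, prelim, y, alpha = 0), sum(cePer),
               tolerance = 1e-8)
  expect_equal(ensembleLoss(final, prelim, y, alpha = 0.3),
               0.3 * ceFinal + 0.7 * sum(cePer), tolerance = 1e-8)

  # M = 1, uniform 2-class probabilities: loss = ln 2 for every alpha
  u <- matrix(0.5, 4, 2)
  for (a in c(0, 0.4, 1)) {
    expect_equal(ensembleLoss(u, list(u), rep(1, 4), a), log(2))
  }
  expect_error(ensembleLoss(final, prelim, y, alpha = 2), "\\[0, 1\\]")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(24)
  M <- 2; K <- 3; n <- 7
  scoreList <- lapply(1:M, function(m) matrix(rnorm(n * K), n, K))
  nets <- lapply(1:M, function(m) initPrelimNet(K, hidden = 5))
  logits <- matrix(rnorm(M * K, sd = 0.3), M, K)
  yIdx <- sample(1:K, n, replace = TRUE)
  alpha <- 0.6
  rows <- 1:n

  lossAt <- function(nets, logits) {
    ef <- scSwarmLDA:::ensembleForward(nets, logits, FALSE, scoreList, rows)
    ensembleLoss(ef$Q / rowSums(ef$Q), ef$prelim, yIdx, alpha)
  }
  ef <- scSwarmLDA:::ensembleForward(nets, logits, FALSE, scoreList, rows)
  gr <- scSwarmLDA:::ensembleBackward(nets, logits, FALSE, ef, yIdx, alpha)
  h <- 1e-6

  for (m in 1:M) {
    for (nm in c("W1", "b1", "W2", "b2")) {
      theta <- nets[[m]][[nm]]
      picks <- sample(length(theta), min(4, length(theta)))
      for (j in picks) {
        np <- nets
        np[[m]][[nm]][j] <- theta[j] + h
        nm2 <- nets
        nm2[[m]][[nm]][j] <- theta[j] - h
        num <- (lossAt(np, logits) - lossAt(nm2, logits)) / (2 * h)
        expect_equal(gr$nets[[m]][[nm]][j], num, tolerance = 1e-4)
      }
    }
  }
  for (j in seq_along(logits)) {
    lp <- logits; lp[j] <- logits[j] + h
    lm <- logits; lm[j] <- logits[j] - h
    num <- (lossAt(nets, lp) - lossAt(nets, lm)) / (2 * h)
    expect_equal(gr$logits[j], num, tolerance = 1e-4)
  }
})

test_that("voting weights are a per-class softmax over models at all times", {
  set.seed(25)
  logits <- matrix(rnorm(12), 4, 3)
  W <- scSwarmLDA:::votingWeightMatrix(logits, FALSE, 3)
  expect_equal(colSums(W), rep(1, 3))
  expect_true(all(W > 0))
  Ws <- scSwarmLDA:::votingWeightMatrix(logits, TRUE, 3)
  expect_equal(Ws[, 1], Ws[, 2])
  expect_equal(colSums(Ws), rep(1, 3))
})

gaussianTrainFixture <- function(seed, M = 8, n = 300, p = 60, K = 4,
                                 config = ensembleConfig(seed = seed)) {
  sim <- simulateGaussian(n = n, p = p, K = K, sep = 2, seed = seed)
  plan <- drawSwarm(n = n, p = p, M = M, cellFrac = 0.8, masterSeed = seed)
  model <- trainEnsemble(sim$X, sim$labels, plan, config)
  list(sim = sim, plan = plan, model = model)
}

test_that("trainEnsemble learns well-separated Gaussian classes", {
  fx <- gaussianTrainFixture(26)
  pred <- predictCells(fx$model, fx$sim$X)
  acc <- mean(as.character(predictedLabels(pred)) ==
                as.character(fx$sim$labels))
  expect_gte(acc, 0.95)
  expect_equal(unname(rowSums(classProbabilities(pred))), rep(1, 300),
               tolerance = 1e-6)
  # training is reproducible from the config seed
  fx2 <- gaussianTrainFixture(26)
  expect_equal(classProbabilities(predictCells(fx2$model, fx2$sim$X)),
               classProbabilities(pred))
})

test_that("a single-member ensemble at alpha = 1 is that member's network", {
  sim <- simulateGaussian(n = 120, p = 20, K = 3, sep = 2, seed = 27)
  plan <- drawSwarm(n = 120, p = 20, M = 1, cellFrac = 1, masterSeed = 27)
  model <- trainEnsemble(sim$X, sim$labels, plan,
                         ensembleConfig(alpha = 1, seed = 27,
                                        maxEpochs = 30))
  pred <- predictCells(model, sim$X, perModel = TRUE)
  expect_equal(unname(classProbabilities(pred)),
               unname(pred@perModelProbs[[1]]), tolerance = 1e-12)
})

test_that("the shared-voter constraint keeps all class columns equal", {
  fx <- gaussianTrainFixture(28, M = 4, n = 200, p = 40,
                             config = ensembleConfig(seed = 28,
                                                     sharedVoter = TRUE,
                                                     maxEpochs = 30))
  W <- votingWeights(fx$model)
  for (k in 2:ncol(W)) expect_equal(W[, k], W[, 1])
})

test_that("prediction aligns query genes by name and imputes absences as zero", {
  fx <- gaussianTrainFixture(29, M = 6, n = 200, p = 50)
  base <- predictCells(fx$model, fx$sim$X)

  # permuting query gene columns changes nothing
  perm <- sample(ncol(fx$sim$X))
  permPred <- predictCells(fx$model, fx$sim$X[, perm])
  expect_equal(classProbabilities(permPred), classProbabilities(base))

  # dropping 10% of genes degrades gracefully on separable data
  set.seed(29)
  keep <- sort(sample(ncol(fx$sim$X), round(0.9 * ncol(fx$sim$X))))
  dropPred <- predictCells(fx$model, fx$sim$X[, keep])
  acc <- mean(as.character(predictedLabels(dropPred)) ==
                as.character(fx$sim$labels))
  expect_gte(acc, 0.90)

  # fewer than half the ensemble's genes present is fatal
  few <- fx$sim$X[, 1:10]
  expect_error(predictCells(fx$model, few), "50%")
})

test_that("a saved bundle reloads to bit-identical predictions", {
  fx <- gaussianTrainFixture(30, M = 4, n = 150, p = 30)
  d <- tempfile()
  saveEnsembleModel(fx$model, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- loadEnsembleModel(d)
  expect_identical(classProbabilities(predictCells(back, fx$sim$X)),
                   classProbabilities(predictCells(fx$model, fx$sim$X)))
})

test_that("the ensemble is at least as accurate as its average member", {
  fx <- gaussianTrainFixture(31, M = 8, n = 300, p = 60)
  pred <- predictCells(fx$model, fx$sim$X, perModel = TRUE)
  truth <- as.character(fx$sim$labels)
  ensAcc <- mean(as.character(predictedLabels(pred)) == truth)
  memberAcc <- vapply(pred@perModelProbs, function(pm) {
    mean(labelOrder(fx$model)[max.col(pm, ties.method = "first")] == truth)
  }, numeric(1))
  expect_gte(ensAcc, mean(memberAcc))
})
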