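test_that("geneSubsetSize follows the sqrt(p) + 70 rule with clamping", {
  expect_identical(geneSubsetSize(10000), 170L)
  expect_identical(geneSubsetSize(2500), 120L)
  expect_identical(geneSubsetSize(49), 49L)  # raw 77 clamps to p
  expect_identical(geneSubsetSize(1), 1L)
  expect_error(geneSubsetSize(0), "positive")
})

test_that("drawSwarm honours the size contracts and is reproducible", {
  plan <- drawSwarm(n = 10, p = 100, M = 5, cellFrac = 0.8, masterSeed = 3)
  for (s in subsetSpecs(plan)) {
    expect_identical(length(s$cell_idx), 8L)
    expect_identical(anyDuplicated(s$cell_idx), 0L)
    expect_identical(length(s$gene_idx), geneSubsetSize(100))
  }

  # degenerate fraction: every subset holds all cells
  planFull <- drawSwarm(n = 10, p = 100, M = 3, cellFrac = 1, masterSeed = 3)
  for (s in subsetSpecs(planFull)) expect_identical(s$cell_idx, 1:10)

  # identical master seed -> identical plan; different seed -> different
  plan2 <- drawSwarm(n = 10, p = 100, M = 5, cellFrac = 0.8, masterSeed = 3)
  expect_identical(subsetSpecs(plan), subsetSpecs(plan2))
  plan3 <- drawSwarm(n = 10, p = 100, M = 5, cellFrac = 0.8, masterSeed = 4)
  expect_false(identical(subsetSpecs(plan), subsetSpecs(plan3)))

  # the global RNG stream is left untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(drawSwarm(10, 100, M = 2, masterSeed = 5))
  expect_identical(rnorm(1), before)
})

test_that("stratified sampling preserves proportions and covers rare classes", {
  lab <- factor(rep(c("big", "mid", "rare"), c(70, 25, 5)))
  plan <- drawSwarm(n = 100, p = 50, M = 20, cellFrac = 0.6,
                    labels = lab, stratify = TRUE, masterSeed = 7)
  for (s in subsetSpecs(plan)) {
    counts <- table(lab[s$cell_idx])
    expect_identical(length(s$cell_idx), 60L)
    expect_true(all(counts >= 1L))
    # proportions within one cell of the largest-remainder allocation
    expect_equal(as.numeric(counts) / 60, c(0.7, 0.25, 0.05),
                 tolerance = 0.04)
  }
})

test_that("weighted gene sampling follows the supplied weights", {
  w <- c(rep(10, 10), rep(0.01, 90))  # first 10 genes heavily favoured
  plan <- drawSwarm(n = 50, p = 100, M = 50, cellFrac = 0.8,
                    samplingMode = "weighted", geneWeights = w,
                    masterSeed = 21)
  inc <- table(factor(unlist(lapply(subsetSpecs(plan), `[[`, "gene_idx")),
                      levels = 1:100))
  expect_gt(mean(inc[1:10]), mean(inc[11:100]))
  expect_error(drawSwarm(50, 100, M = 2, samplingMode = "weighted",
                         geneWeights = rep(0, 100)),
               "not all zero")
  expect_error(drawSwarm(50, 100, M = 2, samplingMode = "weighted"),
               "requires geneWeights")
})

test_that("meanPairwiseOverlap computes the mean Jaccard ratio", {
  expect_equal(meanPairwiseOverlap(list(1:3, 2:4)), 0.5)
  expect_equal(meanPairwiseOverlap(list(c(1, 5, 9), c(1, 5, 9))), 1)
  expect_equal(meanPairwiseOverlap(list(1:2, 3:4)), 0)
  expect_error(meanPairwiseOverlap(list(1:3)), "at least 2")
  expect_error(meanPairwiseOverlap(list(1:3, integer(0))), "empty")
})

test_that("uniform sampling gives every gene a flat inclusion frequency", {
  plan <- drawSwarm(n = 20, p = 100, M = 2000, cellFrac = 0.8,
                    masterSeed = 17)
  inc <- tabulate(unlist(lapply(subsetSpecs(plan), `[[`, "gene_idx")),
                  nbins = 100)
  gof <- suppressWarnings(chisq.test(inc))
  expect_gt(gof$p.value, 0.01)
})

test_that("distinct subsets: no two gene sets coincide when p >> subset size", {
  plan <- drawSwarm(n = 100, p = 1000, M = 300, cellFrac = 0.8,
                    masterSeed = 31)
  keys <- vapply(subsetSpecs(plan),
                 function(s) paste(s$gene_idx, collapse = ","), character(1))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("a SwarmPlan survives the JSON round trip exactly", {
  plan <- drawSwarm(n = 30, p = 200, M = 4, cellFrac = 0.5, masterSeed = 9)
  f <- tempfile(fileext = ".json")
  writeSwarmPlan(plan, f)
  back <- readSwarmPlan(f)
  expect_identical(subsetSpecs(back), subsetSpecs(plan))
  expect_identical(back@masterSeed, plan@masterSeed)
  expect_identical(back@cellFrac, plan@cellFrac)
})
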