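# Shared fixture builders. Everything is generated in code; no data files.

# Raw-count SingleCellExperiment from a dense cells x genes matrix.
makeSCE <- function(counts, cellIds = NULL, geneNames = NULL) {
  if (is.null(cellIds)) cellIds <- paste0("c", seq_len(nrow(counts)))
  if (is.null(geneNames)) geneNames <- paste0("g", seq_len(ncol(counts)))
  m <- t(counts)
  dimnames(m) <- list(geneNames, cellIds)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = as(m, "CsparseMatrix"))
  )
  S4Vectors::metadata(sce)$layer <- "raw"
  sce
}

# Write a minimal 10x-style MTX directory by hand (genes x cells on disk).
# entries: data.frame(gene, cell, value) of 1-based indices.
writeToyTenx <- function(dir, nGenes, nCells, entries,
                         geneNames = paste0("g", seq_len(nGenes)),
                         barcodes = paste0("c", seq_len(nCells))) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c(
    "%%MatrixMarket matrix coordinate integer general",
    paste(nGenes, nCells, nrow(entries)),
    sprintf("%d %d %g", entries$gene, entries$cell, entries$value)
  )
  writeLines(lines, file.path(dir, "matrix.mtx"))
  writeLines(geneNames, file.path(dir, "features.tsv"))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  dir
}

# Random symmetric positive semidefinite matrix.
randomPSD <- function(p, rank = p) {
  A <- matrix(stats::rnorm(p * rank), p, rank)
  tcrossprod(A) / rank
}

# The standard 4-class fixture of the package's tests: NB counts with
# dropout, defaults as in simConfig (n=800, p=1000, lfc=2).
standardFixture <- function(seed) simulateCounts(simConfig(seed = seed))

# Train/test split + pipeline fit on the standard fixture; returns
# held-out evaluation and per-model accuracies.
fitAndScoreFixture <- function(seed, M = 20, nTrain = 600) {
  sim <- standardFixture(seed)
  n <- ncol(sim$sce)
  idx <- withr::with_seed(seed, sample(n))
  trainIdx <- idx[seq_len(nTrain)]
  testIdx <- idx[(nTrain + 1):n]
  model <- trainPipeline(sim$sce[, trainIdx], sim$labels[trainIdx],
                         minGenesPerCell = 50, M = M,
                         config = ensembleConfig(seed = seed))
  pred <- predictCells(model, sim$sce[, testIdx], perModel = TRUE)
  truth <- sim$labels[testIdx]
  memberAcc <- vapply(pred@perModelProbs, function(pm) {
    mean(model@labelOrder[max.col(pm, ties.method = "first")] ==
           as.character(truth))
  }, numeric(1))
  list(model = model, pred = pred, truth = truth,
       accuracy = evaluateAnnotation(pred, truth)$overallAccuracy,
       memberAcc = memberAcc, sim = sim,
       trainIdx = trainIdx, testIdx = testIdx)
}
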