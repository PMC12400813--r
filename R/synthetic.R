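#' Configuration for the count simulator
#'
#' Defaults describe a moderately sparse, imbalanced 4-type reference:
#' negative-binomial counts with a block of up-regulated marker genes per
#' type and independent dropout zeros.
#'
#' @param nCells,nGenes matrix dimensions; defaults 800 x 1000.
#' @param K number of cell types; default 4.
#' @param classProps length-K simplex of class proportions; default
#'   (0.4, 0.3, 0.2, 0.1) for K = 4, else uniform.
#' @param nMarkersPerClass up-regulated genes per type; default 30.
#' @param logFoldChange natural-log fold change of a marker in its own
#'   class; default 2.
#' @param baseMean negative-binomial mean of a background gene; default 1.
#' @param dispersion negative-binomial size parameter; default 2.
#' @param dropoutRate independent zeroing probability in [0, 1); default
#'   0.3.
#' @param seed RNG seed.
#' @return a validated configuration list.
#' @export
simConfig <- function(nCells = 800, nGenes = 1000, K = 4,
                      classProps = NULL, nMarkersPerClass = 30,
                      logFoldChange = 2, baseMean = 1, dispersion = 2,
                      dropoutRate = 0.3, seed = 1L) {
  if (is.null(classProps)) {
    classProps <- if (K == 4) c(0.4, 0.3, 0.2, 0.1) else rep(1 / K, K)
  }
  if (length(classProps) != K || any(classProps <= 0) ||
      abs(sum(classProps) - 1) > 1e-8) {
    stopf("classProps must be a length-%d positive simplex", K)
  }
  if (nMarkersPerClass * K > nGenes) {
    stopf("markers per class x K exceeds nGenes")
  }
  if (dropoutRate < 0 || dropoutRate >= 1) {
    stopf("dropoutRate must be in [0, 1)")
  }
  if (logFoldChange < 0 || baseMean <= 0 || dispersion <= 0) {
    stopf("logFoldChange must be >= 0; baseMean, dispersion > 0")
  }
  list(nCells = as.integer(nCells), nGenes = as.integer(nGenes),
       K = as.integer(K), classProps = classProps,
       nMarkersPerClass = as.integer(nMarkersPerClass),
       logFoldChange = logFoldChange, baseMean = baseMean,
       dispersion = dispersion, dropoutRate = dropoutRate,
       seed = as.integer(seed))
}

#' Simulate labelled scRNA-seq-like counts
#'
#' Draws a cells x genes count matrix: gene g in a cell of class k is
#' negative binomial with mean \code{baseMean * exp(logFoldChange)} if g is
#' one of class k's markers and \code{baseMean} otherwise, with the
#' configured dispersion; entries are then independently zeroed with
#' probability \code{dropoutRate}. Class sizes follow \code{classProps}
#' deterministically (largest-remainder rounding). Markers are disjoint
#' leading gene blocks, returned as the ground truth. Bit-identical output
#' for identical seeds.
#'
#' @param cfg a configuration list from [simConfig()].
#' @return list with \code{sce} (raw-count \code{SingleCellExperiment} with
#'   a \code{cellType} column), \code{labels} (named factor) and
#'   \code{markers} (named list of per-class marker gene names).
#' @export
simulateCounts <- function(cfg) {
  K <- cfg$K
  classes <- paste0("type", seq_len(K))
  nPer <- floor(cfg$classProps * cfg$nCells)
  rem <- cfg$nCells - sum(nPer)
  if (rem > 0) {
    frac <- cfg$classProps * cfg$nCells - nPer
    add <- order(-frac)[seq_len(rem)]
    nPer[add] <- nPer[add] + 1L
  }
  labels <- factor(rep(classes, nPer), levels = classes)
  geneNames <- sprintf("gene%04d", seq_len(cfg$nGenes))
  markers <- lapply(seq_len(K), function(k) {
    geneNames[((k - 1L) * cfg$nMarkersPerClass + 1L):
              (k * cfg$nMarkersPerClass)]
  })
  names(markers) <- classes
  counts <- withSeed(cfg$seed, {
    m <- matrix(0L, cfg$nCells, cfg$nGenes)
    for (k in seq_len(K)) {
      rows <- which(labels == classes[k])
      mu <- rep(cfg$baseMean, cfg$nGenes)
      mu[geneNames %in% markers[[k]]] <-
        cfg$baseMean * exp(cfg$logFoldChange)
      m[rows, ] <- stats::rnbinom(length(rows) * cfg$nGenes,
                                  size = cfg$dispersion,
                                  mu = rep(mu, each = length(rows)))
    }
    if (cfg$dropoutRate > 0) {
      keep <- stats::rbinom(length(m), 1L, 1 - cfg$dropoutRate)
      m <- m * keep
    }
    m
  })
  cellIds <- sprintf("cell%04d", seq_len(cfg$nCells))
  dimnames(counts) <- list(cellIds, geneNames)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = as(t(counts), "CsparseMatrix")),
    colData = S4Vectors::DataFrame(cellType = labels, row.names = cellIds)
  )
  S4Vectors::metadata(sce)$layer <- "raw"
  names(labels) <- cellIds
  list(sce = sce, labels = labels, markers = markers)
}

#' Simulate Gaussian data matching the LDA model exactly
#'
#' Draws continuous data from the shared-covariance Gaussian model that LDA
#' assumes: class k is \code{N(mu_k, Sigma)} with \code{Sigma = sigma^2 I}
#' and mean vectors separated by \code{sep} in disjoint coordinate blocks.
#' Used for oracle-equivalence tests where the generative model must match
#' the classifier's assumptions.
#'
#' @param n cells, \code{p} genes, \code{K} classes.
#' @param p,K see above.
#' @param sep mean shift of a class's block; default 3.
#' @param sigma within-class standard deviation; default 1.
#' @param blockSize coordinates shifted per class; default
#'   \code{floor(p / K)}.
#' @param classProps class proportions; default uniform.
#' @param seed RNG seed.
#' @return list with \code{X} (cells x genes matrix) and \code{labels}
#'   (factor).
#' @export
simulateGaussian <- function(n, p, K, sep = 3, sigma = 1,
                             blockSize = NULL, classProps = NULL,
                             seed = 1L) {
  if (is.null(blockSize)) blockSize <- max(1L, floor(p / K))
  if (is.null(classProps)) classProps <- rep(1 / K, K)
  nPer <- floor(classProps * n)
  nPer[1L] <- nPer[1L] + (n - sum(nPer))
  classes <- paste0("type", seq_len(K))
  labels <- factor(rep(classes, nPer), levels = classes)
  mu <- matrix(0, K, p)
  for (k in seq_len(K)) {
    cols <- ((k - 1L) * blockSize + 1L):min(k * blockSize, p)
    mu[k, cols] <- sep
  }
  X <- withSeed(seed, {
    mu[as.integer(labels), , drop = FALSE] +
      matrix(stats::rnorm(n * p, sd = sigma), n, p)
  })
  colnames(X) <- sprintf("gene%04d", seq_len(p))
  rownames(X) <- sprintf("cell%04d", seq_len(n))
  names(labels) <- rownames(X)
  list(X = X, labels = labels, means = mu)
}
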