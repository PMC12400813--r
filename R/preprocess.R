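#' Quality-control filtering of cells and genes
#'
#' Removes low-quality cells (fewer than \code{minGenesPerCell} detected
#' genes), rarely detected genes (fewer than \code{minCellsPerGene} cells
#' with a nonzero count), and then any gene with zero variance across the
#' surviving cells. Row/column order of survivors is preserved.
#'
#' @param sce a raw-count \code{SingleCellExperiment}.
#' @param minGenesPerCell minimum number of detected (nonzero) genes per
#'   cell; default 200.
#' @param minCellsPerGene minimum number of cells a gene must be detected in;
#'   default 3.
#' @return the filtered \code{SingleCellExperiment}.
#' @export
qcFilter <- function(sce, minGenesPerCell = 200, minCellsPerGene = 3) {
  stopifnot(identical(S4Vectors::metadata(sce)$layer, "raw"))
  m <- SummarizedExperiment::assay(sce, "counts")
  detectedPerCell <- Matrix::colSums(m > 0)
  keepCells <- detectedPerCell >= minGenesPerCell
  if (!any(keepCells)) {
    stopf("QC removed all cells (minGenesPerCell = %d); largest cell detects %d genes",
          minGenesPerCell, max(detectedPerCell))
  }
  m <- m[, keepCells, drop = FALSE]
  keepGenes <- Matrix::rowSums(m > 0) >= minCellsPerGene
  m2 <- m[keepGenes, , drop = FALSE]
  # zero-variance removal on the survivors (covers constant nonzero genes)
  n <- ncol(m2)
  rs <- Matrix::rowSums(m2)
  rs2 <- Matrix::rowSums(m2^2)
  v <- rs2 / n - (rs / n)^2
  keepVar <- v > 0
  keep <- which(keepGenes)[keepVar]
  if (!length(keep)) stopf("QC removed all genes")
  out <- sce[keep, keepCells]
  S4Vectors::metadata(out)$layer <- "raw"
  out
}

#' Library-size log-normalization
#'
#' Per cell, each count becomes \code{log(1 + count / cellTotal *
#' scaleFactor)} (natural log; counts-per-10,000 by default). Adds a
#' \code{"logcounts"} assay and sets \code{metadata(x)$layer} to
#' \code{"lognorm"}. Zeros map to zeros, and the output is invariant to
#' rescaling any cell's counts by a positive factor.
#'
#' @param sce a raw-count \code{SingleCellExperiment}; every cell must have a
#'   positive total count.
#' @param scaleFactor target per-cell total before \code{log1p}; default
#'   10000.
#' @return \code{sce} with a \code{"logcounts"} assay added.
#' @export
logNormalize <- function(sce, scaleFactor = 10000) {
  stopifnot(identical(S4Vectors::metadata(sce)$layer, "raw"))
  m <- SummarizedExperiment::assay(sce, "counts")
  totals <- Matrix::colSums(m)
  if (any(totals <= 0)) {
    stopf("cell '%s' has zero total count; run qcFilter first",
          colnames(sce)[which(totals <= 0)[1L]])
  }
  if (methods::is(m, "CsparseMatrix")) {
    ln <- m
    percell <- rep.int(totals, diff(ln@p))
    ln@x <- log1p(ln@x / percell * scaleFactor)
  } else {
    ln <- log1p(sweep(as.matrix(m), 2L, totals, "/") * scaleFactor)
  }
  SummarizedExperiment::assay(sce, "logcounts") <- ln
  S4Vectors::metadata(sce)$layer <- "lognorm"
  S4Vectors::metadata(sce)$scaleFactor <- scaleFactor
  sce
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of a location difference between two samples. Small
#' tie-free samples are tested exactly; otherwise the normal approximation
#' with midranks, tie-corrected variance and continuity correction is used
#' (the same policy as \code{stats::wilcox.test}).
#'
#' @param x,y numeric vectors, each nonempty.
#' @return list with \code{statistic} (the Mann-Whitney U for \code{x}) and
#'   \code{pvalue}.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be nonempty")
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), pvalue = min(1, ht$p.value))
}

# Vectorized one-vs-rest Wilcoxon over the columns of a cells x genes matrix,
# for all K classes at once. Midranks are computed once per gene and shared
# across the K contrasts; p-values use the normal approximation with
# tie-corrected variance and continuity correction (the large-sample policy
# of stats::wilcox.test, cross-checked in the test suite). Returns K x p
# matrices W (Mann-Whitney U of class vs rest) and pvalue.
rankSumOneVsRest <- function(X, classes) {
  classes <- droplevels(as.factor(classes))
  n <- nrow(X)
  p <- ncol(X)
  K <- nlevels(classes)
  ranks <- matrix(0, n, p)
  tieTerm <- numeric(p)
  for (j in seq_len(p)) {
    r <- rank(X[, j])
    ranks[, j] <- r
    tie <- tabulate(match(r, unique(r)))
    tieTerm[j] <- sum(tie^3 - tie)
  }
  ind <- stats::model.matrix(~ classes - 1)  # n x K membership
  rankSums <- crossprod(ind, ranks)          # K x p
  n1 <- as.numeric(table(classes))
  W <- rankSums - n1 * (n1 + 1) / 2
  pv <- matrix(1, K, p)
  for (k in seq_len(K)) {
    n2 <- n - n1[k]
    sigma2 <- (n1[k] * n2 / 12) * ((n + 1) - tieTerm / (n * (n - 1)))
    z <- W[k, ] - n1[k] * n2 / 2
    zc <- abs(z) - 0.5  # continuity correction
    zc[zc < 0] <- 0
    ok <- sigma2 > 0
    pv[k, ok] <- pmin(1, 2 * stats::pnorm(-zc[ok] / sqrt(sigma2[ok])))
  }
  dimnames(W) <- dimnames(pv) <- list(levels(classes), colnames(X))
  list(W = W, pvalue = pv)
}
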