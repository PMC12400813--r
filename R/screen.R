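#' Wilcoxon marker-gene screening
#'
#' For each cell type, tests every gene for differential expression between
#' that type and all other cells (two-sided Wilcoxon rank-sum on the
#' log-normalized values), keeps the \code{topN} genes with the smallest
#' p-values per type, and returns their union in original gene order. Ties in
#' p-value are broken by the larger deviation of the rank-sum statistic from
#' its null expectation, then by gene index, so the selection is
#' deterministic. Raw (unadjusted) p-values are ranked and retained for
#' downstream weighted gene sampling.
#'
#' @param sce a log-normalized \code{SingleCellExperiment} (see
#'   [logNormalize()]).
#' @param labels factor of cell types aligned to \code{colnames(sce)}; every
#'   class needs at least 2 cells (20-30 cells per type are recommended for
#'   stable screening).
#' @param topN per-class list size; default 400.
#' @return a [GeneScreenResult-class].
#' @export
screenMarkerGenes <- function(sce, labels, topN = 400) {
  stopifnot(identical(S4Vectors::metadata(sce)$layer, "lognorm"))
  labels <- droplevels(as.factor(labels))
  if (length(labels) != ncol(sce)) {
    stopf("labels length (%d) must match number of cells (%d)",
          length(labels), ncol(sce))
  }
  if (nlevels(labels) < 2L) stopf("need at least 2 cell types")
  counts <- table(labels)
  if (any(counts < 2L)) {
    stopf(paste0("cell type '%s' has %d cell(s); at least 2 are required ",
                 "and 20-30 cells per type are recommended for reliable ",
                 "gene selection"),
          names(counts)[which.min(counts)], min(counts))
  }
  X <- t(as.matrix(SummarizedExperiment::assay(sce, "logcounts")))
  rs <- rankSumOneVsRest(X, labels)
  p <- ncol(X)
  K <- nlevels(labels)
  n <- nrow(X)
  n1 <- as.numeric(counts)
  topNeff <- min(as.integer(topN), p)
  perClassTop <- vector("list", K)
  names(perClassTop) <- levels(labels)
  for (k in seq_len(K)) {
    # deviation of U from its null mean n1*n2/2, larger = more extreme
    dev <- abs(rs$W[k, ] - n1[k] * (n - n1[k]) / 2)
    ord <- order(rs$pvalue[k, ], -dev, seq_len(p))
    perClassTop[[k]] <- colnames(X)[ord[seq_len(topNeff)]]
  }
  selected <- colnames(X)[sort(unique(match(unlist(perClassTop),
                                            colnames(X))))]
  methods::new("GeneScreenResult",
    pvalues = rs$pvalue,
    statistics = rs$W,
    perClassTop = perClassTop,
    selectedGenes = selected,
    topN = topNeff
  )
}

#' Serialize a screening result to TSV
#'
#' Writes one row per (gene, class) with the p-value, rank-sum statistic and
#' whether the gene is in that class's top list.
#'
#' @param screen a [GeneScreenResult-class].
#' @param path output path.
#' @return the output path, invisibly.
#' @export
writeScreenTSV <- function(screen, path) {
  pv <- screen@pvalues
  dt <- data.table::data.table(
    gene = rep(colnames(pv), each = nrow(pv)),
    class = rep(rownames(pv), times = ncol(pv)),
    p_value = as.vector(pv),
    statistic = as.vector(screen@statistics)
  )
  dt$selected <- mapply(function(g, cl) g %in% screen@perClassTop[[cl]],
                        dt$gene, dt$class)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Per-gene screening weights for weighted subsampling
#'
#' Turns the screening p-values into nonnegative per-gene weights
#' (\code{-log10} of the minimum p-value across classes, floored at a small
#' constant), a convenient hook for importance-weighted gene sampling in
#' [drawSwarm()].
#'
#' @param screen a [GeneScreenResult-class].
#' @param genes character vector of genes to produce weights for (e.g. the
#'   selected union); defaults to all screened genes.
#' @return named numeric vector of weights.
#' @export
screenGeneWeights <- function(screen, genes = selectedGenes(screen)) {
  pmin <- apply(screen@pvalues[, genes, drop = FALSE], 2L, min)
  w <- -log10(pmax(pmin, 1e-300))
  pmax(w, 1e-3)
}
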