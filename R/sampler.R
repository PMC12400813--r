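#' Gene subset size rule
#'
#' Number of genes each swarm member sees: \code{floor(sqrt(p)) + 70},
#' clamped at \code{p}. The square-root term keeps per-model dimensionality
#' far below the cell count while the additive constant guarantees enough
#' genes on small panels.
#'
#' @param p total number of (screened) genes, at least 1.
#' @return integer subset size.
#' @examples
#' geneSubsetSize(10000)  # 170
#' @export
geneSubsetSize <- function(p) {
  p <- as.integer(p)
  if (is.na(p) || p < 1L) stopf("p must be a positive integer")
  min(as.integer(floor(sqrt(p))) + 70L, p)
}

#' Draw the swarm's random data subsets
#'
#' Generates \code{M} independent subsets, each containing
#' \code{round(cellFrac * n)} cells and \code{geneSubsetSize(p)} genes, both
#' sampled without replacement. In uniform mode every cell and gene has equal
#' inclusion probability; in weighted mode genes are sampled with
#' probabilities proportional to \code{geneWeights} (a hook for
#' importance-based samplers, see [screenGeneWeights()]). With
#' \code{stratify = TRUE} cell sampling preserves each class's proportion
#' (largest-remainder allocation) and guarantees at least one cell per class
#' per subset. The whole plan is reproducible from \code{masterSeed}; each
#' subset records its own derived seed.
#'
#' @param n,p number of cells / genes to index.
#' @param M number of subsets; default 300.
#' @param cellFrac fraction of cells per subset in (0, 1]; default 0.8.
#' @param samplingMode \code{"uniform"} (default) or \code{"weighted"}.
#' @param geneWeights length-p nonnegative weights, required in weighted
#'   mode.
#' @param labels optional factor of cell types (required when
#'   \code{stratify = TRUE}).
#' @param stratify preserve class proportions in cell sampling; default
#'   FALSE.
#' @param masterSeed integer seed.
#' @return a [SwarmPlan-class].
#' @export
drawSwarm <- function(n, p, M = 300, cellFrac = 0.8,
                      samplingMode = c("uniform", "weighted"),
                      geneWeights = NULL, labels = NULL, stratify = FALSE,
                      masterSeed = 1L) {
  samplingMode <- match.arg(samplingMode)
  n <- as.integer(n); p <- as.integer(p); M <- as.integer(M)
  if (M < 1L) stopf("M must be >= 1")
  if (cellFrac <= 0 || cellFrac > 1) stopf("cellFrac must be in (0, 1]")
  if (samplingMode == "weighted") {
    if (is.null(geneWeights) || length(geneWeights) != p) {
      stopf("weighted mode requires geneWeights of length p = %d", p)
    }
    if (any(geneWeights < 0) || all(geneWeights == 0)) {
      stopf("geneWeights must be nonnegative and not all zero")
    }
  }
  if (stratify && is.null(labels)) {
    stopf("stratify = TRUE requires labels")
  }
  if (!is.null(labels)) {
    labels <- droplevels(as.factor(labels))
    if (length(labels) != n) stopf("labels length must equal n")
  }
  nCellsSub <- max(1L, as.integer(round(cellFrac * n)))
  nGenesSub <- geneSubsetSize(p)
  if (stratify && nCellsSub < nlevels(labels)) {
    stopf("subset size %d cannot cover all %d classes; raise cellFrac",
          nCellsSub, nlevels(labels))
  }
  subsets <- vector("list", M)
  for (m in seq_len(M)) {
    seed <- deriveSeed(masterSeed, m)
    subsets[[m]] <- withSeed(seed, {
      cellIdx <- if (stratify) {
        sampleStratified(labels, nCellsSub)
      } else if (nCellsSub == n) seq_len(n) else sample.int(n, nCellsSub)
      geneIdx <- if (nGenesSub == p) seq_len(p)
        else if (samplingMode == "weighted") {
          sample.int(p, nGenesSub, prob = geneWeights)
        } else sample.int(p, nGenesSub)
      list(cell_idx = sort(as.integer(cellIdx)),
           gene_idx = sort(as.integer(geneIdx)),
           seed = seed)
    })
  }
  methods::new("SwarmPlan",
    subsets = subsets, n = n, p = p, M = M, cellFrac = cellFrac,
    samplingMode = samplingMode, stratify = isTRUE(stratify),
    geneWeights = if (samplingMode == "weighted") as.numeric(geneWeights)
      else numeric(0),
    masterSeed = as.integer(masterSeed)
  )
}

# Proportional (largest remainder) allocation of `size` cells across the
# classes of `labels`, at least 1 per class, then uniform sampling within
# each class.
sampleStratified <- function(labels, size) {
  counts <- table(labels)
  K <- length(counts)
  exact <- as.numeric(counts) / sum(counts) * size
  base <- pmax(1L, floor(exact))
  base <- pmin(base, as.integer(counts))
  rem <- size - sum(base)
  if (rem > 0) {
    frac <- exact - floor(exact)
    room <- as.integer(counts) - base
    ord <- order(-frac)
    for (k in ord) {
      if (rem == 0) break
      add <- min(room[k], rem)
      if (add > 0) { base[k] <- base[k] + add; rem <- rem - add }
    }
  } else if (rem < 0) {
    ord <- order(base, decreasing = TRUE)
    for (k in ord) {
      if (rem == 0) break
      take <- min(base[k] - 1L, -rem)
      if (take > 0) { base[k] <- base[k] - take; rem <- rem + take }
    }
  }
  if (any(base < 1L)) {
    stopf("stratified sampling left class '%s' empty",
          names(counts)[which.min(base)])
  }
  idx <- integer(0)
  for (k in seq_len(K)) {
    inK <- which(labels == names(counts)[k])
    idx <- c(idx, if (base[k] == length(inK)) inK
             else inK[sample.int(length(inK), base[k])])
  }
  idx
}

#' Mean pairwise Jaccard overlap of index sets
#'
#' Mean over all unordered pairs of \code{|A intersect B| / |A union B|}.
#' Used to quantify the diversity induced by subsampling: for uniform
#' sampling of a fraction f of items without replacement the expectation is
#' approximately \code{f / (2 - f)} (2/3 at f = 0.8).
#'
#' @param indexSets list of at least two nonempty integer vectors.
#' @return mean Jaccard ratio in [0, 1].
#' @examples
#' meanPairwiseOverlap(list(1:3, 2:4))  # 0.5
#' @export
meanPairwiseOverlap <- function(indexSets) {
  if (length(indexSets) < 2L) stopf("need at least 2 index sets")
  sizes <- lengths(indexSets)
  if (any(sizes == 0L)) stopf("empty index set at position %d",
                              which(sizes == 0L)[1L])
  u <- max(vapply(indexSets, max, numeric(1)))
  S <- length(indexSets)
  inc <- matrix(0, u, S)
  for (s in seq_len(S)) inc[indexSets[[s]], s] <- 1
  inter <- crossprod(inc)               # S x S intersection sizes
  uni <- outer(sizes, sizes, "+") - inter
  jac <- inter / uni
  mean(jac[upper.tri(jac)])
}

#' Serialize / restore a SwarmPlan as JSON
#'
#' The JSON file stores all indices and seeds, so a plan can be re-used for
#' an exact rerun.
#'
#' @param plan a [SwarmPlan-class].
#' @param path output (input) path.
#' @return \code{writeSwarmPlan}: the path, invisibly; \code{readSwarmPlan}:
#'   the restored [SwarmPlan-class].
#' @export
writeSwarmPlan <- function(plan, path) {
  obj <- list(
    n = plan@n, p = plan@p, M = plan@M, cell_frac = plan@cellFrac,
    sampling_mode = plan@samplingMode, stratify = plan@stratify,
    gene_weights = plan@geneWeights, master_seed = plan@masterSeed,
    subsets = plan@subsets
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSwarmPlan
#' @export
readSwarmPlan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  subsets <- lapply(seq_len(obj$M), function(m) {
    s <- if (is.data.frame(obj$subsets)) {
      list(cell_idx = obj$subsets$cell_idx[[m]],
           gene_idx = obj$subsets$gene_idx[[m]],
           seed = obj$subsets$seed[[m]])
    } else obj$subsets[[m]]
    list(cell_idx = as.integer(s$cell_idx),
         gene_idx = as.integer(s$gene_idx),
         seed = as.integer(s$seed))
  })
  methods::new("SwarmPlan",
    subsets = subsets, n = as.integer(obj$n), p = as.integer(obj$p),
    M = as.integer(obj$M), cellFrac = as.numeric(obj$cell_frac),
    samplingMode = obj$sampling_mode, stratify = isTRUE(obj$stratify),
    geneWeights = as.numeric(obj$gene_weights %||% numeric(0)),
    masterSeed = as.integer(obj$master_seed)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
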