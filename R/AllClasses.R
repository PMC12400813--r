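#' @import methods
NULL

#' Marker-gene screening result
#'
#' Holds the per-class one-vs-rest Wilcoxon rank-sum p-values for every gene,
#' the per-class top gene lists, and their union (in original gene order).
#' Produced by [screenMarkerGenes()].
#'
#' @slot pvalues K x p numeric matrix of two-sided p-values; rows are cell
#'   types, columns are genes.
#' @slot statistics K x p numeric matrix of rank-sum statistics (W, the
#'   Mann-Whitney U for the class relative to the rest).
#' @slot perClassTop named list of K character vectors: the top genes per
#'   class, best first.
#' @slot selectedGenes character vector: union of the per-class top lists,
#'   ordered as in the input matrix, no duplicates.
#' @slot topN integer, the per-class list size requested.
#'
#' @exportClass GeneScreenResult
setClass("GeneScreenResult",
  representation(
    pvalues = "matrix",
    statistics = "matrix",
    perClassTop = "list",
    selectedGenes = "character",
    topN = "integer"
  )
)

setValidity("GeneScreenResult", function(object) {
  p <- object@pvalues
  msg <- character()
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    msg <- c(msg, "p-values must be finite and in [0, 1]")
  }
  if (!identical(dim(object@statistics), dim(p))) {
    msg <- c(msg, "statistics and pvalues must have identical dimensions")
  }
  if (length(object@perClassTop) != nrow(p)) {
    msg <- c(msg, "perClassTop must have one entry per class (row of pvalues)")
  }
  if (anyDuplicated(object@selectedGenes)) {
    msg <- c(msg, "selectedGenes must not contain duplicates")
  }
  if (!all(object@selectedGenes %in% colnames(p))) {
    msg <- c(msg, "selectedGenes must be a subset of the screened genes")
  }
  if (length(msg)) msg else TRUE
})

#' Swarm subsampling plan
#'
#' The full description of the M random data subsets used to train the swarm:
#' for each subset, the sampled cell indices, gene indices (into the screened
#' gene list) and the RNG seed it was drawn with. Reproducible from
#' \code{masterSeed}. Produced by [drawSwarm()].
#'
#' @slot subsets list of M lists, each with integer fields \code{cell_idx}
#'   (sorted, unique), \code{gene_idx} (sorted, unique) and \code{seed}.
#' @slot n,p integer: number of cells / genes the plan indexes into.
#' @slot M integer, number of subsets.
#' @slot cellFrac fraction of cells per subset, in (0, 1].
#' @slot samplingMode "uniform" or "weighted".
#' @slot stratify logical; if TRUE cell sampling preserved class proportions.
#' @slot geneWeights numeric weights used in weighted mode (length 0 otherwise).
#' @slot masterSeed integer seed the plan was generated from.
#'
#' @exportClass SwarmPlan
setClass("SwarmPlan",
  representation(
    subsets = "list",
    n = "integer",
    p = "integer",
    M = "integer",
    cellFrac = "numeric",
    samplingMode = "character",
    stratify = "logical",
    geneWeights = "numeric",
    masterSeed = "integer"
  )
)

setValidity("SwarmPlan", function(object) {
  msg <- character()
  if (object@M < 1L) msg <- c(msg, "M must be >= 1")
  if (length(object@subsets) != object@M) {
    msg <- c(msg, "number of subsets must equal M")
  }
  if (object@cellFrac <= 0 || object@cellFrac > 1) {
    msg <- c(msg, "cellFrac must be in (0, 1]")
  }
  for (s in object@subsets) {
    ci <- s$cell_idx; gi <- s$gene_idx
    if (anyDuplicated(ci) || is.unsorted(ci) ||
        any(ci < 1L) || any(ci > object@n)) {
      msg <- c(msg, "cell indices must be sorted, unique and in 1..n")
      break
    }
    if (anyDuplicated(gi) || is.unsorted(gi) ||
        any(gi < 1L) || any(gi > object@p)) {
      msg <- c(msg, "gene indices must be sorted, unique and in 1..p")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Fitted penalized LDA model for one swarm subset
#'
#' A closed-form shared-covariance Gaussian classifier with a regularized
#' covariance estimate. Scoring uses a Cholesky factorization of the
#' regularized covariance rather than an explicit inverse. Produced by
#' [fitPLDA()].
#'
#' @slot means K x p_s matrix of class mean vectors on the subset's genes.
#' @slot sigmaChol upper-triangular Cholesky factor R of the regularized
#'   covariance (so that t(R) %*% R reproduces it).
#' @slot coefs p_s x K matrix of discriminant coefficients, the solve of the
#'   regularized covariance against the class means.
#' @slot consts length-K vector of per-class constants
#'   (-1/2 mu_k' Sigma^-1 mu_k + log pi_k).
#' @slot logPriors length-K vector of log class priors.
#' @slot beta regularization weight.
#' @slot penaltyKind "trace_shrinkage" (convex combination with the
#'   trace-matched scaled identity) or "tikhonov" (add beta * I).
#' @slot geneNames character vector naming the subset's p_s genes.
#' @slot classLevels character vector, the K class labels in order.
#'
#' @exportClass PLDAModel
setClass("PLDAModel",
  representation(
    means = "matrix",
    sigmaChol = "matrix",
    coefs = "matrix",
    consts = "numeric",
    logPriors = "numeric",
    beta = "numeric",
    penaltyKind = "character",
    geneNames = "character",
    classLevels = "character"
  )
)

setValidity("PLDAModel", function(object) {
  msg <- character()
  K <- nrow(object@means)
  ps <- ncol(object@means)
  if (K < 2L) msg <- c(msg, "need at least 2 classes")
  if (length(object@classLevels) != K) {
    msg <- c(msg, "classLevels length must match number of mean rows")
  }
  if (length(object@geneNames) != ps) {
    msg <- c(msg, "geneNames length must match number of mean columns")
  }
  if (length(object@logPriors) != K) {
    msg <- c(msg, "logPriors must have length K")
  }
  if (abs(sum(exp(object@logPriors)) - 1) > 1e-8) {
    msg <- c(msg, "exp(logPriors) must sum to 1")
  }
  if (!identical(dim(object@sigmaChol), c(ps, ps))) {
    msg <- c(msg, "sigmaChol must be p_s x p_s")
  }
  if (length(msg)) msg else TRUE
})

#' Trained swarm ensemble
#'
#' The complete trained annotator: M fitted [PLDAModel-class] members, M
#' per-model prediction networks mapping the K discriminant scores to class
#' probabilities, the per-(model, class) voting-weight logits, and the
#' training configuration. Produced by [trainEnsemble()] or [trainPipeline()].
#'
#' @slot pldaModels list of M [PLDAModel-class] objects.
#' @slot prelimNets list of M network parameter lists (input standardization,
#'   one hidden ReLU layer, softmax output).
#' @slot votingLogits M x K matrix of voting logits; the voting weights are
#'   their per-column softmax over models. In shared-voter mode all columns
#'   are constrained equal.
#' @slot labelOrder character vector of the K cell types, fixed ordering.
#' @slot alpha loss mixing weight in [0, 1].
#' @slot sharedVoter logical, whether a single voter is shared by all classes.
#' @slot config list: training configuration (optimizer settings, seed,
#'   scale factor, screened genes, QC thresholds ...).
#' @slot history data.frame of per-epoch training/validation loss.
#'
#' @exportClass EnsembleModel
setClass("EnsembleModel",
  representation(
    pldaModels = "list",
    prelimNets = "list",
    votingLogits = "matrix",
    labelOrder = "character",
    alpha = "numeric",
    sharedVoter = "logical",
    config = "list",
    history = "data.frame"
  )
)

setValidity("EnsembleModel", function(object) {
  msg <- character()
  M <- length(object@pldaModels)
  K <- length(object@labelOrder)
  if (M < 1L) msg <- c(msg, "need at least one swarm member")
  if (length(object@prelimNets) != M) {
    msg <- c(msg, "one prediction network per pLDA model is required")
  }
  if (!identical(dim(object@votingLogits), c(M, as.integer(K)))) {
    msg <- c(msg, "votingLogits must be M x K")
  }
  if (object@alpha < 0 || object@alpha > 1) {
    msg <- c(msg, "alpha must be in [0, 1]")
  }
  for (mod in object@pldaModels) {
    if (!identical(mod@classLevels, object@labelOrder)) {
      msg <- c(msg, "all members must agree on the label order")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Prediction result
#'
#' Per-cell class probabilities and hard labels from [predictCells()].
#'
#' @slot probs cells x K matrix of final class probabilities (rows sum to 1).
#' @slot labels factor of predicted cell types with levels = label order.
#' @slot perModelProbs optional list of M cells x K per-model probability
#'   matrices (empty list unless requested).
#'
#' @exportClass PredictionResult
setClass("PredictionResult",
  representation(
    probs = "matrix",
    labels = "factor",
    perModelProbs = "list"
  )
)

setValidity("PredictionResult", function(object) {
  msg <- character()
  if (nrow(object@probs) != length(object@labels)) {
    msg <- c(msg, "one label per row of probs is required")
  }
  if (nrow(object@probs) > 0) {
    rs <- rowSums(object@probs)
    if (any(abs(rs - 1) > 1e-6) || any(object@probs < 0)) {
      msg <- c(msg, "probability rows must be nonnegative and sum to 1")
    }
  }
  if (length(msg)) msg else TRUE
})
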