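#' @rdname accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @rdname accessors
#' @export
setGeneric("labelOrder", function(x) standardGeneric("labelOrder"))

#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname accessors
#' @export
setGeneric("votingWeights", function(x) standardGeneric("votingWeights"))

#' @rdname accessors
#' @export
setGeneric("subsetSpecs", function(x) standardGeneric("subsetSpecs"))

#' Accessors for scSwarmLDA objects
#'
#' \code{nModels} returns the number of swarm members; \code{labelOrder} the
#' fixed ordering of cell types; \code{selectedGenes} the screened marker
#' union; \code{votingWeights} the softmax-normalized M x K voting-weight
#' matrix (columns sum to 1 over models); \code{subsetSpecs} the list of
#' per-subset index sets of a [SwarmPlan-class].
#'
#' @param x a [GeneScreenResult-class], [SwarmPlan-class],
#'   [EnsembleModel-class] or [PredictionResult-class] object, as applicable.
#' @return See description; vectors, matrices or lists.
#' @name accessors
#' @aliases nModels labelOrder selectedGenes votingWeights subsetSpecs
NULL

#' @rdname accessors
#' @export
setMethod("nModels", "SwarmPlan", function(x) x@M)

#' @rdname accessors
#' @export
setMethod("nModels", "EnsembleModel", function(x) length(x@pldaModels))

#' @rdname accessors
#' @export
setMethod("labelOrder", "EnsembleModel", function(x) x@labelOrder)

#' @rdname accessors
#' @export
setMethod("labelOrder", "PredictionResult", function(x) levels(x@labels))

#' @rdname accessors
#' @export
setMethod("selectedGenes", "GeneScreenResult", function(x) x@selectedGenes)

#' @rdname accessors
#' @export
setMethod("votingWeights", "EnsembleModel", function(x) {
  softmaxColumns(x@votingLogits)
})

#' @rdname accessors
#' @export
setMethod("subsetSpecs", "SwarmPlan", function(x) x@subsets)

setMethod("show", "GeneScreenResult", function(object) {
  cat("GeneScreenResult:", nrow(object@pvalues), "cell types x",
      ncol(object@pvalues), "genes\n")
  cat("  top", object@topN, "genes per class;",
      length(object@selectedGenes), "genes in the selected union\n")
})

setMethod("show", "SwarmPlan", function(object) {
  s1 <- object@subsets[[1L]]
  cat("SwarmPlan:", object@M, "subsets of", object@n, "cells x",
      object@p, "genes\n")
  cat("  per subset:", length(s1$cell_idx), "cells (fraction",
      format(object@cellFrac), "),", length(s1$gene_idx), "genes;",
      "sampling:", object@samplingMode,
      if (object@stratify) "(stratified)" else "", "\n")
  cat("  master seed:", object@masterSeed, "\n")
})

setMethod("show", "PLDAModel", function(object) {
  cat("PLDAModel:", nrow(object@means), "classes,",
      ncol(object@means), "genes\n")
  cat("  penalty:", object@penaltyKind, "beta =", format(object@beta), "\n")
})

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel:", length(object@pldaModels), "pLDA members,",
      length(object@labelOrder), "cell types\n")
  cat("  classes:", paste(object@labelOrder, collapse = ", "), "\n")
  cat("  alpha =", object@alpha,
      if (object@sharedVoter) "; shared voter" else "; per-class voters", "\n")
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat("  trained", nrow(object@history), "epochs; final val loss",
        format(last$val_loss, digits = 4), "\n")
  }
})

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult:", nrow(object@probs), "cells,",
      ncol(object@probs), "classes\n")
  if (length(object@labels)) {
    tab <- table(object@labels)
    cat("  predicted counts:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' Extract predicted labels and probabilities
#'
#' @param x a [PredictionResult-class].
#' @return \code{predictedLabels}: factor of per-cell calls;
#'   \code{classProbabilities}: cells x K probability matrix.
#' @export
predictedLabels <- function(x) {
  stopifnot(is(x, "PredictionResult"))
  x@labels
}

#' @rdname predictedLabels
#' @export
classProbabilities <- function(x) {
  stopifnot(is(x, "PredictionResult"))
  x@probs
}
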