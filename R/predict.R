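#' Annotate query cells with a trained ensemble
#'
#' Runs the inference path: per member, the query expression is aligned to
#' the member's gene list by gene name (genes absent from the query are
#' imputed as 0 on the log scale), discriminant scores are computed, passed
#' through the member's prediction network, and the per-model probabilities
#' are combined by the softmax-weighted vote. A raw-count query is
#' log-normalized with the scale factor stored at training time.
#'
#' @param model an [EnsembleModel-class].
#' @param query a \code{SingleCellExperiment} (raw or log-normalized) or a
#'   cells x genes numeric matrix of log-normalized values with gene names
#'   as column names.
#' @param perModel also return the M per-model probability matrices;
#'   default FALSE.
#' @return a [PredictionResult-class]. Hard labels are the per-row argmax,
#'   with ties broken by position in \code{labelOrder(model)}.
#' @export
predictCells <- function(model, query, perModel = FALSE) {
  if (methods::is(query, "SingleCellExperiment")) {
    if (identical(S4Vectors::metadata(query)$layer, "raw")) {
      sf <- model@config$scaleFactor %||% 10000
      query <- logNormalize(query, scaleFactor = sf)
    }
    X <- t(as.matrix(SummarizedExperiment::assay(query, "logcounts")))
  } else {
    X <- as.matrix(query)
  }
  if (is.null(colnames(X))) stopf("query must carry gene names")
  ensGenes <- unique(unlist(lapply(model@pldaModels,
                                   function(m) m@geneNames)))
  present <- intersect(ensGenes, colnames(X))
  if (length(present) < 0.5 * length(ensGenes)) {
    stopf(paste0("only %d of the ensemble's %d genes are present in the ",
                 "query (%.1f%%); at least 50%% are required"),
          length(present), length(ensGenes),
          100 * length(present) / length(ensGenes))
  }
  nCells <- nrow(X)
  K <- length(model@labelOrder)
  M <- length(model@pldaModels)
  # one zero-padded block holding every ensemble gene, aligned by name
  Xall <- matrix(0, nCells, length(ensGenes),
                 dimnames = list(rownames(X), ensGenes))
  Xall[, present] <- X[, present, drop = FALSE]
  prelim <- vector("list", M)
  for (m in seq_len(M)) {
    pm <- model@pldaModels[[m]]
    sc <- discriminantScores(pm, Xall[, pm@geneNames, drop = FALSE])
    prelim[[m]] <- prelimForwardFull(model@prelimNets[[m]], sc)$probs
  }
  W <- votingWeightMatrix(model@votingLogits, model@sharedVoter, K)
  probs <- aggregateVote(prelim, W)
  colnames(probs) <- model@labelOrder
  rownames(probs) <- rownames(X)
  lab <- if (nCells > 0) {
    factor(model@labelOrder[argmaxFirst(probs)], levels = model@labelOrder)
  } else {
    factor(character(0), levels = model@labelOrder)
  }
  names(lab) <- rownames(X)
  methods::new("PredictionResult",
    probs = probs, labels = lab,
    perModelProbs = if (perModel) prelim else list()
  )
}

#' Persist / restore a trained ensemble
#'
#' Writes the model as a bundle directory: \code{manifest.json} (label
#' order, configuration, alpha, voter mode, package version) plus
#' \code{params.rds} holding all numeric parameters. Reloading then
#' predicting reproduces the original predictions bit-exactly.
#'
#' @param model an [EnsembleModel-class].
#' @param path bundle directory.
#' @return \code{saveEnsembleModel}: the path, invisibly;
#'   \code{loadEnsembleModel}: the restored [EnsembleModel-class].
#' @export
saveEnsembleModel <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  manifest <- list(
    package = "scSwarmLDA",
    version = as.character(utils::packageVersion("scSwarmLDA")),
    label_order = model@labelOrder,
    n_models = length(model@pldaModels),
    alpha = model@alpha,
    shared_voter = model@sharedVoter,
    config = model@config[setdiff(names(model@config), "screen")]
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(list(pldaModels = model@pldaModels,
               prelimNets = model@prelimNets,
               votingLogits = model@votingLogits,
               labelOrder = model@labelOrder,
               alpha = model@alpha,
               sharedVoter = model@sharedVoter,
               config = model@config,
               history = model@history),
          file.path(path, "params.rds"))
  invisible(path)
}

#' @rdname saveEnsembleModel
#' @export
loadEnsembleModel <- function(path) {
  f <- file.path(path, "params.rds")
  if (!file.exists(f)) stopf("no model bundle at '%s'", path)
  x <- readRDS(f)
  methods::new("EnsembleModel",
    pldaModels = x$pldaModels, prelimNets = x$prelimNets,
    votingLogits = x$votingLogits, labelOrder = x$labelOrder,
    alpha = x$alpha, sharedVoter = x$sharedVoter, config = x$config,
    history = x$history
  )
}
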