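#' End-to-end training pipeline
#'
#' Composes the full workflow on a labelled reference: QC filtering,
#' log-normalization, Wilcoxon marker screening, swarm subset drawing, and
#' joint ensemble training. Returns the trained [EnsembleModel-class] with a
#' run manifest (all tunables, seeds, selected genes and per-stage counts)
#' stored in its configuration.
#'
#' @param sce raw-count \code{SingleCellExperiment} reference.
#' @param labels factor of cell types aligned to \code{colnames(sce)} (or a
#'   column name of \code{colData(sce)}).
#' @param minGenesPerCell,minCellsPerGene QC thresholds, see [qcFilter()].
#' @param scaleFactor log-normalization scale; default 10000.
#' @param topN per-class screening list size; default 400.
#' @param M number of swarm members; default 300.
#' @param cellFrac cell fraction per subset; default 0.8.
#' @param samplingMode,stratify subset sampling options, see [drawSwarm()].
#' @param weightedByScreen in weighted mode, derive gene weights from the
#'   screening p-values via [screenGeneWeights()]; default TRUE.
#' @param config ensemble training configuration from [ensembleConfig()];
#'   its seed also seeds the swarm plan.
#' @param verbose log per-stage progress; default FALSE.
#' @return an [EnsembleModel-class] whose \code{config} carries the run
#'   manifest (\code{screen}, \code{plan}, stage counts, all tunables).
#' @export
trainPipeline <- function(sce, labels,
                          minGenesPerCell = 200, minCellsPerGene = 3,
                          scaleFactor = 10000, topN = 400,
                          M = 300, cellFrac = 0.8,
                          samplingMode = c("uniform", "weighted"),
                          stratify = FALSE, weightedByScreen = TRUE,
                          config = ensembleConfig(), verbose = FALSE) {
  samplingMode <- match.arg(samplingMode)
  say <- function(...) if (verbose) message("[", ..., "]")
  if (is.character(labels) && length(labels) == 1L) {
    labels <- SummarizedExperiment::colData(sce)[[labels]]
    names(labels) <- colnames(sce)
  }
  if (is.null(names(labels))) names(labels) <- colnames(sce)
  missing <- setdiff(colnames(sce), names(labels))
  if (length(missing)) {
    stopf("no label for cell '%s' (%d unlabelled cells)",
          missing[1L], length(missing))
  }

  say("qc: ", ncol(sce), " cells x ", nrow(sce), " genes in")
  t0 <- proc.time()[["elapsed"]]
  sce <- qcFilter(sce, minGenesPerCell, minCellsPerGene)
  labels <- droplevels(as.factor(labels[colnames(sce)]))
  say("qc: ", ncol(sce), " cells x ", nrow(sce), " genes kept")

  sce <- logNormalize(sce, scaleFactor)
  screen <- screenMarkerGenes(sce, labels, topN = topN)
  genes <- selectedGenes(screen)
  say("screen: ", length(genes), " genes selected")

  X <- t(as.matrix(
    SummarizedExperiment::assay(sce, "logcounts")[genes, , drop = FALSE]))
  plan <- drawSwarm(
    n = nrow(X), p = ncol(X), M = M, cellFrac = cellFrac,
    samplingMode = samplingMode,
    geneWeights = if (samplingMode == "weighted" && weightedByScreen) {
      screenGeneWeights(screen, genes)
    } else NULL,
    labels = labels, stratify = stratify, masterSeed = config$seed
  )
  say("swarm: ", M, " subsets of ", length(plan@subsets[[1L]]$cell_idx),
      " cells x ", length(plan@subsets[[1L]]$gene_idx), " genes")

  model <- trainEnsemble(X, labels, plan, config)
  say("train: ", nrow(model@history), " epochs, ",
      round(proc.time()[["elapsed"]] - t0, 1), "s total")

  model@config <- c(model@config, list(
    scaleFactor = scaleFactor, topN = topN,
    minGenesPerCell = minGenesPerCell, minCellsPerGene = minCellsPerGene,
    M = M, cellFrac = cellFrac, samplingMode = samplingMode,
    stratify = stratify,
    nCellsUsed = nrow(X), nGenesScreened = ncol(X),
    screen = screen, plan = plan
  ))
  model
}

#' Evaluate predicted against true cell types
#'
#' Computes overall accuracy (proportion of correctly assigned cells), the
#' confusion matrix (truth in rows), per-class F1 (harmonic mean of
#' precision and recall; 0 for degenerate classes with no true and no
#' predicted positives, which are flagged) and macro F1 (unweighted mean
#' over classes present in the truth). Truth labels absent from the model's
#' label order are scored as errors.
#'
#' @param pred a [PredictionResult-class], factor, or character vector of
#'   predicted types.
#' @param truth factor or character vector of true types, same length.
#' @return list with \code{overallAccuracy}, \code{macroF1},
#'   \code{perClassF1}, \code{confusion}, \code{degenerateClasses}.
#' @export
evaluateAnnotation <- function(pred, truth) {
  if (methods::is(pred, "PredictionResult")) pred <- predictedLabels(pred)
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    stopf("pred (%d) and truth (%d) lengths differ",
          length(pred), length(truth))
  }
  levs <- union(unique(truth), unique(pred))
  predF <- factor(pred, levels = levs)
  truthF <- factor(truth, levels = levs)
  confusion <- table(truth = truthF, predicted = predF)
  acc <- sum(diag(confusion)) / length(truth)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  names(f1) <- levs
  degenerate <- levs[tp == 0 & fp == 0 & fn == 0]
  inTruth <- levs[rowSums(confusion) > 0]
  list(
    overallAccuracy = acc,
    macroF1 = mean(f1[inTruth]),
    perClassF1 = f1,
    confusion = confusion,
    degenerateClasses = degenerate
  )
}

#' Write predictions as TSV
#'
#' One row per cell: \code{cell_id}, \code{predicted_type}, then one
#' probability column per cell type in label order. An empty prediction
#' yields a valid header-only file.
#'
#' @param pred a [PredictionResult-class].
#' @param path output path.
#' @return the output path, invisibly.
#' @export
writePredictionsTSV <- function(pred, path) {
  probs <- classProbabilities(pred)
  dt <- data.table::data.table(
    cell_id = if (is.null(rownames(probs))) {
      as.character(seq_len(nrow(probs)))
    } else rownames(probs),
    predicted_type = as.character(predictedLabels(pred))
  )
  for (k in colnames(probs)) {
    data.table::set(dt, j = paste0("prob_", k), value = probs[, k])
  }
  if (nrow(dt) == 0L) {
    # fwrite drops the header of 0-row tables built with set(); write it
    writeLines(paste(c("cell_id", "predicted_type",
                       paste0("prob_", colnames(probs))), collapse = "\t"),
               path)
  } else {
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}
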