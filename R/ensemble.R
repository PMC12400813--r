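#' Softmax-weighted aggregation of per-model predictions
#'
#' Combines the M preliminary probability matrices into final class
#' probabilities: \code{P[i,k] = sum_m w_mk p_m[i,k] / sum_m w_mk}, followed
#' by a row renormalization so every cell's probabilities sum to 1. With
#' softmax-normalized weights the explicit division by \code{sum_m w_mk} is
#' the identity, but it is kept to guard masked/shared-weight variants.
#'
#' @param prelim list of M cells x K probability matrices.
#' @param weights M x K matrix of nonnegative voting weights whose columns
#'   sum to 1 over models (see [votingWeights()]).
#' @return cells x K matrix of final probabilities, rows summing to 1.
#' @export
aggregateVote <- function(prelim, weights) {
  M <- length(prelim)
  stopifnot(M >= 1L, is.matrix(weights), nrow(weights) == M)
  K <- ncol(prelim[[1L]])
  if (ncol(weights) != K) stopf("weights must be M x K")
  Q <- matrix(0, nrow(prelim[[1L]]), K)
  for (m in seq_len(M)) {
    pm <- prelim[[m]]
    if (!identical(dim(pm), dim(Q))) {
      stopf("per-model prediction %d has mismatched shape", m)
    }
    Q <- Q + sweep(pm, 2L, weights[m, ], "*")
  }
  Q <- sweep(Q, 2L, colSums(weights), "/")
  sw <- rowSums(Q)
  if (nrow(Q)) Q <- Q / sw
  colnames(Q) <- colnames(prelim[[1L]])
  Q
}

#' Combined ensemble loss
#'
#' \code{alpha * CE(final, y) + (1 - alpha) * sum_m CE(prelim_m, y)}, where
#' CE is the mean-over-cells cross-entropy. The second term aligns each
#' model's preliminary predictions with the truth, acting as a skip
#' connection from the intermediate outputs to the loss; \code{alpha = 1}
#' recovers the standard final-layer cross-entropy.
#'
#' @param final cells x K matrix of final probabilities.
#' @param prelim list of M cells x K preliminary probability matrices.
#' @param y factor (or integer codes) of true classes, aligned to rows.
#' @param alpha mixing weight in [0, 1].
#' @return scalar loss, nonnegative.
#' @export
ensembleLoss <- function(final, prelim, y, alpha) {
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  yIdx <- if (is.factor(y)) as.integer(y) else as.integer(y)
  ceFinal <- crossEntropy(final, yIdx)
  cePrelim <- sum(vapply(prelim, crossEntropy, numeric(1), yIdx = yIdx))
  alpha * ceFinal + (1 - alpha) * cePrelim
}

#' Training configuration for the ensemble
#'
#' Collects all tunables of [trainEnsemble()] with their defaults and
#' validates ranges.
#'
#' @param beta covariance regularization weight; default \code{1e-6}.
#' @param penaltyKind \code{"trace_shrinkage"} or \code{"tikhonov"}.
#' @param priors \code{"empirical"} (full-reference class proportions) or
#'   \code{"uniform"}.
#' @param alpha loss mixing weight in [0, 1]; default 0.5.
#' @param sharedVoter constrain all K voting-weight columns to be equal;
#'   default FALSE (cell-type-specific voters).
#' @param hidden hidden width of each prediction network; default
#'   \code{max(16, 4K)} (resolved at fit time when NULL).
#' @param lr SGD learning rate; default 0.01.
#' @param momentum SGD momentum; default 0.9.
#' @param batchSize minibatch size; default 64. Small enough to give a
#'   useful number of SGD updates per epoch on references of a few hundred
#'   cells; raise it for large references.
#' @param maxEpochs epoch cap; default 200.
#' @param patience early-stopping patience on validation loss; default 10.
#' @param valFrac stratified validation fraction; default 0.1.
#' @param seed RNG seed governing initialization, the split and batching.
#' @return a validated configuration list.
#' @export
ensembleConfig <- function(beta = 1e-6,
                           penaltyKind = c("trace_shrinkage", "tikhonov"),
                           priors = c("empirical", "uniform"),
                           alpha = 0.5, sharedVoter = FALSE, hidden = NULL,
                           lr = 0.01, momentum = 0.9, batchSize = 64,
                           maxEpochs = 200, patience = 10, valFrac = 0.1,
                           seed = 1L) {
  penaltyKind <- match.arg(penaltyKind)
  priors <- match.arg(priors)
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  if (lr <= 0) stopf("lr must be positive")
  if (momentum < 0 || momentum >= 1) stopf("momentum must be in [0, 1)")
  if (valFrac < 0 || valFrac >= 0.5) stopf("valFrac must be in [0, 0.5)")
  list(beta = beta, penaltyKind = penaltyKind, priors = priors,
       alpha = alpha, sharedVoter = isTRUE(sharedVoter), hidden = hidden,
       lr = lr, momentum = momentum, batchSize = as.integer(batchSize),
       maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
       valFrac = valFrac, seed = as.integer(seed))
}

# Forward pass of the whole ensemble on precomputed score matrices.
# Returns prelim list, pre-normalization Q, and final probabilities.
ensembleForward <- function(nets, logits, sharedVoter, scoreList, rows) {
  M <- length(nets)
  W <- votingWeightMatrix(logits, sharedVoter, ncol(scoreList[[1L]]))
  fwd <- vector("list", M)
  prelim <- vector("list", M)
  for (m in seq_len(M)) {
    fwd[[m]] <- prelimForwardFull(nets[[m]],
                                  scoreList[[m]][rows, , drop = FALSE])
    prelim[[m]] <- fwd[[m]]$probs
  }
  Q <- matrix(0, length(rows), ncol(W))
  for (m in seq_len(M)) Q <- Q + sweep(prelim[[m]], 2L, W[m, ], "*")
  s <- rowSums(Q)
  list(fwd = fwd, prelim = prelim, Q = Q, final = Q / s, W = W)
}

votingWeightMatrix <- function(logits, sharedVoter, K) {
  if (sharedVoter) {
    w <- softmaxColumns(matrix(logits[, 1L], ncol = 1L))
    matrix(w, nrow(logits), K)
  } else {
    softmaxColumns(logits)
  }
}

# Gradients of the combined loss wrt net parameters and voting logits for
# one minibatch. Derivation: with Q[i,k] = sum_m w_mk p_m[i,k] and
# s_i = sum_k Q[i,k], the final cross-entropy has
# dCE/dQ[i,k] = -(1/n) (1[k = y_i]/Q[i,y_i] - 1/s_i); the softmax voting
# weights give dL/dlogit[m,k] = alpha * w_mk * sum_i G[i,k] (p_m - Q)[i,k].
ensembleBackward <- function(nets, logits, sharedVoter, ef, yIdx, alpha,
                             eps = 1e-12) {
  M <- length(nets)
  nB <- length(yIdx)
  K <- ncol(ef$Q)
  Q <- pmax(ef$Q, eps)
  s <- rowSums(ef$Q)
  G <- matrix(1 / s, nB, K)
  idx <- cbind(seq_len(nB), yIdx)
  G[idx] <- G[idx] - 1 / Q[idx]
  G <- G / nB
  netGrads <- vector("list", M)
  gLogits <- matrix(0, M, K)
  for (m in seq_len(M)) {
    pm <- ef$prelim[[m]]
    dP <- sweep(G, 2L, ef$W[m, ], "*") * alpha
    if (alpha < 1) {
      D <- matrix(0, nB, K)
      D[idx] <- -1 / (nB * pmax(pm[idx], eps))
      dP <- dP + (1 - alpha) * D
    }
    netGrads[[m]] <- prelimBackward(nets[[m]], ef$fwd[[m]], dP)
    gLogits[m, ] <- alpha * ef$W[m, ] * colSums(G * (pm - ef$Q))
  }
  if (sharedVoter) {
    gLogits <- matrix(rowSums(gLogits), M, 1L)
  }
  list(nets = netGrads, logits = gLogits)
}

# Stratified index split: returns list(train, val) preserving class
# proportions; every class keeps >= 1 training cell.
stratifiedSplit <- function(y, valFrac) {
  val <- integer(0)
  for (lev in levels(y)) {
    inK <- which(y == lev)
    nVal <- floor(length(inK) * valFrac)
    nVal <- min(nVal, length(inK) - 1L)
    if (nVal > 0) val <- c(val, inK[sample.int(length(inK), nVal)])
  }
  list(train = setdiff(seq_along(y), val), val = sort(val))
}

#' Train the swarm ensemble
#'
#' Fits the full annotator on a screened, log-normalized reference: (1) each
#' of the plan's M subsets gets a closed-form penalized LDA fit (no
#' gradients); (2) each member's discriminant scores are precomputed for all
#' reference cells; (3) the M preliminary-prediction networks and the voting
#' logits are trained jointly by minibatch SGD with momentum on the combined
#' loss [ensembleLoss()], with a stratified held-out split for early
#' stopping (the best-validation parameters are kept). Fully reproducible
#' from \code{config$seed}.
#'
#' @param X cells x genes matrix of log-normalized expression restricted to
#'   the screened genes (column names = gene names), or a log-normalized
#'   \code{SingleCellExperiment} (its \code{"logcounts"} assay is used).
#' @param labels factor of cell types aligned to the cells; each class needs
#'   at least 2 cells.
#' @param plan a [SwarmPlan-class] indexing into the cells and genes of
#'   \code{X}.
#' @param config a list from [ensembleConfig()].
#' @return an [EnsembleModel-class].
#' @export
trainEnsemble <- function(X, labels, plan, config = ensembleConfig()) {
  if (methods::is(X, "SingleCellExperiment")) {
    stopifnot(identical(S4Vectors::metadata(X)$layer, "lognorm"))
    X <- t(as.matrix(SummarizedExperiment::assay(X, "logcounts")))
  }
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  n <- nrow(X); p <- ncol(X); K <- nlevels(labels)
  if (length(labels) != n) stopf("labels length must match rows of X")
  if (plan@n != n || plan@p != p) {
    stopf("plan was drawn for %d cells x %d genes, data are %d x %d",
          plan@n, plan@p, n, p)
  }
  if (any(table(labels) < 2L)) stopf("every class needs at least 2 cells")
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(p))

  fullProps <- table(labels) / n
  M <- plan@M
  pldaModels <- vector("list", M)
  scoreList <- vector("list", M)
  for (m in seq_len(M)) {
    s <- plan@subsets[[m]]
    pldaModels[[m]] <- fitPLDA(
      X[s$cell_idx, s$gene_idx, drop = FALSE],
      labels[s$cell_idx],
      beta = config$beta, penaltyKind = config$penaltyKind,
      priors = config$priors,
      priorWeights = if (config$priors == "empirical") fullProps else NULL
    )
    scoreList[[m]] <- discriminantScores(pldaModels[[m]],
                                         X[, s$gene_idx, drop = FALSE])
  }

  hidden <- if (is.null(config$hidden)) max(16L, 4L * K)
    else as.integer(config$hidden)
  trained <- withSeed(config$seed, {
    split <- stratifiedSplit(labels, config$valFrac)
    nets <- lapply(seq_len(M), function(m) {
      tr <- scoreList[[m]][split$train, , drop = FALSE]
      sds <- apply(tr, 2L, stats::sd)
      initPrelimNet(K, hidden,
                    center = colMeans(tr),
                    scale = ifelse(sds > 0, sds, 1))
    })
    logits <- matrix(0, M, if (config$sharedVoter) 1L else K)
    sgdTrain(nets, logits, config, scoreList, as.integer(labels), split, K)
  })

  methods::new("EnsembleModel",
    pldaModels = pldaModels,
    prelimNets = trained$nets,
    votingLogits = if (config$sharedVoter) {
      matrix(trained$logits[, 1L], M, K)
    } else trained$logits,
    labelOrder = levels(labels),
    alpha = config$alpha,
    sharedVoter = config$sharedVoter,
    config = config,
    history = trained$history
  )
}

# Joint minibatch SGD with momentum and early stopping. Runs inside
# withSeed(config$seed, ...) so batching is reproducible.
sgdTrain <- function(nets, logits, config, scoreList, yIdx, split, K) {
  M <- length(nets)
  alpha <- config$alpha
  vel <- list(
    nets = lapply(nets, function(nt) {
      list(W1 = nt$W1 * 0, b1 = nt$b1 * 0, W2 = nt$W2 * 0, b2 = nt$b2 * 0)
    }),
    logits = logits * 0
  )
  evalLoss <- function(rows) {
    ef <- ensembleForward(nets, logits, config$sharedVoter, scoreList, rows)
    final <- ef$Q / rowSums(ef$Q)
    list(
      loss = ensembleLoss(final, ef$prelim, yIdx[rows], alpha),
      acc = mean(argmaxFirst(final) == yIdx[rows])
    )
  }
  hasVal <- length(split$val) > 0
  best <- list(loss = Inf, nets = nets, logits = logits, epoch = 0L)
  wait <- 0L
  hist <- vector("list", config$maxEpochs)
  nTrain <- length(split$train)
  for (epoch in seq_len(config$maxEpochs)) {
    ord <- split$train[sample.int(nTrain)]
    starts <- seq(1L, nTrain, by = config$batchSize)
    for (st in starts) {
      rows <- ord[st:min(st + config$batchSize - 1L, nTrain)]
      ef <- ensembleForward(nets, logits, config$sharedVoter, scoreList,
                            rows)
      if (any(!is.finite(ef$Q))) {
        stopf("training diverged (non-finite loss); lower lr (current %g)",
              config$lr)
      }
      gr <- ensembleBackward(nets, logits, config$sharedVoter, ef,
                             yIdx[rows], alpha)
      for (m in seq_len(M)) {
        for (nm in c("W1", "b1", "W2", "b2")) {
          vel$nets[[m]][[nm]] <- config$momentum * vel$nets[[m]][[nm]] -
            config$lr * gr$nets[[m]][[nm]]
          nets[[m]][[nm]] <- nets[[m]][[nm]] + vel$nets[[m]][[nm]]
        }
      }
      vel$logits <- config$momentum * vel$logits - config$lr * gr$logits
      logits <- logits + vel$logits
    }
    trainStats <- evalLoss(split$train)
    valStats <- if (hasVal) evalLoss(split$val) else trainStats
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = trainStats$loss,
                                train_acc = trainStats$acc,
                                val_loss = valStats$loss,
                                val_acc = valStats$acc)
    if (valStats$loss < best$loss - 1e-8) {
      best <- list(loss = valStats$loss, nets = nets, logits = logits,
                   epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(nets = best$nets, logits = best$logits,
       history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]))
}
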