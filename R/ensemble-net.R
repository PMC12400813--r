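# Per-model prediction networks g^(m): a fixed affine input standardization
# (mean/sd of the training-set discriminant scores, needed because raw
# discriminant values can span orders of magnitude), one hidden ReLU layer,
# and a softmax output. Parameters are plain lists so the joint SGD loop can
# update them in place without any framework.

#' Initialize a preliminary-prediction network
#'
#' Creates the parameter list of one per-model network g: a fixed input
#' standardization (from \code{center}/\code{scale}), a hidden ReLU layer of
#' \code{hidden} units (He initialization) and a linear softmax output
#' initialized at zero.
#'
#' @param K number of classes (input and output dimension).
#' @param hidden hidden width; default \code{max(16, 4 * K)}.
#' @param center,scale length-K standardization of the input scores
#'   (defaults: no shift / unit scale).
#' @return a network parameter list (fields \code{center}, \code{scale},
#'   \code{W1}, \code{b1}, \code{W2}, \code{b2}).
#' @export
initPrelimNet <- function(K, hidden = max(16L, 4L * K),
                          center = rep(0, K), scale = rep(1, K)) {
  stopifnot(K >= 2L, hidden >= 1L,
            length(center) == K, length(scale) == K, all(scale > 0))
  list(
    center = as.numeric(center),
    scale = as.numeric(scale),
    W1 = matrix(stats::rnorm(K * hidden, sd = sqrt(2 / K)), K, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(stats::rnorm(hidden * K, sd = sqrt(2 / hidden)), hidden, K),
    b2 = rep(0, K)
  )
}

#' Forward pass of a preliminary-prediction network
#'
#' Maps a cells x K matrix of discriminant scores to rows on the probability
#' simplex. Deterministic given the parameters.
#'
#' @param net a network parameter list from [initPrelimNet()].
#' @param scores cells x K matrix of finite discriminant scores.
#' @return cells x K matrix; each row is nonnegative and sums to 1.
#' @export
prelimForward <- function(net, scores) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stopf("discriminant scores must be finite")
  prelimForwardFull(net, scores)$probs
}

# Forward pass keeping intermediates for backprop.
prelimForwardFull <- function(net, scores) {
  Z0 <- sweep(sweep(scores, 2L, net$center, "-"), 2L, net$scale, "/")
  A1 <- Z0 %*% net$W1
  A1 <- sweep(A1, 2L, net$b1, "+")
  H <- pmax(A1, 0)
  Z <- H %*% net$W2
  Z <- sweep(Z, 2L, net$b2, "+")
  list(probs = softmaxRows(Z), H = H, Z0 = Z0)
}

# Backprop through one net given dLoss/dprobs; returns parameter gradients.
# fwd is the list from prelimForwardFull.
prelimBackward <- function(net, fwd, dProbs) {
  P <- fwd$probs
  # softmax jacobian: dZ = P * (dP - rowSums(dP * P))
  dZ <- P * (dProbs - rowSums(dProbs * P))
  gW2 <- crossprod(fwd$H, dZ)
  gb2 <- colSums(dZ)
  dH <- dZ %*% t(net$W2)
  dH[fwd$H <= 0] <- 0
  gW1 <- crossprod(fwd$Z0, dH)
  gb1 <- colSums(dH)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

#' Baseline proportional preliminary prediction
#'
#' The non-learned reference mapping from a vector of K discriminant scores
#' to class probabilities. Because discriminant values can be negative, the
#' direct ratio \code{delta_k / sum(delta)} is ill-defined off the positive
#' orthant, so the probabilities are taken proportional to
#' \code{exp(delta_k)} (softmax), which preserves the score ordering and is
#' invariant to adding a constant to all scores. Provided as a diagnostic
#' reference, not used in training.
#'
#' @param scores numeric vector of K discriminant scores, or a cells x K
#'   matrix (applied row-wise).
#' @return probability vector (or matrix of rows) on the simplex.
#' @examples
#' proportionalProbs(c(0, log(3)))  # 0.25 0.75
#' @export
proportionalProbs <- function(scores) {
  if (is.matrix(scores)) {
    softmaxRows(scores)
  } else {
    as.numeric(softmaxRows(matrix(scores, nrow = 1L)))
  }
}
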