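#' Class means and pooled maximum-likelihood covariance
#'
#' Computes the per-class sample means and the pooled within-class
#' covariance with denominator n (the maximum-likelihood estimator under the
#' shared-covariance Gaussian model, not the unbiased n - K version).
#'
#' @param X cells x genes numeric matrix.
#' @param y factor of class labels; every level must be present.
#' @return list with \code{means} (K x p) and \code{S} (p x p, symmetric
#'   positive semidefinite).
#' @export
pooledCovariance <- function(X, y) {
  X <- as.matrix(X)
  y <- as.factor(y)
  counts <- table(y)
  if (any(counts == 0L)) {
    stopf("class '%s' has no cells in this subset",
          names(counts)[which(counts == 0L)[1L]])
  }
  if (nlevels(y) < 2L) stopf("need at least 2 classes")
  n <- nrow(X)
  means <- rowsum(X, y) / as.numeric(counts)
  Xc <- X - means[as.integer(y), , drop = FALSE]
  S <- crossprod(Xc) / n
  S <- (S + t(S)) / 2
  list(means = means, S = S)
}

#' Trace-preserving shrinkage of a covariance matrix
#'
#' Returns \code{(1 - beta) * S + beta * Tr(S) * I / p}, the convex
#' combination of the sample covariance with the trace-matched scaled
#' identity. The total variance Tr(S) is conserved for every beta, and the
#' result is positive definite whenever \code{beta > 0} and \code{Tr(S) > 0}.
#'
#' @param S symmetric positive semidefinite matrix.
#' @param beta shrinkage weight in [0, 1].
#' @return regularized covariance matrix.
#' @export
shrinkCovariance <- function(S, beta) {
  checkCovArgs(S, beta)
  if (beta < 0 || beta > 1) stopf("beta must be in [0, 1]")
  tr <- sum(diag(S))
  if (beta > 0 && tr <= 0) {
    stopf("Tr(S) = 0: data are degenerate, shrinkage target is undefined")
  }
  p <- ncol(S)
  out <- (1 - beta) * S
  diag(out) <- diag(out) + beta * tr / p
  out
}

#' Tikhonov (ridge) regularization of a covariance matrix
#'
#' Returns \code{S + beta * I}, the alternative penalty that shifts every
#' eigenvalue up by beta. Unlike [shrinkCovariance()] it does not conserve
#' the trace.
#'
#' @param S symmetric positive semidefinite matrix.
#' @param beta nonnegative ridge weight.
#' @return regularized covariance matrix.
#' @export
tikhonovCovariance <- function(S, beta) {
  checkCovArgs(S, beta)
  if (beta < 0) stopf("beta must be >= 0")
  out <- S
  diag(out) <- diag(out) + beta
  out
}

checkCovArgs <- function(S, beta) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stopf("S must be square")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stopf("S must be symmetric")
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta)) {
    stopf("beta must be a single finite number")
  }
}

#' Fit a penalized LDA model
#'
#' Closed-form fit of the shared-covariance Gaussian classifier with a
#' regularized covariance estimate: class means and pooled ML covariance,
#' the chosen penalty (trace shrinkage by default, Tikhonov as an
#' alternative), and log class priors. Scoring quantities are precomputed
#' through a Cholesky factorization of the regularized covariance; no
#' explicit matrix inverse is formed.
#'
#' @param X cells x genes numeric matrix (log-normalized expression).
#' @param y factor of class labels aligned to rows of \code{X}.
#' @param beta regularization weight; default \code{1e-6}.
#' @param penaltyKind \code{"trace_shrinkage"} (default) or
#'   \code{"tikhonov"}.
#' @param priors \code{"empirical"} (class proportions; default) or
#'   \code{"uniform"}.
#' @param priorWeights optional named numeric vector of class proportions to
#'   use instead of the proportions in \code{y} (e.g. the full-reference
#'   proportions when \code{X} is a subset); must cover all levels of
#'   \code{y}.
#' @return a [PLDAModel-class].
#' @export
fitPLDA <- function(X, y, beta = 1e-6,
                    penaltyKind = c("trace_shrinkage", "tikhonov"),
                    priors = c("empirical", "uniform"),
                    priorWeights = NULL) {
  penaltyKind <- match.arg(penaltyKind)
  priors <- match.arg(priors)
  X <- as.matrix(X)
  y <- as.factor(y)
  pc <- pooledCovariance(X, y)
  Sreg <- if (penaltyKind == "trace_shrinkage") {
    shrinkCovariance(pc$S, beta)
  } else {
    tikhonovCovariance(pc$S, beta)
  }
  K <- nlevels(y)
  pk <- if (priors == "uniform") {
    stats::setNames(rep(1 / K, K), levels(y))
  } else if (!is.null(priorWeights)) {
    if (!all(levels(y) %in% names(priorWeights))) {
      stopf("priorWeights must name every class")
    }
    w <- priorWeights[levels(y)]
    w / sum(w)
  } else {
    tab <- table(y)
    stats::setNames(as.numeric(tab) / length(y), names(tab))
  }
  R <- tryCatch(chol(Sreg), error = function(e) {
    stopf(paste0("regularized covariance is numerically singular (%s); ",
                 "raise beta"), conditionMessage(e))
  })
  # coefs = Sigma(beta)^{-1} mu_k via two triangular solves
  coefs <- backsolve(R, backsolve(R, t(pc$means), transpose = TRUE))
  consts <- -0.5 * colSums(t(pc$means) * coefs) + log(pk)
  gn <- colnames(X)
  if (is.null(gn)) gn <- paste0("g", seq_len(ncol(X)))
  methods::new("PLDAModel",
    means = pc$means,
    sigmaChol = R,
    coefs = coefs,
    consts = as.numeric(consts),
    logPriors = as.numeric(log(pk)),
    beta = beta,
    penaltyKind = penaltyKind,
    geneNames = gn,
    classLevels = levels(y)
  )
}

#' Discriminant scores of a penalized LDA model
#'
#' Evaluates \code{delta_k(x) = x' Sigma(beta)^{-1} mu_k - 1/2 mu_k'
#' Sigma(beta)^{-1} mu_k + log pi_k} for every cell and class, using the
#' precomputed factorization solve.
#'
#' @param model a [PLDAModel-class].
#' @param X cells x genes matrix whose columns align with
#'   \code{model@geneNames}.
#' @return cells x K score matrix (column names = class levels).
#' @export
discriminantScores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model@means)) {
    stopf("X has %d columns but the model expects %d genes",
          ncol(X), ncol(model@means))
  }
  sc <- X %*% model@coefs
  sc <- sweep(sc, 2L, model@consts, "+")
  colnames(sc) <- model@classLevels
  sc
}
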