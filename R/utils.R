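# Internal numerical helpers.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-subset seed derived from a master seed and an index.
# Multiplicative hash kept below 2^31 so it is always a valid R integer.
deriveSeed <- function(masterSeed, index) {
  x <- (as.double(masterSeed) %% 2147483647) + 1
  x <- (x * 48271) %% 2147483647
  x <- (x + as.double(index) * 2654435761) %% 2147483647
  as.integer(x)
}

# Row-wise softmax with max subtraction for stability.
softmaxRows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Column-wise softmax (over models within each class column).
softmaxColumns <- function(x) {
  x <- sweep(x, 2L, apply(x, 2L, max), "-")
  e <- exp(x)
  sweep(e, 2L, colSums(e), "/")
}

# Mean cross-entropy of probability rows against integer class labels.
# probs: n x K, yIdx: integer vector in 1..K.
crossEntropy <- function(probs, yIdx, eps = 1e-12) {
  p <- probs[cbind(seq_along(yIdx), yIdx)]
  -mean(log(pmax(p, eps)))
}

# argmax over columns with ties broken by the first (label-order) column.
argmaxFirst <- function(x) max.col(x, ties.method = "first")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
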