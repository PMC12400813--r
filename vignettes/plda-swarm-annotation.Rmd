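---
title: "Annotating cell types with a swarm of penalized LDA models"
author: "scSwarmLDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating cell types with a swarm of penalized LDA models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scSwarmLDA)
```

# The problem and the model

Supervised cell-type annotation takes a labelled reference scRNA-seq
dataset and assigns one of its K cell types to every cell of an unlabelled
query. The obstacles are the usual ones of single-cell data: tens of
thousands of genes against a much smaller number of informative cells per
type, heavy sparsity from dropout, and strongly imbalanced type
frequencies.

scSwarmLDA addresses this with three layers.

**Penalized LDA members.** Each member is a shared-covariance Gaussian
classifier. With class means $\mu_k$ and a pooled covariance $\Sigma$
estimated by maximum likelihood (denominator $n$, matching the Gaussian
log-likelihood being maximized), a cell $x$ is scored by the linear
discriminant

$$\delta_k(x) = x^\top \hat\Sigma(\beta)^{-1}\hat\mu_k
  - \tfrac12 \hat\mu_k^\top \hat\Sigma(\beta)^{-1}\hat\mu_k + \log \pi_k ,$$

where $\pi_k$ is the proportion of type $k$ in the reference. Because the
sample covariance is singular or ill-conditioned whenever the number of
genes approaches the number of cells, the member uses the trace-preserving
shrinkage estimator

$$\hat\Sigma(\beta) = (1-\beta)\,\hat\Sigma
  + \beta\,\mathrm{Tr}(\hat\Sigma)\, I / p ,$$

which interpolates between the sample covariance ($\beta = 0$, plain LDA)
and a scaled identity ($\beta = 1$, the nearest-centroid rule under
uniform priors) while conserving the total variance
$\mathrm{Tr}(\hat\Sigma)$ exactly. A Tikhonov alternative
$\hat\Sigma + \beta I$ is available via `penaltyKind = "tikhonov"`. The
default $\beta = 10^{-6}$ is deliberately tiny: its role is numerical
(guaranteeing positive definiteness), not statistical, because each member
only ever sees a small gene subset. Scoring is done through a Cholesky
factorization of $\hat\Sigma(\beta)$; no explicit inverse is formed, and a
test verifies agreement with brute-force inversion to within $10^{-8}$
relative error.

**A swarm of random subsets.** `drawSwarm()` draws M subsets, each with
80% of the cells and $\lfloor\sqrt p\rfloor + 70$ of the $p$ screened
genes, sampled uniformly without replacement. The gene fraction is tiny,
so members see nearly disjoint gene panels and stay diverse; the cell
fraction is large, so every member still sees each type. For a cell
fraction $f$ the expected pairwise Jaccard overlap between two subsets is
$f/(2-f)$ — $2/3$ at $f = 0.8$ — which the test suite confirms
empirically to within a percentage point. Weighted gene sampling
(proportional to screening evidence, `screenGeneWeights()`) and stratified
cell sampling that preserves type proportions and guarantees rare types a
seat in every subset are available behind flags; uniform sampling is the
default.

**A trained combination.** Raw discriminant scores are not probabilities
(they are unbounded and can be negative, so the naive normalization
$\delta_k/\sum_j\delta_j$ is undefined off the positive orthant; the
diagnostic baseline `proportionalProbs()` therefore uses a softmax). Each
member instead gets a small trainable network $g^{(m)}$ mapping its K
scores to class probabilities, and the M preliminary predictions are
combined per class by a weighted vote

$$P(y = k) = \sum_m w_{mk}\, p^{(m)}_k \Big/ \sum_m w_{mk},$$

with $w_{mk}$ the softmax over members of a learned logit matrix, so
weights are positive and sum to one within each class. All networks and
the voting logits are trained jointly on the combined loss

$$\mathcal L = \alpha\, \mathrm{CE}(\text{final}, y)
  + (1-\alpha) \sum_m \mathrm{CE}(p^{(m)}, y),$$

whose second term pushes every member's preliminary output toward the
truth directly — a skip connection from the intermediate outputs to the
loss. $\alpha = 1$ is the conventional final-layer loss; on the package's
4-class fixture it collapses held-out accuracy from about 0.96 to below
0.7, because with only the final cross-entropy the gradient reaching each
individual network is diluted through the voting layer and the members
never learn to emit calibrated probabilities. The default is
$\alpha = 0.5$.

# Preprocessing

`qcFilter()` removes cells with fewer than 200 detected genes and genes
detected in fewer than 3 cells (community-standard defaults; both are
arguments), then drops zero-variance genes. `logNormalize()` applies
counts-per-10,000 log1p normalization per cell (natural log); zeros stay
zero and the transform is invariant to per-cell rescaling.
`screenMarkerGenes()` runs a two-sided one-vs-rest Wilcoxon rank-sum test
per type and gene on the log-normalized values and keeps each type's 400
smallest p-values; the union is the working gene set. One-vs-rest is the
natural contrast because the top list is taken per type. Raw p-values are
ranked without multiplicity adjustment — only the ranking matters, and any
monotone adjustment would leave it unchanged. Ties are broken by the
larger deviation of the rank-sum statistic from its null mean, then by
gene index, so screening is fully deterministic. The vectorized screen is
cross-checked against `stats::wilcox.test` in the test suite. At least
2 cells per type are required, and 20-30 are recommended for stable
selection.

# The networks and their training

Each $g^{(m)}$ is: a fixed affine standardization of the K input scores
(mean/sd computed from the training cells — necessary because
discriminant values can span orders of magnitude, far outside the range
any fixed learning rate could handle), one hidden ReLU layer of
$\max(16, 4K)$ units, and a softmax output. Inputs are only K scores, so
small networks suffice and keep M of them cheap. Gradients are analytic
(derived through the row-normalized vote and the per-column softmax of the
voting logits) and are verified against finite differences in the test
suite.

Training uses minibatch SGD with learning rate 0.01, momentum 0.9, batch
size 64, at most 200 epochs, and early stopping (patience 10) on a 10%
stratified validation split; the best-validation parameters are kept. The
batch size is chosen for references of a few hundred to a few thousand
cells: much larger batches give too few updates per epoch to converge
within the epoch cap. All randomness — initialization, the split, batch
order — is governed by the single `ensembleConfig()` seed, and retraining
with the same seed is bit-reproducible. Per-class voters are the default;
a shared voter ($f_1 = \dots = f_K$) is available via `sharedVoter = TRUE`
but couples all types to one weighting, which is why type-specific voters
are preferred.

Member priors $\pi_k$ are taken from the full reference rather than the
member's subset: subset proportions are noisy estimates of the same
quantity (and identical in expectation under uniform sampling). Members
missing a class entirely are an error — stratified sampling is the remedy
when types are very rare.

# Inference

`predictCells()` aligns query genes to each member's panel by name; genes
absent from the query are imputed as 0, the modal value of log-normalized
scRNA-seq data, which keeps the closed-form scoring intact. If fewer than
half of the ensemble's genes are present the query is rejected with an
overlap report. Raw-count queries are log-normalized with the scale factor
stored at training time. Argmax ties break to the first type in
`labelOrder()`. A saved bundle (`saveEnsembleModel()`) reloads to
bit-identical predictions.

# The synthetic generator

`simulateCounts()` emulates the data regime the annotator targets without
shipping any data: negative-binomial counts (size 2, base mean 1) with a
disjoint block of 30 marker genes per type raised by a natural-log fold
change of 2, independent dropout zeroing at rate 0.3, and imbalanced type
proportions (0.4, 0.3, 0.2, 0.1 for K = 4). The default fixture is 800
cells by 1000 genes and roughly 60% zeros. It reproduces the features
that matter for testing — high dimensionality relative to informative
cells, sparsity, imbalance, and marker structure — but deliberately not
library-size variation, batch effects, doublets, or continuous
trajectories; passing tests therefore demonstrate correctness of the
machinery and robustness to NB-plus-dropout noise, not performance on any
real tissue. Because the generator is NB with dropout, it also does not
satisfy the Gaussian assumption the members make post-normalization;
that mismatch is intentional and part of what the end-to-end tests probe.
`simulateGaussian()` generates data matching the LDA assumptions exactly
(shared identity covariance, shifted means) for the oracle-equivalence
tests where the decision rule must be reproduced exactly.

# Problem sizes used in the tests

The test suite and the acceptance script run the full pipeline on the
800-cell fixture with M = 20 members over 5 seeds (training on 600 cells,
scoring the 200 held-out cells), which finishes in a couple of minutes on
one CPU while leaving the conclusions unchanged relative to larger
swarms: M = 300 remains the default for real use, where member diversity
across tens of thousands of genes needs the larger ensemble. Overlap
diagnostics use M = 300 subsets of n = 1000 cells, matching the analytic
expectation to three digits.

# Worked example

```{r example, eval = FALSE}
sim <- simulateCounts(simConfig(seed = 1))
idx <- sample(ncol(sim$sce))
ref <- idx[1:600]; query <- idx[601:800]

model <- trainPipeline(sim$sce[, ref], sim$labels[ref],
                       minGenesPerCell = 50, M = 20,
                       config = ensembleConfig(seed = 1))
pred <- predictCells(model, sim$sce[, query])
evaluateAnnotation(pred, sim$labels[query])$overallAccuracy
```

# Known limitations

* Types absent from the reference cannot be predicted; query cells of an
  unseen type are necessarily misassigned (and scored as errors by
  `evaluateAnnotation()`).
* Training time grows linearly in M; the pure-R SGD loop is comfortable
  up to a few hundred members and a few thousand reference cells, beyond
  which per-stage parallelism would be the next step.
* A member that never sees a rare type cannot vote for it; with very rare
  types enable `stratify = TRUE`.
* The discriminant is linear per member; strongly non-elliptic class
  boundaries are only captured through the ensemble and the networks.
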