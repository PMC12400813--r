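# scSwarmLDA

Supervised cell-type annotation for single-cell RNA-seq. scSwarmLDA trains
an ensemble ("swarm") of closed-form penalized linear discriminant
analysis (pLDA) models, each on a random subset of the reference's cells
and genes, and combines their discriminant scores through small per-model
prediction networks and a softmax-weighted per-class vote, trained jointly
with a combined cross-entropy loss. It is aimed at analysts who have a
labelled reference dataset and want fast, reproducible annotation of query
cells, including rare types in imbalanced references.

## Method

Each swarm member scores a cell `x` against type `k` with the linear
discriminant

    delta_k(x) = x' S(b)^-1 mu_k - 1/2 mu_k' S(b)^-1 mu_k + log pi_k

where `mu_k` is the class mean, `pi_k` the reference proportion of type
`k`, and `S(b) = (1-b) S + b Tr(S) I / p` the trace-preserving shrinkage
of the pooled ML covariance (a Tikhonov variant `S + b I` is available).
Subsets contain 80% of the cells and `floor(sqrt(p)) + 70` genes, so
members are diverse in gene space (expected pairwise cell overlap
`f/(2-f) = 2/3` at `f = 0.8`). Per member, a small network `g_m` maps the
K scores to probabilities; the final probability of type `k` is
`sum_m w_mk p_mk / sum_m w_mk` with `w_mk` a per-class softmax over
members. Networks and voting logits are trained jointly by SGD on

    L = alpha * CE(final, y) + (1 - alpha) * sum_m CE(p_m, y)

whose second term acts as a skip connection to each member. Preprocessing
is standard: QC filtering, counts-per-10,000 log1p normalization, and
one-vs-rest Wilcoxon rank-sum screening keeping each type's top 400 genes.
See `vignette("plda-swarm-annotation")` for assumptions, defaults and
design choices.

## Worked example

```r
library(scSwarmLDA)

# a labelled synthetic reference: 800 cells x 1000 genes, 4 imbalanced
# types, 30 marker genes per type (natural-log fold change 2), dropout
sim <- simulateCounts(simConfig(seed = 1))

set.seed(1)
idx <- sample(ncol(sim$sce))
ref <- idx[1:600]; query <- idx[601:800]

model <- trainPipeline(sim$sce[, ref], sim$labels[ref],
                       minGenesPerCell = 50, M = 20,
                       config = ensembleConfig(seed = 1))
model
#> EnsembleModel: 20 pLDA members, 4 cell types
#>   classes: type1, type2, type3, type4
#>   alpha = 0.5 ; per-class voters
#>   trained 144 epochs; final val loss 4.112

pred <- predictCells(model, sim$sce[, query])
ev <- evaluateAnnotation(pred, sim$labels[query])
round(c(accuracy = ev$overallAccuracy, macroF1 = ev$macroF1), 3)
#> accuracy  macroF1
#>    0.955    0.931
ev$confusion
#>        predicted
#> truth   type2 type1 type3 type4
#>   type2    60     0     0     0
#>   type1     0    83     0     0
#>   type3     1     0    32     0
#>   type4     2     6     0    16
```

The accuracy is the fraction of held-out cells assigned their true type;
the confusion matrix shows the residual errors concentrate in the rarest
type (type4, 10% of cells), the hard part of imbalanced annotation.

A command-line interface wrapping the same functions ships in
`inst/cli/scswarmlda.R` with subcommands `train`, `predict`, `evaluate`
and `simulate` (10x-style MTX directories or dense CSV in, TSV/JSON out).

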