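---
title: "Gene embeddings from co-expression: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene embeddings from co-expression: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

genevec learns a dense vector per gene from gene co-expression, in direct
analogy to word embeddings: where word2vec reads sentences, genevec reads a
corpus of highly co-expressed gene pairs, each pair acting as a two-token
sentence. This vignette is the package's own account of the models it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## From expression matrices to a pair corpus

Each input dataset is one study's expression matrix (genes x samples).
Preprocessing follows standard microarray practice: log2 transformation of
linear-scale intensities, then quantile normalization
(`preprocess_expression()`, delegated to limma), which forces every
sample's value distribution to the average empirical distribution.
Platforms with several probe sets per gene are collapsed to the probe with
the largest sample variance (`collapse_probes()`); the most variable probe
is the one most likely to carry condition-dependent signal. Variance ties
are broken by lexicographically smallest probe id — the choice is
arbitrary, but determinism under input reordering is not negotiable.

Within one dataset, the co-expression of two genes is the Pearson
correlation of their rows. `coexpr_pairs()` keeps the unordered pairs with
PCC at or above a threshold, 0.9 by default and *inclusive* — a pair at
exactly the threshold survives. PCC is computed with the sample (n-1)
variance convention; any consistent convention cancels in the ratio, but
it is stated so the code has one documented meaning. Genes with zero
variance have undefined PCC and are skipped per dataset (not globally: a
gene flat in one study may vary in another). Pairs from all datasets are
merged by `merge_corpora()`; the multiplicity of a pair is the number of
datasets that selected it, and biological conditions are deliberately
ignored — the corpus is meant to aggregate context across the whole
compendium.

A note on ordering: preprocessing happens before correlation. Whether
correlations should be computed pre- or post-normalization is not obvious;
we follow the stated preprocessing chain (log, quantile normalization,
then PCC) so that the corpus is reproducible from raw intensities alone.

## The skip-gram model and its training surrogate

Let $W \in \mathbb{R}^{d \times k}$ hold one row $v_i$ per vocabulary
gene. The model assigns

$$\Pr(g_j \mid g_i) = \frac{\exp(v_i^\top v_j)}{\sum_{j'} \exp(v_i^\top v_{j'})},$$

and the exact training objective is the negative log-likelihood of the
corpus under this full softmax (`corpus_loss()`). The printed conditional
is ambiguous about which slot is "word" and which "context"; since the
score $v_i^\top v_j$ is symmetric, we treat the model as symmetric and
train *both* directions of every pair — exactly what skip-gram does on a
two-token sentence with window 1.

Full-softmax training is quadratic in the vocabulary and is therefore kept
as a small-vocabulary mode (`method = "exact"`). The production trainer is
skip-gram with negative sampling (`method = "sgns"`, compiled): each
observed (center, context) update contrasts the positive context against
`negative_samples = 5` draws from a unigram$^{0.75}$ noise distribution,
the word2vec defaults. The learning rate decays linearly from 0.025 to
1e-4 across all epochs; the pair sequence is reshuffled every epoch
(changing visit order, never the pair multiset); genes with
multiplicity-weighted frequency below 5 are dropped before training along
with every pair touching them. Frequencies are counted on the full corpus,
so the vocabulary invariant (every retained gene has frequency >= 5) holds
by construction. All randomness — initialization, shuffles, negative draws
— flows from R's RNG, so a single seed makes training bit-reproducible;
training is single-threaded by design, trading speed for exactness of that
contract.

Two further choices in the exact mode deserve a note. First, the loss as
printed in the skip-gram literature sometimes omits the log; we implement
the standard cross-entropy (negative *log*-likelihood) — the quantity that
is additive over pairs and bounded below. Second, plain fixed-step
gradient descent converges too slowly on this ill-conditioned objective,
so the exact trainer uses Barzilai–Borwein step sizes with a backtracking
safeguard; on toy corpora it reaches the same minimum as a generic
quasi-Newton optimizer to well under 1%. The exact mode ties input and
output weights in a single matrix $W$; the negative-sampling mode keeps
separate input/output matrices and exports the input matrix as the
embedding, matching common word2vec practice.

## Clusteredness: the tuning objective

An embedding is good when genes that share function sit close together.
With a pathway collection $Q$ (gene sets of 2–50 genes; larger sets are
diffuse and quadratically expensive) and a background $Q'$ of all pairs
among $n$ randomly sampled genes,

$$\text{clusteredness} =
\frac{\tfrac{1}{|Q|}\sum_{P \in Q}\tfrac{1}{\#\text{pairs in } P}
      \sum_{i,j \in P} v_i^\top v_j}
     {\tfrac{1}{\#\text{pairs in } Q'}\sum_{i,j \in Q'} v_i^\top v_j}.$$

Each pathway is weighted equally (the outer mean is over pathways, not
pairs); pathway genes missing from the vocabulary are dropped per pathway,
and pathways left with fewer than two genes are skipped. The ratio is
invariant under global rotation of the embedding and under global
rescaling (numerator and denominator each scale as $c^2$), but note it is
*not* location-invariant: a common positive drift in all vectors inflates
both terms. If the background mean inner product is within 1e-12 of zero
the statistic is undefined and the function refuses rather than returning
a wild ratio — see the caveat below.

`grid_search()` scans embedding dimension and epoch count. Rather than
training one run per (dimension, epochs) cell, it trains once per
dimension with per-epoch checkpoints and scores every checkpoint — the
epoch axis of the grid is then free. Checkpoints of one run are not
statistically identical to independent runs of different lengths (the
learning-rate schedule is pinned to the full run), but they are equivalent
in expectation for the purpose of locating the best cell at a tenth of the
cost. Ties at the maximum resolve toward smaller dimension, then fewer
epochs — the cheaper model. The background sample's seed is recorded in
the result so a grid is reproducible.

**A caveat worth knowing.** The clusteredness ratio is only comparable
between embeddings with similar global geometry. Negative-sampling
training leaves a sizeable common positive component in all vectors, so
background inner products are comfortably positive and the ratio is
stable. The exact full-softmax objective instead pushes unrelated genes
toward negative inner products; its background mean sits near zero and the
ratio becomes numerically meaningless even when the embedding separates
modules perfectly (which it does — the package tests verify module
recovery for both trainers via within- versus between-module inner
products, a statistic that does not suffer this pathology). Clusteredness
values should therefore only ever be compared across hyperparameters of
the *same* training method.

## The pair-interaction classifier

`positive_pairs()` builds functionally associated pairs as those sharing
an annotation term that is (a) experimentally evidenced (IDA, IMP, IPI,
IGI, TAS), (b) not in a configurable list of over-broad terms (by default
the signal-transduction and phosphorylation terms GO:0007165, GO:0006468,
GO:0046777, GO:0006470), and (c) deeper than level 3 of the hierarchy,
where a term's level is its minimum depth from the root (root = 0).
`negative_pairs()` is stricter than "no shared term": the descendant
closures of the two genes' annotation sets must be disjoint, so a pair
annotated to a term and to that term's child still does not qualify as
negative. The two constructions are mutually exclusive on any input —
sharing a retained term implies overlapping closures.

Negatives are downsampled (seeded) to the number of positives *before*
splitting, so class balance is a property of the dataset, not of each
split. The split itself is gene-disjoint: genes — not pairs — are
partitioned 7:1:2 into train/validation/test, and a pair is retained only
when both endpoints share a group. Pairs spanning groups are discarded
(about half the pairs at these proportions, the price of honest
evaluation): without this, a classifier can score well by memorizing how
promiscuous each gene is rather than learning anything about pairs.

The classifier itself (`ggipnn_train()`) looks up both genes in a shared
embedding matrix, concatenates the two vectors ($2k$ inputs) and applies
fully connected ReLU layers of widths 100, 100 and 10 with dropout 0.5 on
the first two, ending in a 2-unit softmax (equivalent to a sigmoid for a
binary task) trained by mean cross-entropy. The optimizer is Adam at 1e-3
with batches of 256 and early stopping on validation AUC (patience 5) —
conventional defaults, all exposed in `ggipnn_config()`. The embedding
matrix can be pretrained or random, frozen or trainable; in frozen mode it
is bitwise identical before and after training, a contract the tests
assert. The network is implemented directly in vectorized base R: at
these widths a deep-learning framework would add nothing but a
dependency. Evaluation uses the Mann–Whitney formulation of AUC with
midrank ties (`auc_score()`), cross-checked in the tests against both an
$O(n^2)$ pairwise count and an independent ROC package.

The expected ordering of the four regimes on gene-disjoint test pairs —
pretrained-frozen well above chance, pretrained-trainable at or below
pretrained-frozen (fine-tuning desynchronizes train-gene vectors from the
untouched test-gene vectors), random-frozen at chance — is exactly what
the acceptance tests verify on synthetic data.

## The 2-D co-expression map

`reduce_and_map()` centers the embedding, takes up to 50 principal
components (a pure rotation when $k \le 50$, preserving pairwise
distances, which the tests check to 1e-8) and hands the scores to
Barnes–Hut t-SNE (Rtsne, $\theta = 0.5$, single-threaded, seeded;
perplexity 30 and learning rate 200 by default). t-SNE is a delegated
standard algorithm here: the package pins parameters and seeds, it does
not re-derive the method. The iteration default in this package is 1000 —
enough for the few-hundred-gene embeddings of the test suite; maps of
genome-scale vocabularies need one to two orders of magnitude more
iterations to stabilize, and the parameter is exposed for exactly that
reason. t-SNE needs more than `3 * perplexity` points; the error message
states the rule.

Tissue overlays come from `tissue_zscores()`: per gene,
$z_{gt} = (x_{gt} - \bar{x}_{g\cdot}) / s_{g\cdot}$ across tissue means,
with the sample (n-1) standard deviation — the convention is recorded in
the output's attributes since either choice is defensible. Mean expression
is log2(x+1)-transformed first by default (a flag, since the right answer
depends on how the tissue summaries were produced). Genes constant across
tissues have undefined z; they get an all-zero row and are listed in an
attribute so plotting code can grey them out.

## What the simulator emulates, and what it does not

`module_plan()` / `simulate_compendium()` generate the planted-module
compendium that underpins every statistical test in the package. Each
module has one latent factor per sample, $f \sim N(0,1)$; a member gene is
$s f + N(0, \sigma^2)$, giving the closed-form within-module correlation
$\rho = s^2/(s^2 + \sigma^2)$ that makes analytic checks possible.
Background genes are pure noise with marginal variance matched to module
genes ($s^2 + \sigma^2$), so no variance filter can separate them — only
correlation structure can. The defaults are 200 genes, four modules of 40,
three datasets of 100 samples, $s = 1$ and $\sigma = 1/\sqrt{24}$, i.e.
$\rho = 0.96$: strong planted signal safely above the 0.9 pair threshold,
with 100 samples giving tight enough correlation estimates that module
membership, not sampling noise, determines which pairs survive. Each
dataset draws from its own stream, seeded as `seed * 1000 + dataset`, so
the compendium is reproducible per dataset and as a whole.
`modules_to_pathways()` and `modules_to_annotations()` re-express the
planted truth in the formats the tuning and classification modules
consume (the synthetic ontology hangs every module term at level 5 below
a four-term chain, so the level filter is exercised but never fires).

The simulator deliberately omits everything that makes real compendia
hard: batch and platform effects, intensity saturation, probe
cross-hybridization, heavy-tailed expression, overlapping pathways,
annotation noise and incompleteness, and the scale of real corpora (a
thousand studies, tens of thousands of genes, millions of pairs). Passing
tests on this fixture demonstrate that the implementation is correct and
that the method behaves as designed when its assumptions hold; they say
nothing about how strong real co-expression signal is. Reference results
on real compendia (clusteredness around 1.5, pair-classification AUC
around 0.72) depend on specific database releases and are out of desk
scale by design.

## Numerical choices and degenerate inputs

* Softmax computations subtract the row maximum before exponentiation;
  probabilities are exact to machine precision, never clipped.
* The clusteredness denominator is refused within 1e-12 of zero rather
  than returning an unstable ratio.
* Probe-collapse ties: lexicographic probe id. Grid ties: smaller
  dimension, then fewer epochs. AUC ties: midrank.
* Zero-variance expression rows are excluded from correlation with a
  warning; constant tissue rows yield zero z-scores and a flag.
* An empty vocabulary after frequency filtering, an out-of-vocabulary
  gene in a corpus or pair list, a single-class AUC evaluation, a cyclic
  term hierarchy, and an annotated term with no hierarchy level are all
  hard errors that name the offending object.
* A gene split group with zero genes is an error; a group that retains no
  pairs is a warning (the 10-gene worked example in the tests hits this
  legitimately).

## Problem sizes used by the test suite

The suite runs the full chain — simulation, corpus extraction, embedding
(k = 50, 5 epochs), clusteredness, grid search (dims 10 and 20, 8
epochs), classifier regimes (20 epochs, 5 seeds each) and the t-SNE map
(120–200 points, a few hundred iterations) — in well under two minutes on
one core. These sizes are the package's chosen desk-scale study
conditions: large enough that every statistical claim (module recovery,
chance-level random baselines, regime ordering) is measured rather than
assumed, small enough to run everywhere.

## Known limitations

* Clusteredness comparisons across training objectives are unreliable
  (see the caveat above); the statistic is a tuning objective, not an
  absolute quality measure.
* Negative-sampling training is deterministic only in single-threaded
  mode; there is no multi-worker mode in this implementation.
* The annotation reader expects flat TSV extractions (records plus
  parent/child edges); it does not parse ontology releases directly.
* The exact trainer is quadratic in vocabulary size and is intended for
  vocabularies of at most a few hundred genes.
* HDF5 input support depends on the optional rhdf5 package; TSV is the
  primary dialect.
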