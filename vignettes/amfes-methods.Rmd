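---
title: "Adaptive SVM gene selection, kernel mutual information and network synergy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive SVM gene selection, kernel mutual information and network synergy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amfes)
```

This vignette is the package's account of what it computes and why the
defaults are what they are. The package has three parts: an adaptive
SVM-based gene ranking and selection scheme for labeled expression
matrices; Gaussian-kernel mutual-information (MI) matrices over gene pairs
with per-condition contrast statistics; and a network-pharmacology synergy
score for pairs of agent gene sets on a background interaction network.

## The selection protocol

### Ranking by objective drop

A binary soft-margin SVM is trained on a gene subset (genes standardized to
mean 0, variance 1 using training-component statistics only — without a
common scale, objective changes are not comparable across genes). Writing
the trained dual solution as coefficients $\alpha_i y_i$ on support vectors
$v_1,\dots,v_s$, the importance of gene $g$ is the magnitude of the change
in the dual objective when coordinate $g$ is deleted from the support
vectors *at fixed coefficients* — no retraining. For the linear kernel this
is exactly $\tfrac12 w_g^2$, the familiar recursive-feature-elimination
criterion, which is the package's test oracle. At fixed coefficients the
dual value can only increase when a coordinate is dropped, so the absolute
change is used as a nonnegative ranking weight.

One stage of ranking over $k$ genes draws random subsets of size
$\lfloor k/2\rfloor$, trains one SVM per subset, and scores each gene by
the mean of its weights over the subsets that contained it. Subsets are
added one at a time, starting from `m_min = 10`, until the score vector
$\theta_m$ stabilizes:
$\lVert\theta_{m-1}-\theta_m\rVert^2 / \lVert\theta_{m-1}\rVert^2 < 0.01$,
with a hard cap `m_max = 200` (a non-converged stage is used with a
warning, not an error). The vectorwise norm-of-difference reading is the
stricter of the two readings the stopping rule admits, and it is the one
the Euclidean-norm phrasing supports. With `m_min = 10` half-size draws,
the chance a gene is never sampled is $2^{-10}$ per gene; any such
stragglers score 0 with a warning rather than dividing by zero.

Ranking is recursive halving: all $k$ genes are scored and sorted, then
only the top $\lceil k/2\rceil$ are re-ranked while the bottom half keeps
its order below them, until at most three genes remain. The ceiling
convention keeps the re-ranked set at least as large as the frozen set for
odd $k$, while subset sizes use $\lfloor k/2\rfloor$. Ties are broken by
the incoming order, making every ranking a deterministic permutation of
its input.

### Probe genes and the gene-index

Selection needs a null reference for "how high would an uninformative gene
rank?". The package appends one *artificial probe* per original gene: by
default a label-independent within-gene permutation of that gene's values,
which preserves the marginal distribution exactly while destroying any
class association (Gaussian probes matching each gene's moments are a
config alternative). After ranking originals and probes together, each
original gene's **gene-index** is the fraction of probes ranked strictly
above it (strictly: a tie with a probe does not count as "above", the
conservative reading). Candidate subsets live on the grid
$p_i = i \times 0.005$, $i = 1..200$: $B(p_i)$ holds the originals with
index $\le p_i$, so candidates are nested and $B(1)$ is everything.

### Accuracy curve and stopping rule

Samples are split 5:1 into training subset $S$ and test subset $T$
(stratified; test size `round(n/6)`, largest-remainder allocation across
classes so an 11-sample class still appears on both sides). From $S$,
$r = \max(5, \mathrm{int}(500/n + 0.5))$ stratified 4:1
training-validation pairs are drawn. Each pair ranks its own
probe-augmented training component and scores all 200 candidates on its
validation component; curves are averaged into $av(p_i)$, and the baseline
$v_{baseline}$ is the all-gene validation accuracy averaged over the same
pairs (symmetry with $av$; the alternative — one baseline on all of $S$ —
would compare quantities measured on different sample splits). The chosen
$p^*$ is the first grid point with $av(p_k) \ge v_{baseline}$ and
$av(p_k) \ge av(p_l)$ for $l$ in the look-ahead window $k..k{+}10$,
clipped at the grid end so "first $k$" semantics survive near $p = 1$. If
nothing qualifies, the full set is returned with an explicit fallback
flag — by construction its accuracy is the baseline. Empty candidates at
small $p$ are skipped in evaluation and treated as $-\infty$ in selection.

Because each pair has its own $B(p^*)$, the final subset is made unique by
re-ranking on *all* of $S$ with fresh probes (dedicated seed stream) and
keeping the originals with index $\le p^*$. Test accuracy on $T$ is
reported for the selected genes and, for reference, for the all-gene
model. In the degenerate case where the final ranking leaves $B(p^*)$
empty, the full gene set is used and flagged.

Multi-class problems run as an ordered list of binary tasks (e.g. class 1
versus the rest, then class 2 versus class 3 on the remaining samples);
per-task selections are merged as a duplicate-free union with the raw sum
and duplicate count reported.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `kernel`, `cost` | linear, 1.0 | SVM kernel and soft-margin constant; the linear kernel makes the objective-drop weight exact and fast |
| `m_min`, `m_max` | 10, 200 | subset budget per ranking stage |
| `conv_tol` | 0.01 | relative-change stopping threshold for $\theta_m$ |
| `artificial_method` | permute | probe construction |
| `lookahead` | 10 | stopping-rule window on the $p$-grid |
| `test_frac` | 1/6 | held-out test fraction (5:1) |

A master seed spawns labeled sub-streams (split, pairs, per-pair probes
and draws, final ranking), so any component is independently replayable
and the whole run is deterministic in (data, config, seed).

## Kernel mutual information

For two expression vectors of length $M$ the package uses the Gaussian
kernel plug-in estimator: substitute kernel density estimates with a
shared bandwidth $h$ into $I(X,Y)=\iint f(x,y)\log\frac{f(x,y)}{f(x)f(y)}$,
giving the double-sum form
$$\hat I = \frac1M \sum_w \log
  \frac{M\,\sum_u e^{-\frac{1}{2h^2}\left[(x_w-x_u)^2+(y_w-y_u)^2\right]}}
  {\sum_u e^{-\frac{(x_w-x_u)^2}{2h^2}} \sum_u e^{-\frac{(y_w-y_u)^2}{2h^2}}}.$$
Normalization constants cancel in the ratio. A constant coordinate gives
exactly 0 (the joint kernel factorizes), and the estimate is symmetric in
its arguments by construction. Plug-in estimates are biased and **can be
negative**; negative entries are reported, never clipped — with the
rule-of-thumb bandwidth the bias on independent data is a small positive
offset ($\approx +0.04$ nat at $M = 1000$), while wide bandwidths
(oversmoothing) push independent pairs below zero, which is how negative
minima arise in published MI tables.

The matrix routine applies the two classic loop-nest optimizations: each
gene's $M\times M$ kernel values and its marginal kernel sums are computed
once, up front, so a sample-pair kernel distance is evaluated once per
gene rather than once per gene pair. The optimized matrix is tested to
agree with the naive double loop to $10^{-10}$; in exact arithmetic they
are identical.

Genes are standardized per condition before kernel evaluation — a single
$h$ across genes is only meaningful on a common scale — and `h = "auto"`
is the Silverman-style rule $1.06\,M^{-1/5}$ on the standardized values
(for a pair, $1.06\,\bar s\,M^{-1/5}$ with $\bar s$ the pooled sd). Every
matrix records the bandwidth it used. Against the bivariate-Gaussian
closed form $-\tfrac12\ln(1-\rho^2)$ the auto-bandwidth estimator is
within $\pm 0.05$ nat at $M = 1000$ over $\rho \in \{0, 0.5, 0.9\}$ and
monotone in $|\rho|$.

Condition statistics (mean, sd, strictly positive and strictly negative
counts, min, max) run over **all** $N\times N$ entries including the
diagonal — published contrast tables of this kind have positive + negative
counts summing to $N^2$, which forces the diagonal in — and exact zeros
count in neither sign. The sign-difference count between two conditions
compares $\mathrm{sign}\in\{-1,0,+1\}$ positionally and refuses matrices
whose gene order differs rather than silently realigning.

## Target-network synergy

Agent gene sets live on a shared background network. Node importance (IP)
integrates betweenness, closeness (undirected, normalized; isolated nodes
scored 0) and PageRank (damping 0.85 — the standard choice, configurable)
by z-scoring the three columns and projecting on the first principal
component. Two conventions make this well-defined: the eigenvector sign is
fixed so the closeness loading is nonnegative (falling back to
betweenness, then PageRank), and scores are shifted by
$-\min + 10^{-6}$ so all IP weights are strictly positive — the topology
score is an IP-weighted average and needs positive weights. A centrality
that is constant up to floating-point noise (regular graphs) is mapped to
zeros rather than z-scored into amplified noise.

The topology score of sets $A_1, A_2$ is
$$TS = \frac12\left[
 \frac{\sum_i IP_{1i}\, e^{-\min_j d(i,j)}}{\sum_i IP_{1i}} +
 \frac{\sum_j IP_{2j}\, e^{-\min_i d(j,i)}}{\sum_j IP_{2j}}\right],$$
with $d$ the unweighted shortest-path distance on the joint network
(computing distances per-agent-subgraph instead would discard the
background connectivity the score is meant to capture). A shared gene is
at distance 0; a gene with no path contributes $e^{-\infty}=0$. Hence
$TS \in (0, 1]$ for connected sets, $TS = 1$ exactly when every gene of
each set touches the other set, and $TS$ shrinks as cross-set distances
grow. The agent score is $AS = \sum_{i,j} P_{ij}/M$ over a user-supplied
phenotype-similarity matrix (a cosine helper is provided for feature
vectors; building $P$ from a phenotype database is out of scope), and the
synergy score is the product $SS = TS \times AS$, so scaling $AS$ scales
$SS$ linearly. Pairs are ranked by $SS$ descending with name-based tie
breaks.

## What the synthetic generators do and do not emulate

The planted-signal generator produces independent Gaussian noise genes
plus a random subset of informative genes whose class-B mean is shifted by
`effect_size` noise-sds — the simplest structure a margin-based selector
must detect, and the one under which recovery statements are made:
200 genes, 8 informative, 30 + 30 samples, effect 2, unit noise. It does
**not** model probe effects, batch effects, gene-gene correlation, heavy
tails or class imbalance, so passing recovery tests demonstrates the
machinery works under its stated assumptions, not that selections on real
microarray data are biologically correct. The correlated-pair generator
(bivariate normal, unit variances) exists because it is the one
dependence structure with a closed-form MI. The toy-network generator
(Erdős–Rényi plus two random agent sets) exercises the score algebra, not
realistic interactome topology.

## Numerical conventions and degenerate inputs

- Grid inclusion `index <= p` is tested with a $10^{-12}$ slack so ratios
  like $1/5$ compare sanely against $40 \times 0.005$.
- Zero-variance genes: an SVM view keeps them (scale factor 1; they get
  zero weight), an all-zero-variance view is an error; in MI they are
  centered only, flagged, and have MI 0 against everything; the automatic
  bandwidth refuses constant vectors.
- Missing values are a load-time error; duplicate gene ids are rejected
  naming the duplicates; label files are joined by sample id, never by
  row order.
- SVM training is deterministic given data and parameters; weights are
  invariant to sample order and to permuting the other genes only up to
  the solver's termination tolerance ($\sim 10^{-3}$ relative), which is
  what the tests assert.
- MI write/read round trips preserve 12+ significant digits (`%.17g`).

## Problem sizes

The shipped verification suite uses: 50 random 20-gene × 30-sample
instances for the MI oracle equivalence; 20 seeds × $M = 1000$ per
correlation for the Gaussian closed form; 100 random small SVM instances
for the weight oracle; 1000 random curves for the stopping rule; and 10
seeded end-to-end runs at 200 genes × 60 samples for planted-gene
recovery. These sizes were chosen as the smallest at which each property
is statistically unambiguous.

## Known limitations

- Published biomarker counts from specific microarray accessions are not
  reproduced: they depend on external data, unspecified kernel and
  regularization settings, an unspecified MI bandwidth, and unseeded
  randomization in the original analyses. The package instead pins every
  such free choice, documents it, and verifies the algorithmic properties
  that *are* checkable.
- The objective-drop interpretation is exact for linear kernels; for
  radial kernels the weight is still computed from the fixed-coefficient
  dual but has no closed-form primal reading.
- The probe-based gene-index calibrates relevance against marginal
  permutations; correlated noise genes can still ride on true signal.
- Kernel MI values depend on $h$; only comparisons made at the same
  recorded bandwidth are meaningful.
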