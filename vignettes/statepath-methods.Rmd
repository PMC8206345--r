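---
title: "Inferring cell states and transitions from time-series transcriptomes"
author: "statepath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell states and transitions from time-series transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statepath)
```

## The problem

A time course of bulk or averaged single-cell transcriptomes — a synchronised
cell cycle, a developmental or perturbation response, or cell types averaged
along a differentiation trajectory — carries information about the hidden
cellular states the system passes through. Genes that realise one state share
a temporal activation pattern, so the states appear as clusters of gene
expression profiles and the transitions as the temporal order of those
clusters. `statepath` infers both from the expression matrix alone: no marker
genes, no prior number of states, no cell-type annotation. Inputs are a genes
× (time points × replicates) matrix with an explicit numeric time grid;
outputs are a selected number of clusters, a Gaussian-process (GP) summary
per cluster, and a directed path over the clusters whose edges can be
annotated with biological pathways shared across a transition.

## Model and procedure

### Preprocessing

Expression values are log-transformed (`log(x + 1)` by default; the offset is
configurable and log-scale input can be flagged) and z-scored per gene across
all time points and replicates jointly. Joint z-scoring, rather than
per-time-point scaling, is used because clustering compares temporal
*shapes*; a gene's amplitude should not dominate. Zero-variance genes become
all-zero rows and are flagged, not dropped — callers can filter
deterministically. Normalization happens before replicate averaging so the
replicate-level profiles used by the GP likelihood are on the normalized
scale; the transform is recorded and exactly invertible
(`inverseNormalize()`). Genes with zero or missing values in more than a
configurable number of time points (default 4) can be removed with
`dropSparseGenes()`. An optional functional-PCA step (`functionalPCA()`)
computes modes of variation as the eigenvectors of the time-grid sample
covariance — a discretized functional PCA on the observed grid; no smoothing
basis is imposed.

### Cluster number by a likelihood gap statistic

For each candidate k the genes are clustered (k-means with 10 restarts, or
Ward agglomerative) on their replicate-averaged profiles. The classic gap
statistic compares the log within-cluster sum of squares of the observed
data against its expectation under B structureless reference draws, each
feature sampled uniformly over its observed range. `statepath` additionally
implements a GP variant: each cluster is summarised by a GP regression over
all member profiles, and the dispersion is the summed log marginal
likelihood of the members under their cluster's process,
$$W_k^{GP} = \sum_{r=1}^{k} \sum_{x \in C_r} \log P(x \mid \hat\mu_r, C_r),
\qquad C_r = K_r + (\sigma^N_r)^2 I.$$
A larger value means tighter clusters. The gap is
$Gap^{GP}(k) = W_k^{GP,obs} - E^*[W_k^{GP,ref}]$, with the reference data
re-clustered and re-fitted by the identical pipeline. Two definitional
choices deserve note:

* **No outer logarithm.** The textbook gap takes `log` of the dispersion,
  but a summed log-likelihood is typically negative, so the logged form is
  undefined; the difference of likelihoods is used instead
  (monotone-equivalent wherever the log exists). The literal form is
  available via `literalLog = TRUE` and errors on non-positive dispersion.
* **Member-likelihood covariance.** The density of a member profile is
  evaluated at the GP posterior mean with covariance equal to the posterior
  covariance of the latent process at the observed times plus the fitted
  white-noise variance — i.e. the cluster's fitted confidence band. With the
  *prior* RBF kernel in its place (available via `covariance = "prior"`)
  the density barely responds to smooth residuals, because a unit-amplitude
  smooth kernel explains any smooth deviation cheaply; in experiments the
  merged version of two genuinely distinct states then scored higher than
  the correct split even when the clustering itself was correct. The
  posterior form penalises members outside a tight band and clusters that
  need a wide band, which is the behaviour the likelihood gap needs.

k is selected as the smallest candidate whose gap is within one reference
standard error of the global maximum (`gapCriterion = "se-max"`). A bare
argmax is also provided, but the likelihood gap plateaus beyond the true k —
splitting a coherent cluster rarely lowers the summed likelihood — so an
argmax rides reference sampling noise to the top of the k range; the
one-SE-of-the-maximum rule is the standard guard. The k-vs-(k+1) SE rule
(`"tibshirani-se"`) is included as well. Ties in the argmax break towards
the smallest k (parsimony).

### Per-cluster Gaussian processes

The kernel over time is RBF plus white noise,
$K(t_i,t_j) = \exp(-\|t_i/l - t_j/l\|^2/2) + [t_i\!=\!t_j]\,(\sigma^N)^2$.
In fitting, the white term is applied as $\sigma^2 I$ on the training
diagonal — observations from different genes at the same time point share
the time-equality of the kernel definition but not a noise draw. The length
scale is box-constrained to $[10^{-3}\,t_{max},\ t_{max}]$ (a nominal lower
bound of zero is degenerate, hence the small floor) and the noise sd to
$[10^{-5}, 10]$, which brackets unit variance on z-scored data. Both are
chosen by maximising the joint log marginal likelihood with L-BFGS-B from 5
seeded random restarts (analytic gradients).

Because every profile in a cluster is observed on the same time grid, the
joint covariance over all points has the structure
$K = \mathbf{1}_{G\times G} \otimes R + \sigma^2 I$, whose eigenstructure
splits into the replicated-mean direction and $G-1$ pure-noise directions.
The likelihood therefore costs $O(N_t^3 + G N_t)$ instead of
$O((G N_t)^3)$; the identity is verified against a dense-Cholesky oracle in
the test suite, and a dense path handles genuinely scattered (time, value)
input. Posterior means and standard deviations are evaluated on the
interpolation grid — all multiples of the interpolation step (default 1
time unit) spanning the observed range, united with the observed points —
so unobserved times are summarised too.

### Ordering clusters: shape-based distance and ranked pairs

For every unordered pair of clusters the shape-based distance is computed
between their GP mean curves on the interpolation grid:
$SBD(a,b) = 1 - \max_w CC_w(\mu_a,\mu_b)/\sqrt{CC_0(\mu_a,\mu_a)\,
CC_0(\mu_b,\mu_b)}$, sliding over every integer shift
$w \in [1-m, m-1]$ with zero padding. A negative optimal shift means the
first cluster precedes the second; zero is a tie. Exact ties in the maximal
correlation break towards the smallest |w|, then the negative shift. The
cross-correlation is computed directly in $O(m^2)$ — grid lengths are at
most a few hundred, so an FFT buys nothing.

Pairwise precedences are merged into one order by the ranked-pairs
(Tideman) election: victories are sorted by strength, locked into a
directed graph in turn, and any victory that would close a cycle is
skipped; the locked graph's topological order is the state sequence. The
strength of a victory is taken as $1 - SBD$ — a more similar pair with a
decisive shift is stronger evidence of adjacency; strength ties break by
larger |w| first, then lexicographic cluster ids, and remaining topological
ambiguity breaks towards the smaller cluster id, making the whole order
deterministic. Zero-shift pairs abstain rather than voting an arbitrary
direction; if every pair abstains there is no ordering signal and the
caller is told so.

The result is a simple path — exactly $k-1$ edges. Branching topologies are
out of scope by design; nodes carry the GP mean with a 95% band
($\hat\mu \pm 1.96\,\hat\sigma$) for rendering.

### Pathway tests

Cluster-level filtering and edge annotation both use the hypergeometric
upper tail $P(X \ge c)$ with the gene universe set to the analysed matrix's
genes (not the genome): the clustered set is the population the draws come
from. Pathway genes outside the universe are ignored; genes in no pathway
still count in the universe. `filterClusters()` keeps clusters with tail
p ≤ a user threshold (0.1 is a practical default for pathway-of-interest
filtering). An edge between adjacent clusters is annotated with pathway p
when the union of the two clusters is enriched while neither cluster alone
is — union tail ≤ 0.05 < min of the single tails — and the pathway has more
than 10 genes in the universe. The asymmetric ≤/< reading follows the
criterion as stated; raw 0.05 is used with no multiple-testing correction
for fidelity to the original procedure (a Benjamini–Hochberg layer can be
applied downstream by the caller if desired).

## Synthetic data

`simulateTimeSeries()` plants k clusters as noisy copies of one smooth base
curve (GP draw, sinusoid, Gaussian impulse, or logistic activation),
temporally shifted per cluster so that the shift order *is* the
ground-truth state sequence, with optional planted pathway memberships.
Three presets mirror common study designs: a 5-point averaged pseudo-time
series (3 states × 120 genes), a 17-point 10-minute cyclic series (5 phase
clusters of 31/81/44/31/34 genes, sinusoids over two periods), and an
uneven 8-point developmental series at 0, 6, 12, 24, 36, 48, 72, 96 hours
(3 states × 544 genes, sequential logistic activations). The default noise
sd of 0.3 on the z scale was chosen once as a realistic signal-to-noise for
post-filter expression data. For the cyclic preset the temporal order is
well defined only up to rotation of the cycle — phase-shifted sinusoids
wrap — which is a property of cyclic biology, not of the estimator.

What the generator does *not* emulate: count noise (negative binomial
dispersion, dropout), gene-specific amplitude and baseline heterogeneity,
correlated noise across genes, or batch structure. Passing tests on these
fixtures therefore demonstrate correctness of the algorithms under their
own model assumptions, not performance on raw sequencing data.

## Numerical and testing choices

* All randomness (k-means restarts, reference draws, GP restarts,
  simulation) flows from a single integer seed through derived child
  streams; identical seeds give bit-identical scans and fixtures.
* Degenerate inputs: a constant cluster fits a flat GP (not an error);
  zero-norm mean curves are rejected by the SBD with a clear message;
  duplicated times with a zero noise floor raise an error advising a noise
  floor; k equal to the gene count assigns singletons directly.
* Reference draws in the gap scan are refitted per draw (hyperparameters
  are not reused from the observed fit), keeping the comparison
  self-consistent; a k exceeding the gene count is skipped with a warning.
* Test problem sizes — tens of genes per cluster, 5–17 time points, B of
  6–10 reference draws, 10–20 seeds per recovery experiment — were chosen
  so the whole suite exercises every recovery claim at meaningful power
  while remaining quick on a laptop.

## Limitations

The output topology is a path; branching differentiation is not modelled.
The likelihood is Gaussian, appropriate for log-scale normalized
expression; raw counts would need a negative-binomial observation model.
Cyclic processes are ordered up to rotation. The two-group edge test
inherits the usual caveats of enrichment analysis: it conditions on the
chosen universe, and raw per-pathway thresholds are deliberately
uncorrected.

## A worked run

```{r example, eval = FALSE}
sim <- simulateTimeSeries(scrnaLikeSpec(seed = 7))
tse <- logZNormalize(sim$tse, alreadyLog = TRUE)
scan <- gapScan(tse, kRange = c(1, 8), B = 10, mode = "gp", seed = 7)
kOpt(scan)
net <- buildClusterNetwork(tse, clusterLabels(scan),
                           geneSets = sim$geneSets, seed = 7)
clusterOrder(net)
plotClusterFits(net)
```
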