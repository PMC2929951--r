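---
title: "Methods: linking physico-chemical features to pathway activity and toxicity"
author: "pcflink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking physico-chemical features to pathway activity and toxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Quantitative structure-activity (QSAR) models predict a toxicity endpoint
directly from a chemical's physico-chemical features (PCFs); expression
profiling predicts the same endpoint from the molecular response of the
exposed tissue. `pcflink` implements a strategy that connects the two layers:
it asks which *pathways'* transcriptional activity can be explained by small
combinations of descriptors, which pathways distinguish toxic from non-toxic
exposures, whether those two pathway sets sit close together on a pathway
overlap map, and whether the descriptors selected through the transcriptional
layer are better toxicity predictors than descriptors chosen without it.

The intended data shape is a repeat-dose toxicogenomics study: a panel of
compounds, each with a few treated replicates and a matched control group,
binary toxicity annotation per compound, a gene-set collection standing in for
a pathway database, and a compounds-by-descriptors table of precomputed PCFs.
Expression is assumed pre-processed and on a log scale; no normalization is
performed in this package.

# Pathway activity indices

For every gene set with **more than five** member genes present in the
expression matrix, the samples-by-genes submatrix is mean-centered per gene
and decomposed with `stats::prcomp`. Components are retained until the
cumulative variance fraction reaches the target (default 0.8), capped at two
components dataset-wide; when two components fall short for a specific
pathway the cap still applies and the pathway is recorded in `belowTarget`
with a warning. Genes are **centered but not unit-scaled** by default:
centering-only is the default of the underlying PCA routine and preserves
amplitude information; a `scale` flag exposes the alternative. Sign
indeterminacy is resolved by forcing each component's largest-magnitude gene
loading to be positive, which makes downstream regression targets
reproducible. Genes belonging to several pathways contribute to each of them.

# Hotelling T2 statistics

Both perturbation and differential testing use the two-sample Hotelling
statistic on the retained component scores,

$$T^2 = \frac{nm}{n+m}\, d' S^{-1} d, \qquad
F = T^2\,\frac{n+m-p-1}{p\,(n+m-2)} \sim F(p,\; n+m-p-1),$$

with $d$ the mean difference and $S$ the pooled covariance. A singular pooled
covariance is ridge-regularized with $\lambda = 10^{-8}\,\mathrm{tr}(S)/p$ and
flagged — with three replicates per group near-singular covariances are a
real possibility and the ridge keeps the statistic continuous in that regime,
unlike a pseudo-inverse.

The **perturbation index** of a drug on a pathway is the T2 of its treated
replicate scores against its matched control group's scores. Drugs are then
clustered on 1 − Pearson correlation between perturbation profiles (average
linkage); correlation is used because the interesting structure is the shape
of the profile across pathways, not its magnitude, and it is
config-overridable. A constant profile makes correlation undefined, in which
case the clustering falls back to Euclidean distance with a warning.

The **differential test** compares toxic against non-toxic exposures on the
retained components, Benjamini–Hochberg adjusted across pathways with
selection at q < 0.01. The unit of analysis is the **compound**: each
compound's treated replicate scores are averaged before the test. Pooling raw
replicates as if they were independent exposures is anti-conservative
whenever pathway activity varies at the compound level — replicates of one
compound share that compound's latent activity, so the within-class variance
is underestimated (pseudoreplication) and null pathways are selected in
excess of the nominal FDR. The compound-level test is calibrated; the test
suite checks this on null synthetic data. Control samples do not enter this
test.

# Eq.1 interaction regressions and the GA search

The link between descriptors and a pathway component is the three-descriptor
interaction regression

$$PC_{ik} = a + b D_1 + c D_2 + d D_3 + e D_1 D_2 + f D_1 D_3 + g D_2 D_3 +
\varepsilon,$$

fit by ordinary least squares. The regression target for a pathway is the
per-compound mean of treated replicate scores on the second component, which
carries the toxicity-linked signal (the first component is dominated by
non-specific effects). Model search runs a genetic algorithm over
chromosomes of three descriptor indices: tournament selection of size two,
uniform crossover, per-gene point mutation (rate 1/3), elitism, with
compounds split 2/3 training / 1/3 test and fitness equal to the 5-fold
cross-validated $R^2$ inside the training split. The fold assignment is drawn
once per search so that fitness values are comparable across triples and can
be cached; the untouched test split provides a second, reported $R^2$.
The model population keeps the best model of each independent GA run
(deduplicated, best instance kept); a pathway is flagged **PCF-linked** when
at least one model reaches the fitness threshold of 0.5 *and* validates
externally, i.e. its R² on the untouched test split is non-negative. The
external check matters: with ~27 training compounds, the maximum
cross-validated R² over the thousands of triples a search visits crosses 0.5
by chance for a substantial fraction of null pathways, whereas chance models
essentially never generalize to held-out compounds — rejecting models with
negative external R² is standard QSAR validation practice and is what keeps
the flag specific. The threshold of 0.5 was chosen because reported models
of this kind cluster just above it; both it and the external bound are
exposed in the configuration. A constant target defines $R^2 = 0$ so GA
fitness stays totally ordered; collinear triples receive fitness $-\infty$.

GA sizes are a tunable trade-off: the demo configuration uses 6 runs with a
population of 24 over 40 generations per pathway, which on instances small
enough to enumerate matches exhaustive search almost always (this equivalence
is tested); much larger run counts buy little on 60-descriptor panels while
multiplying runtime.

The `interactionShare` diagnostic refits the model with and without the
three product terms and reports the share of explained sum-of-squares lost,
clipped to [0, 1]. The descriptor-group network summarizes flagged pathways:
the weight of edge $(g_1, g_2)$ counts pathways with at least one passing
model pairing a $g_1$ with a $g_2$ descriptor in an interaction term.

# The pathway map and the association test

Pathway similarity is the Jaccard index of member overlap, by default
computed after restricting sets to the genes present in the expression data.
Average-linkage clustering of $1 - J$ gives the map; its faithfulness is
verified by the cophenetic correlation between tree-implied and input
distances.

The association between the PCF-linked and the toxicity-linked pathway sets
is assessed with a statistic of our own construction (the underlying
question — "do the two sets sit close together on the map?" — does not come
with a canonical test): the observed mean cophenetic distance over all
cross-pairs, against a null that redraws both label sets as uniform leaf
subsets of the same sizes. $p = (1 + \#\{\mathrm{null} \le \mathrm{obs}\}) /
(n_{perm} + 1)$, so the resolution is $1/(n_{perm}+1)$; the two sets may
overlap. The output records that this construction is package-defined.

# Toxicity classification from descriptor subsets

`splitFeatures` partitions descriptors into the subset appearing in passing
Eq.1 models ("linked") and the subset of remaining descriptors whose absolute
Pearson correlation with every linked descriptor stays below 0.5
("uncorrelated"); descriptors correlated with the linked set belong to
neither. Each subset is searched by the same GA machinery with chromosomes
of three features and fitness equal to stratified 5-fold cross-validated
accuracy of a maximum-likelihood Gaussian discriminant (class means, pooled
covariance, equal priors by default — the panel is imbalanced, and equal
priors match the classic discriminant rule; empirical priors are a flag).
One best model per run forms the accuracy distribution, and the accuracy
reported for a selected model is re-estimated under a second, independent
fold assignment — the selection fitness is a maximum over the many
chromosomes a search visits and is therefore optimistic enough that
pure-noise feature subsets can appear to rival informative ones; decoupling
selection from reporting removes most of that winner's-curse bias, in the
same spirit as the regression stage's held-out test split. The
two distributions are compared with a two-sided Mann–Whitney test (again a
package choice, documented as such). The representative model refits the
discriminant on the three most frequently selected features (ties broken by
the mean fitness of models containing the feature) and reports stratified
cross-validated sensitivity, specificity and confusion counts, plus compound
coordinates on the leading principal components of those features.

# The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which the pipeline's claims are checked.

* **Gene sets** are organized in blocks: sets in a block share a common core
  (half the minimum set size by default) and blocks use disjoint gene pools,
  so within-block Jaccard overlap is substantial and across-block overlap is
  exactly zero — the overlap structure that makes the pathway map non-trivial.
* **Expression**: treated samples of compound $c$ follow
  $x_{gs} = \mu_g + l_{1g} f_1(c) + l_{2g} f_{2k}(c) + N(0, \sigma)$, matched
  controls are $\mu_g + N(0, \sigma)$ (latent factors zero, so the
  perturbation index is a signal-to-noise readout). $f_1$ is a compound-level
  non-specific (dose-like) factor, sd 3; $f_{2k}$ is the pathway's specific
  factor. The planted differential pathways share a common toxicity factor
  $t_c = \mathrm{effect} \cdot \mathbf{1}[\mathrm{toxic}] + N(0,1)$; all
  other pathways receive independent standard-normal factors. Because the
  dose factor has the larger variance, pathway PCA puts it on PC1 and the
  specific signal on PC2 — the geometry the downstream analyses presume.
  Every gene carries one loading pair ($|l| \sim U(0.7, 1.2)$, random sign);
  the specific factor loads only on genes unique to a set, while shared
  backbone genes respond to dose alone. This keeps pathway-specific signals
  independent across sets; two earlier designs (summing loading
  contributions across sets; letting shared genes follow a single owner
  set's factor) respectively made the PC1/PC2 split unstable across seeds
  and correlated the null pathways' PC2 targets within blocks.
* **Descriptors**: for each linked pathway, $D_1$ and $D_2$ are drawn around
  shared latent family components ($D = \rho u + \sqrt{1-\rho^2}\,v$,
  $\rho = 0.85$) — real descriptor panels are heavily inter-correlated
  within families, and this correlation is also what lets the downstream
  $|r| \ge 0.5$ rule recognize causal descriptors that were not themselves
  selected in a model. Coefficients are drawn with a dominant $D_1 D_2$
  interaction against main effects of 0.1–0.3, and $D_3$ is solved from the
  factor identity after injecting noise with variance
  $(1-\mathrm{linkStrength})\,var(f_2)$, so the true triple explains exactly
  the requested variance fraction. The interaction weight $|e|$ balances two
  requirements that pull in opposite directions — interaction terms must
  carry at least half of the explained sum-of-squares, while the *linear*
  discriminant downstream can only use the marginal (non-product)
  information the descriptors retain — and its default range was chosen by
  measuring both properties jointly under the default conditions. The
  remaining two interaction coefficients are planted at zero: solving for
  $D_3$ with nonzero $f, g$ would put $D_1, D_2$ in the denominator and blow
  up near its roots. All other descriptors are independent noise; columns
  are shuffled and assigned round-robin to named descriptor groups.
* **Default demo conditions**: 40 compounds (25% toxic) with 3 treated
  replicates and 3 matched controls each; 60 sets in 6 blocks of 10;
  nDifferential = 10 — exactly the first block, so signal leakage through
  shared block cores stays inside the planted set; 8 of those are
  descriptor-linked; effect size 3 at unit residual and unit gene noise;
  60 descriptors in 12 groups at linkStrength 0.9. Gaussian factors and
  noise are an explicit modelling choice; the generator does not attempt
  realistic microarray noise (dye bias, probe effects, heavy tails), so
  passing recovery tests demonstrates correctness of the statistical
  machinery under its stated model, not performance on real arrays.

# Numerical choices and degenerate inputs

Zero-variance pathway submatrices are excluded with reason "degenerate"
rather than raising; per-cell perturbation failures yield NA plus a log
entry, never an aborted matrix. Ridge fallbacks (T2 and the discriminant) use
$\lambda = 10^{-8}\,\mathrm{tr}(S)/p$. BH adjustment is a validated wrapper
over `stats::p.adjust`. All randomness is scoped: every stochastic operation
takes a seed, saves and restores the global RNG state, and pipeline stages
derive per-stage seeds from the global seed and the stage name, so one stage
can be re-run bit-identically without disturbing the others. Problem sizes
in the demo configuration (and the GA sizes above) were chosen so the whole
pipeline runs in a couple of minutes on one CPU; they are stated in
`defaultConfig()` and changeable.

# Known limitations

* The association statistic, the subset-comparison test and the
  representative-model selection rule are minimal formalizations of analyses
  that are usually argued visually; alternatives (e.g. cluster-membership
  counts, permutation of compound labels upstream) are not implemented.
* The compound-level differential test discards within-compound replicate
  information beyond the mean; a mixed model would use it, at the cost of a
  different test family.
* Only two-class toxicity is supported end-to-end; the discriminant itself
  accepts more classes.
* Eq.1 is the only model family: no regularization, no higher-order
  interactions, no nonlinear components.

# A worked run

```{r demo}
library(pcflink)
res <- runAll(defaultConfig(), "demo_run")
resultTable(res$differential)        # per-pathway T2 / q-values
qsprSummary(res$populations, res$descriptors)
res$classifier$comparison            # linked vs uncorrelated accuracy
```
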