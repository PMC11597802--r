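---
title: "Methods: screening, dose-response and co-expression in stresscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, dose-response and co-expression in stresscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresscreen)
```

stresscreen implements a complete screening-to-network workflow for
abiotic-stress tolerance studies in crop varieties: multi-criteria variety
ranking from growth and physiological indicators, lethal-concentration
estimation from mortality counts, selection of the most informative
sampling time, and a weighted co-expression analysis that links gene
modules and hub genes to physiology. This vignette explains each model,
its assumptions, the tunable parameters, and the design choices made
where the methodology is genuinely open.

## Relative indicators

All screening operates on *relative indicators*: the ratio of a
measurement under stress to the same measurement in the paired control,

$$x_{ij} = \frac{\text{treatment}_{ij}}{\text{control}_{ij}}.$$

Dividing by the control removes constitutive between-variety differences
(a tall variety is not "more tolerant" merely for being tall), leaving
the proportional stress response. `relative_values()` requires strictly
positive control values and averages replicates before taking the ratio
(mean-then-ratio); the alternative ratio-then-mean weights replicates by
their control magnitudes, and with three replicate plants per arm the two
differ negligibly. Entities with missing values are dropped with a
warning rather than imputed, since a ranking over partially observed
criteria is not comparable.

The composite growth metrics follow the usual field definitions:
growth rate $(h_{10}-h_1)/h_1$ and biomass accumulation
$fw_{10}-fw_1$. The growth-rate denominator is the *initial* height; a
`denominator = "final"` switch covers the convention that divides by the
final height instead.

## Grey relational analysis with CRITIC weighting

Grey relational analysis (GRA) scores each variety by its closeness to an
ideal reference series. After orientation-aware min-max normalisation
(`orient_normalize()`; larger-is-better columns map max to 1,
smaller-is-better columns are reflected so 1 is always desirable), the
ideal reference is the all-ones series and the deviation of variety $i$
on indicator $k$ is $\Delta_i(k) = |1 - x_i(k)|$. The Deng relational
coefficient is

$$\xi_i(k) = \frac{\Delta_{\min} + \rho\,\Delta_{\max}}
                  {\Delta_i(k) + \rho\,\Delta_{\max}},$$

with $\Delta_{\min},\Delta_{\max}$ taken globally over the whole matrix
(the standard two-level min/max). The distinguishing coefficient $\rho$
(default 0.5, the near-universal convention) controls contrast: as
$\rho \to 0$ off-ideal cells collapse towards 0, and at $\rho = 1$ the
worst attainable coefficient is 1/2. With $\Delta_{\min} = 0$ the worst
cell scores exactly $\rho/(1+\rho)$ — 1/3 at the default.

The relational degree is the weighted mean
$\gamma_i = \sum_k w_k \xi_i(k)$. Weights are either uniform or objective
CRITIC weights,

$$C_j = \sigma_j \sum_k (1 - r_{jk}), \qquad w_j = C_j / \sum_j C_j,$$

where $\sigma_j$ is the sample (n−1) standard deviation of the
normalised column and $r_{jk}$ the plain (not absolute) Pearson
correlation, as in the original CRITIC formulation: an indicator is
informative when it varies a lot *and* disagrees with the others. A
constant indicator carries no information and gets weight 0.

Because the two weighting schemes can disagree, `grey_rank()` reports the
squared Pearson correlation between the unweighted and weighted degree
vectors as an agreement gate (default threshold $R^2 \ge 0.9$): above the
gate either ranking tells the same story; below it both rankings should
inform any decision.

### Key-time-point selection

To choose a sampling time for sequencing, `select_key_timepoint()` takes
one (unweighted, weighted) degree pair per time point and returns the
time with the largest absolute divergence — the point where objective
weighting carries the most discriminating information. Ties go to the
earliest time point, with a warning. How a single degree pair per day is
obtained from a varieties × indicators panel is not canonical; the
pipeline treats the *time points* as GRA entities, with criteria equal to
the relative physiological indicators averaged over the contrasted
varieties, run once unweighted and once CRITIC-weighted. One consequence
worth knowing: when stress deepens monotonically, the final day tends to
be worst on *every* indicator, so all its coefficients sit at the
$\rho/(1+\rho)$ floor and weighting cannot matter there — under this
summary the divergence criterion highlights early-to-mid time points in
our simulations. The per-day summary is therefore exposed rather than
hard-wired.

## Log-logistic LC50 and tolerance classes

Mortality counts at stressor concentration $c$ follow a two-parameter
log-logistic dose-response

$$p(c) = \frac{1}{1 + (e/c)^b},$$

with $p(0) = 0$: the lower asymptote is fixed at 0 (no control
mortality) and the upper at 1. $e$ is the LC50 in concentration units —
$p(e) = 0.5$ holds exactly by construction — and $b$ is the slope on the
log-concentration scale. `fit_log_logistic()` maximises the binomial
likelihood of dead-of-cohort counts, pooling replicates within a variety
(one LC50 per variety), over $(\log b, \log e)$; this is preferable to
least squares on proportions because it weights concentrations by the
information they carry. The model is exactly logistic regression on
$\log c$, which the test suite uses as an independent oracle. Zero
concentration rows are excluded; all-zero or all-dead outcomes at every
positive dose leave the LC50 unidentifiable and raise an error. The Wald
standard error of $\log e$ comes from the inverse Hessian. The default
fitting day is the last recorded day, where cumulative mortality carries
the full dose-response.

Per-variety LC50 values are grouped into tolerance classes by
**exact one-dimensional k-means** (`classify_kmeans_1d()`): the optimal
1-D clusters are contiguous in sorted order, so a dynamic program over
contiguous partitions finds the global within-sum-of-squares optimum with
no random initialisation and no seed sensitivity. Classes are named
`tolerant`, `moderate`, `sensitive` by descending centre at the default
$k = 3$.

## Weighted co-expression network

The network stage follows the standard weighted gene co-expression
recipe, with every step exposed as its own function.

**Filtering and QC.** `filter_genes()` drops genes whose mean (or,
optionally, max) FPKM falls below a floor (default 2; the boundary is
kept). `sample_qc()` clusters samples by average linkage on Euclidean
distance of standardised expression, reports the pairwise correlation
matrix and the first two principal components, and flags samples that
merge into the tree above a height quantile as candidate outliers.

**Soft threshold.** `pick_soft_threshold()` scans integer powers
$\beta$ (default 1–20) of the unsigned adjacency
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ and computes a scale-free fit
index per power: connectivity $k_i = \sum_{j \ne i} a_{ij}$ is binned
into ten equal-width bins and $\log_{10}(\text{frequency})$ is regressed
on $\log_{10}(\text{mean } k)$; the index is the regression $R^2$, made
negative when the slope is positive (a scale-free degree distribution
must decay). The chosen power is the smallest reaching the plateau
target (default 0.85); if none does, the argmax is returned with a
warning flag. Equal-width bins are essential here: equal-count bins
would make the bin frequency constant by construction and the index
meaningless.

The scan is reported, but the pipeline builds its network at a fixed
conventional power (default $\beta = 6$ for unsigned networks,
configurable, including `beta = "scan"` to adopt the scan choice). With
a planted-module design and only 16 samples, the fit index reaches its
plateau only at sharp powers (13–20) that crush moderate within-module
correlations and degrade module recovery, while module detection is
excellent at the conventional power — the same tension practitioners
resolve with sample-size-based default powers when a scan is
inconclusive.

**Topological overlap.** `tom_similarity()` converts adjacency to

$$\omega_{ij} = \frac{\ell_{ij} + a_{ij}}
                     {\min(k_i, k_j) + 1 - a_{ij}},
  \qquad \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},$$

which credits both the direct connection and the shared neighbourhood,
and is bounded in [0, 1] with unit diagonal. An isolated pair with
weight $a$ has $\omega = a$; a complete unweighted triangle has
$\omega = 1$.

**Modules.** `detect_modules()` clusters genes by average linkage on the
TOM dissimilarity $1 - \omega$ and cuts the tree statically at an
absolute dissimilarity height (default 0.95). Unrelated genes overlap
near 0 and merge just below dissimilarity 1, so branches that stay
together below the cut share substantial overlap; a cut defined as a
fraction of the merge-height *range* was considered and rejected because
with a single coherent module it necessarily slices inside the module's
own structure. Clusters smaller than `min_size` (default 30) are
relabelled `grey` (unassigned), and surviving modules take the
conventional colour names in decreasing size order. Dynamic tree cutting
and eigengene-based module merging are out of scope; the static cut is
exposed in the configuration.

**Eigengenes and traits.** The module eigengene is the first right
singular vector of the module's per-gene standardised expression — the
single sample profile explaining the most module variance — with its
sign fixed so the mean correlation with member genes is non-negative,
and the leading squared singular value over the total as variance
explained. `module_trait_correlation()` reports Pearson $r$ between each
eigengene and each physiological trait with the exact two-sided p-value
from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom.

**DEG partition.** `venn_partition()` computes the exact seven-region
partition of three differentially-expressed-gene lists, including the
pairwise-intersection-minus-third regions used to call variety-specific
stress-responsive genes.

## Hub genes and the Mantel linkage

`intramodular_hubs()` ranks a module's genes by degree on a thresholded
within-module similarity graph: edges are pairs at or above the
`edge_quantile` quantile (default 0.95) of within-module off-diagonal
similarities; ties break by summed edge weight, then gene id, making the
ranking total and input-order invariant. The top five by degree are the
module's hub genes by default. `hub_network()` then connects hub genes
across modules at an absolute-correlation threshold (default 0.8),
reporting edges and degrees.

`mantel_test()` links hub expression to physiology: with sample-level
distance matrices from hub-gene FPKM and from trait values (Euclidean on
standardised columns by default; $1 - |\mathrm{cor}|$ optional), the
Mantel statistic is the Pearson correlation of the strict upper
triangles, and the one-sided p-value comes from jointly permuting the
rows and columns of the second matrix:
$p = (1 + \#\{r_\text{perm} \ge r_\text{obs}\})/(1 + n_\text{perm})$.
The observed arrangement contributes the +1, so a sampled identity
permutation is redrawn rather than counted twice; the smallest attainable
p is exactly $1/(n_\text{perm}+1)$.

## Simulated study conditions

The simulators generate data with the statistical structure every
downstream stage assumes, so the whole pipeline is testable without any
download, and they define the default study conditions.

* **Indicator panels** (`simulate_indicator_panel()`): 15 varieties with
  latent tolerance scores on an even grid in [0, 1]; treatment =
  control × $(1 \mp 0.4\,(1-\text{score}))$ with the sign set by
  orientation (stress depresses growth indicators and elevates stress
  markers, more so in sensitive varieties), times multiplicative
  log-normal noise (sd 0.02, a tight assay). The latent ordering is
  returned for recovery tests.
* **Mortality** (`simulate_mortality()`): three replicates of fifty
  plants per variety at 0/100/200/300 mM, observed on days 5–20.
  Final-day deaths are Binomial$(50, p(c))$ under each variety's true
  log-logistic curve, so final-day proportions follow the dose-response
  exactly; each dead plant's death day is uniform over the observation
  days (a linearly accumulating hazard), making within-replicate
  cumulative deaths non-decreasing. Default true LC50s span 200–325 mM
  with slope 6, the range a screening panel of contrasting varieties
  shows.
* **Expression** (`simulate_expression()`): 4 groups × 4 replicates
  (two varieties × control/stress), three planted modules of 50 genes
  plus 100 background genes. Module drivers are orthogonal group
  contrasts plus replicate noise — orthogonality keeps planted modules
  distinct, since random group effects in a 4-dimensional group space
  frequently collide and merge two modules; beyond the contrast space
  extra drivers are unconstrained. Genes are
  $\text{loading} \times \text{driver} + \text{noise}$ on the log scale
  (loadings 0.7–1 with random sign, noise sd 0.3), background genes pure
  noise, and FPKM support comes from exponentiating around per-gene
  baselines in $[\log 5, \log 200]$, which preserves the correlation
  structure. Each physiological trait is its module's driver plus noise
  (sd 0.2), so eigengene-trait correlations are planted by construction.

What the simulators do **not** emulate: count noise and
mean-variance structure of real RNA-seq, batch effects, correlated
background genes, non-monotone dose-responses, or censoring in the
mortality course. Passing tests therefore demonstrate the correctness
and calibration of the *methods* under their stated assumptions, not
performance on any particular real data set.

All generators are pure functions of their configuration: one master
seed per call, with per-variety/gene/replicate sub-streams derived
deterministically from it, so repeated calls are byte-identical.

## Numerical choices and problem sizes

Tolerances and degenerate-input rules worth knowing: CRITIC weights sum
to 1 within 1e−12; a constant normalised column warns and maps to 1 (GRA)
or weight 0 (CRITIC); the LL2 optimiser starts from a logit-linear
interpolation and runs BFGS to `reltol` 1e−12, flagging non-convergence;
k-means ties in the ranking of equal LC50s resolve by variety name;
module detection with no cluster at `min_size` warns and returns all
grey; Mantel requires at least 4 entities and exact symmetry.

The default simulated problem sizes — 250 genes × 16 samples, 15
varieties, 999 permutations — keep a full pipeline run around a second
while leaving every statistical property measurable; all are
configuration keys, and the same code runs unchanged at
transcriptome scale (the TOM is dense, so memory grows with the square
of the gene count; block-wise processing for very large matrices is a
non-goal).

## Orchestration

`run_pipeline()` executes the enabled stages in dependency order from a
single validated configuration (`pipeline_config()`, or a flat YAML file
via `read_pipeline_config()`). Validation is pre-flight and exhaustive:
unknown keys or out-of-range parameters fail before any stage runs. All
randomness derives from the one global seed via fixed per-stage
sub-seeds, recorded in the run report; with `out_dir` set, every stage
artifact is written as plain CSV/JSON so each stage is independently
re-runnable, and identical configurations yield byte-identical outputs.
This R package exposes the workflow as composable functions rather than
a shell tool; the pipeline runner plus the configuration file schema
play the orchestration role.
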