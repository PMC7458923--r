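---
title: "Chemical signatures of syntopic land iguanas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical signatures of syntopic land iguanas: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Femoral glands of land iguanas exude a waxy secretion whose lipophilic
compounds are candidate semiochemicals — molecules that could let
individuals recognize conspecifics and so act as a precopulatory
reproductive isolating mechanism between species that live side by side.
`iguanachem` implements the statistical workflow for asking whether
GC–MS secretion profiles separate two syntopic Galápagos land iguana
species, *Conolophus marthae* (pink) and *C. subcristatus* (yellow):

1. per-individual chemical diversity and group richness summaries;
2. Bray–Curtis dissimilarity, nMDS and principal-coordinate ordination;
3. a PERMDISP-style homogeneity-of-dispersion screen with Tukey HSD
   pairwise comparisons;
4. PERMANOVA with sequential sums of squares and permutations restricted
   within sampling years;
5. SIMPER decomposition with permutation significance, the cross-season
   consistent-marker intersection, and a PCA reduction of the markers;
6. a repeated stratified random-forest protocol that tallies the top
   compound by Gini importance over many randomized splits.

The input data model is a samples × compounds matrix of **percent
relative abundances** (each profile closes to 100) with per-sample
factors `species`, `sex`, `year`, `season`. Because proportions, not
percentages, enter several formulas, `p_i = value / 100` is derived
where needed; entropy and Bray–Curtis are invariant to this scaling.

## The synthetic data generator

The original field data are not publicly deposited, so the package ships
a generator whose **defaults are the study conditions**: 227 samples in
the 11 non-empty year × species × sex design cells (24/54/31/41 in 2012,
15/15/13/17 in 2014, 3/5/–/9 in 2015; 2015 *subcristatus* females were
never sampled), 113 compounds, reproductive season in 2012/2014 and
non-reproductive in 2015.

Per sample $s$ in design cell $g$ and compound $i$ the latent intensity is

$$ y_{si} = z_{si}\,\exp\big(m_i + \beta_i(g) + \varepsilon_{si}\big),
\qquad \varepsilon_{si} \sim N(0, \sigma^2),\quad
z_{si} \sim \mathrm{Bernoulli}(\pi_i), $$

after which the row is closed to percent. Choices, made once:

* **Baseline log-intensity** $m_i \sim N(0, 1.5^2)$ — a ~4.5-fold
  interquartile spread of typical compound intensities, matching the
  strongly uneven abundance distributions of secretion chromatograms.
* **Presence probability** $\pi_i \sim \mathrm{Beta}(5, 2)$ (mean 0.71),
  giving the sparse presence/absence texture of the real tables; planted
  markers are fixed at $\pi = 0.95$ so that effects act mainly through
  abundance, not occupancy.
* **Planted effects**: 7 species-marker compounds at log-effect
  $\delta_{sp} = 2$ (the two species' latent means differ by a factor
  $e^2 \approx 7.4$, signs alternating across markers so each species has
  characteristic compounds), 3 sex markers and 5 year-shifted compounds
  at $\delta = 1$. Seven species markers mirror the seven molecules the
  field study found consistently separating the species.
* **Noise** $\sigma = 1$ — lognormal with ~68% of replicate intensities
  within a factor *e*.

Effects act on the log scale *before* closure, so a planted shift leaks
into every compound's relative abundance (compositional closure), which
is exactly the constraint real percent data impose on SIMPER and the
forest. The random stream does not depend on the effect sizes, so specs
differing only in $\delta$ share common random numbers — used by the
monotonicity tests (larger $\delta_{sp}$ must increase between-species
dissimilarity). `null_spec()` zeroes every effect, making all group
labels exchangeable by construction; this is the substrate for the
type-I-error calibrations.

What the generator does **not** emulate: chromatographic artifacts,
retention-time drift, detection-limit censoring, year-specific compound
loss (the real data had 111/96/94 compounds across years; a
`year_presence_shift` knob exists but is 0 by default), and correlated
compound families. Passing tests therefore demonstrate correctness of
the statistical machinery under a plausible compositional model, not
fidelity to any particular field dataset.

## Diversity

Chemical richness $R_{chem}$ counts compounds positive in at least one
sample of a group. Chemical diversity per individual is
$H_{chem} = -\sum_i p_i \ln p_i$ (natural log; $0\ln 0 = 0$). Group
summaries report the mean and *sample* (n − 1) standard deviation of
$H_{chem}$; a single-sample cell reports `NA` for the SD. Values are
rounded to 2 decimals only in printed summaries; full precision is kept
internally.

## Dissimilarity and ordination

Bray–Curtis, $d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$, is
computed on the percent values with no further transformation (no square
root, no double standardization). On rows closed to 100 this equals the
Manhattan distance / 200 — an identity the tests exploit as an internal
cross-check. Bray–Curtis is a semi-metric: its PCoA has negative
eigenvalues, which the package keeps as separate "imaginary" axes rather
than discarding.

PCoA is classical scaling: $G = -\frac12 J D^{(2)} J$, eigendecomposed;
real axes are eigenvectors scaled by $\sqrt\lambda$; variance explained
is reported over the positive eigenvalues only.

nMDS minimizes Kruskal stress-1 by iterative majorization: each
iteration fits disparities by isotonic regression (pool-adjacent
violators) of configuration distances on the rank order of the input
dissimilarities — ties handled by the primary (weak) treatment,
pre-sorting tied inputs by current configuration distance — and then
applies a Guttman transform. An iteration is accepted only if stress
decreases, so the reported stress sequence is non-increasing by
construction; iteration stops when the improvement falls below `tol`.
Defaults: `k = 3` (profiles are plotted on X–Y–Z axes), 20 starts (one
PCoA-seeded, the rest random Gaussian), `tol = 1e-7`, `max_iter = 300`.
On perfectly Euclidean-embeddable input the PCoA start already has
stress ≈ 0.

## Dispersion homogeneity and PERMANOVA

`permdisp()` follows the PERMDISP2 idea: embed by PCoA keeping both axis
sets, and correct each squared centroid distance by subtracting the
imaginary-part contribution,
$z^2 = \|x^{re}-c^{re}\|^2 - \|x^{im}-c^{im}\|^2$, clamping rare
negative values at 0 with a warning. A one-way ANOVA F on the distances
tests equality of dispersions, and `tukey_hsd_dispersion()` reports the
fraction of group pairs *not* significantly different — the screen used
to justify proceeding to PERMANOVA.

`permanova()` partitions the total sum of squared dissimilarities
($\sum_{i<j} d_{ij}^2 / n$) over an ordered term list via
$ss_k = \mathrm{tr}(H_k G) - \mathrm{tr}(H_{k-1} G)$ (sequential /
Type I SS, so term order matters and is user-supplied). Pseudo-F uses
the full-model residual. p-values come from permuting whole samples,
restricted within `strata` levels (default `"year"`, reflecting the
"three sampling years, each with four treatments" design), with the +1
correction so p can never be 0. Permuted F values tying the observed one
(within square-root machine epsilon) count as exceedances, which keeps
sampled p-values consistent with exhaustive enumeration on tiny designs.

Two design points deserve note:

* **Aliased columns.** The empty 2015 *subcristatus*-female cell makes
  the categorical-year three-way interaction rank deficient. Rather than
  refusing the model, partially aliased columns are dropped in order
  (reducing the term's df) with a warning, as `lm()` does; only a term
  losing *all* its columns is an error. This is required for the study's
  own design to be analyzable.
* **Year coding.** Published tables for designs like this sometimes show
  df = 1 for a three-level year factor, implying numeric coding. Both
  codings are supported (`year_numeric`); categorical is the default and
  neither is asserted correct.

## SIMPER, consistent markers, PCA

For every between-group pair, compound $i$ contributes
$|x_{ij} - x_{ik}| / \sum_i (x_{ij} + x_{ik})$; averaging over pairs
decomposes the mean between-group Bray–Curtis exactly (conservation is
asserted to 1e-10 in the tests). Significance per compound is a
one-sided (greater) permutation test on group labels — the question is
"does this compound contribute more than chance", and the common
practice in the field is one-sided. The Bonferroni flag divides 0.05 by
the **total** number of identified compounds in the table (the 113-style
divisor), not the number tested.

`consistent_markers()` intersects the compounds significant at
`alpha = 0.01` in *every* season; both the raw-p screen and the
Bonferroni flags are reported because the two thresholds select
different subsets. `pca_select()` then reduces the marker submatrix:
correlation-mode PCA by default (abundances span scales; covariance mode
is a flag), retaining components while cumulative variance stays within
75% (always at least one), and naming the compound with the largest
absolute PC1 loading.

One ambiguity is resolved by assumption: SIMPER runs pool males and
females within each season, since the field analysis described only a
species contrast per year.

## The random-forest stability protocol

The contribution here is the *protocol*, not the tree learner — the
forests themselves are fitted with `randomForest` (bootstrap per tree,
`mtry` candidate variables per node, Gini impurity, majority voting).
Per run: a class-stratified split (half-up rounding per class, so
116/111 at 0.5 gives 58 + 56 training), a 500-tree forest with
`mtry = 17` (the study's tuned values; `rf_tune()` reproduces the tuning
by out-of-bag error over a grid, ties toward smaller `mtry` then fewer
trees), test-set confusion with accuracy, Cohen's κ, sensitivity,
specificity and an exact Clopper–Pearson 95% CI on accuracy, and the
top-1 compound by mean decrease in Gini (ties broken lexicographically
with a warning). Across runs: a frequency table of top compounds; a χ²
uniformity test over the $k$ compounds observed as top at least once
($E = n_{runs}/k$, df $= k-1$ — mirroring a reported df of 10 for 11
observed compounds); means of per-run metrics (averaged CI bounds are
means of per-run bounds, matching "average output" reporting); and a
ROC/AUC from the pooled test-set vote fractions (per-run AUC averaging
is available via `pooled_roc = FALSE`). Child seeds derive
deterministically from one master seed, so the whole protocol is
bit-reproducible.

Cohen's κ uses $(p_o - p_e)/(1 - p_e)$; with fully concentrated margins
($p_e = 1$) it is defined as 1 for perfect agreement and 0 otherwise,
with a warning. AUC by the trapezoidal rule equals the Mann–Whitney
statistic divided by $n_1 n_0$, which the tests assert against
`wilcox.test`.

## Numerical choices and degenerate inputs

* All-zero profiles are errors everywhere (they have no composition);
  missing cells in input files are zeros (compound absent) with a
  logged count.
* Permutation p-values always carry the +1 correction.
* PCoA eigenvalues within `1e-9` of 0 (relative) are treated as null.
* `permdisp` excludes size-1 groups with a warning; a fully degenerate
  configuration (all centroid distances equal) is flagged rather than
  tested.
* Compound identity is the `compound_id` token; ChemID and class are
  annotations (distinct compounds can share names across classes).

## Problem sizes

The shipped analysis scripts and the acceptance script run at desk
scale, chosen as the sizes a reviewer can re-run on a laptop while
keeping every Monte-Carlo interval tight enough to be meaningful: 999
permutations for PERMANOVA/SIMPER (the study-scale 9,999 is a single
argument away and is used in `analysis/04_permanova.R`), 100
random-forest runs (study scale 1,000), 500 null datasets × 199
permutations for the type-I calibration, and 200 replicates for the
dispersion calibration. None of the package defaults depend on these
script-level choices.

## Known limitations

* Bray–Curtis only; other indices were not needed and are out of scope.
* SIMPER is the plain two-group decomposition — no dissimilarity-ratio
  ranking, no crossed designs.
* The PERMANOVA is Type I (sequential) only; Type II/III partitions are
  not implemented.
* Synthetic calibration shows correctness of the machinery, not
  recovery of any published effect size: the field data are not
  available, so published table values are not reproduction targets.
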