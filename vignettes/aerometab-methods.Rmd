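---
title: "Methods: two-factor metabolomics analysis with aerometab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-factor metabolomics analysis with aerometab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The study design aerometab targets

aerometab analyzes targeted metabolomics panels from a two-factor animal
study: rat lines artificially selected for high (HCR) or low (LCR) intrinsic
treadmill running capacity, profiled young (Y) and old (O) in serum,
gastrocnemius muscle, and white adipose tissue (WAT). The canonical design
is unbalanced — 34 animals in cells HCR-Y 10, LCR-Y 10, HCR-O 6, LCR-O 8 —
with panels of 89 (serum) and 71 (muscle, WAT) metabolites and a maximal
running speed (m/min) per animal. Every stage works on any dataset with the
same structure: a samples-by-metabolites positive abundance matrix, a
two-level capacity factor, a two-level age factor, and optionally a
continuous speed covariate.

# Transformation and scaling

Raw targeted-panel abundances are positive and right-skewed. Each
metabolite is transformed with a Box-Cox power
$(x^\lambda - 1)/\lambda$ ($\ln x$ at $\lambda = 0$), with $\lambda$ chosen
on a grid from $-2$ to $2$ in steps of $0.1$. The acceptance band for a
candidate $\lambda$ is $|\mathrm{skew}| < 2$ and $|\mathrm{kurtosis}| < 2$
computed on the residuals of the saturated cell-means model (one mean per
capacity-by-age cell), so group-mean differences never masquerade as
non-normality. Among candidates inside the band the selector minimizes
$|\mathrm{skew}| + |\mathrm{kurtosis}|/2$; kurtosis is down-weighted because
its sampling error at $n = 34$ is roughly twice that of skewness. If no
$\lambda$ satisfies the band the global minimizer is kept and the metabolite
is flagged infeasible. Ties break toward $\lambda$ closest to 1 (the "no
transformation" point), then toward the smaller $\lambda$, making the
selection deterministic.

Numerical conventions that matter at this sample size:

* skewness and excess kurtosis use the bias-corrected (type-2) estimators,
  so a Normal sample has expectation 0 for both;
* the cell-means (saturated) residual model is used rather than the
  additive one — with both mains and an interaction under study, only the
  saturated model leaves residuals free of any design signal;
* nonpositive values receive a shift of $|\min| +$ half the smallest
  positive value before transforming, recorded in the transform-spec table;
* constant metabolites are flagged degenerate and excluded with a warning.

After transformation, every column is mean-centered and divided by its
sample standard deviation (unit-variance scaling, denominator $n-1$).
Centering is included because the PLS stage requires it; UV scaling puts
all metabolites on equal footing regardless of abundance range.

A caveat worth stating plainly: with 34 samples, $\lambda$ is only weakly
identified. On log-normal data with log-scale SDs in the 0.3–0.8 range the
selected $\lambda$ has a median at 0 but substantial spread (roughly half
the selections fall within $\pm 0.25$); even a profile-likelihood estimator
has comparable spread at this $n$. The monotonicity of the Box-Cox family
means downstream rank-based behavior is unaffected, and the residual-moment
band still guards against grossly wrong choices.

# PLS-DA: algorithm, validation, VIP

Group separation is assessed by partial least squares against a coded class
response. The default response is the four-class one-hot matrix over
HCR-Y/LCR-Y/HCR-O/LCR-O (column-centered); two-class capacity-only and
age-only responses and a centered/scaled running-speed response are also
available, since published score plots of such studies are sometimes built
either way.

The fit is Wold's NIPALS (PLS2, regression mode) with X-deflation per
component. The inner loop is run in its compact fixed-point form on the
cross-product matrix $X^\top Y$ — the iterate sequence is identical to the
classic four-step NIPALS cycle but each iteration costs $O(JM)$ instead of
$O(nJ)$ — to convergence $10^{-10}$ in the weight vector or 500 iterations.
Initialization is deterministic (the response column with the largest
variance), and each weight vector's largest-magnitude element is made
positive, so fits are reproducible to the byte. Two components are fitted
by default, matching the two-axis score plots standard in the field.

$Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}$ is estimated by stratified 7-fold
cross-validation with a venetian-blinds (interleaved) assignment inside
each class; centering and scaling of X and centering of Y are re-estimated
inside every training split and applied to the held-out block, and SS is
taken about the training means. Stratification keeps all four classes in
every training split; a split that loses a class is an error, not a silent
degradation.

Model validity is established by a label-permutation test, G = 200
permutations per model by default. Each permutation re-fits and
re-cross-validates on row-permuted Y; the permutation p-value uses the
add-one estimator $(1 + \#\{Q^2_{perm} \ge Q^2_{obs}\})/(G+1)$, which can
never be zero. The $R^2$/$Q^2$ intercepts are taken from least-squares
lines through the G permuted points (x = mean absolute column-wise
correlation between permuted and original response) plus the observed point
at similarity 1 — the conventional permutation-plot construction. A
negative $Q^2$ intercept indicates a model that is not overfit.

Variable importance in projection is
$\mathrm{VIP}_j = \sqrt{J \sum_a \mathrm{SSY}_a (w_{ja}/\|w_a\|)^2 /
\sum_a \mathrm{SSY}_a}$ with $\mathrm{SSY}_a$ the response sum of squares
explained by component $a$; mean squared VIP is 1 by construction, so
VIP $\ge 1$ means "above-average contributor".

# Univariate models

Per metabolite, the group model is OLS of the transformed, scaled
abundance on capacity + age + capacity×age with treatment dummies
(reference LCR, Young): `beta_capacity` is the HCR effect among the young,
`beta_age` the old effect among LCR, `beta_interaction` the extra old-HCR
effect. The "combined impact" p-value is the 3-df partial F of the whole
factor block against the intercept-only model; per-term p-values are also
reported because the Venn attribution below needs them. All metabolites
share one design matrix, so the suite is computed from a single QR
decomposition, vectorized across metabolites.

The speed model regresses running speed on the design block (age, capacity,
their interaction) plus the metabolite block (metabolite, metabolite×age,
metabolite×capacity, metabolite×age×capacity); its screening p-value is
the 4-df partial F of the metabolite block against the design-only model.
The metabolite enters uncentered; because the block is tested jointly
against a model containing all design terms, centering would not change the
joint F. Singular fits (e.g. a metabolite constant inside a cell) yield a
flagged row with missing statistics rather than aborting the tissue.
Speed-association p-values are BH-FDR-adjusted within each tissue — the
tissues are separate families, matching how such panels are reported.

# Selection, Venn partition, arrows

A metabolite is influential when VIP $\ge 1$ (four-class PLS-DA) **and**
joint p $< 0.05$ (group model). Both boundaries follow the stated
convention exactly: VIP uses $\ge$, p uses strict $<$.

Selected metabolites are then attributed to Venn regions by which of the
three per-term p-values (capacity, age, interaction — same fitted model)
fall below 0.05; a selected metabolite with no individual term below the
threshold goes to an explicit `joint_only` bucket so the partition is total
and disjoint. Direction arrows are the signs of the qualifying
coefficients, ordered capacity, age, interaction: "up" means higher with
HCR (capacity arrow) or higher with old age (age arrow). This per-term
attribution is the most direct tabular reading of the Venn-diagram figures
such studies print; the attribution rule is a design choice of this
package, recorded here because published figure captions do not specify
one.

# Pathway over-representation

Enrichment of the selected set is the one-sided hypergeometric
(Fisher-exact upper-tail) test per pathway, against a user-supplied GMT
library. The background universe defaults to the tissue's measured panel —
for a targeted panel of 71–89 compounds, the panel, not a full pathway
database compound space, is the correct reference population. Pathway
member sets are intersected with the universe before testing; BH-FDR is
applied across tested pathways. Pathway-topology/impact scoring is out of
scope, as is any bundled pathway database: pathway content is the user's
responsibility (identifiers are treated as opaque strings).

# The synthetic-data generator

The generator exists so that every downstream stage is testable with known
ground truth. It emulates the canonical design: 34 samples in cells
10/10/6/8; panels of 89/71/71 metabolites; per-metabolite log-scale means
uniform in [1, 4] and SDs uniform in [0.3, 0.8] (realistic spread for
targeted panels); abundances generated as
$\exp(\mu_j + \beta_{1j}\,\mathrm{cap} + \beta_{2j}\,\mathrm{age} +
\beta_{3j}\,\mathrm{cap}\cdot\mathrm{age} + \varepsilon)$,
$\varepsilon \sim N(0, \sigma_j)$, so raw data are log-normal and
$\lambda = 0$ is the recoverable transformation truth. Each effect type is
planted in 10% of metabolites (independently drawn, so overlaps occur) with
default standardized magnitude 1.0 within-group SD on the log scale — large
enough that tests have non-trivial power at $n = 34$, small enough that
recovery is not saturated. Running speed follows a design-linear model
(LCR-Y mean 20 m/min, HCR +12, old −2, extra old-HCR −6, residual SD 2,
floored at 1 m/min) reflecting the large young-age line difference and its
age-related shrinkage seen in treadmill phenotyping; 5% of first-tissue
metabolites additionally contribute 1.5 m/min per log-SD to speed.
Metabolites are independent by default; an optional block-correlation mode
(blocks of 5, $\rho = 0.5$) exists to stress PLS under collinearity.

What the generator does **not** emulate: batch and instrument drift,
censoring at the detection limit, heavy-tailed measurement error, and
realistic inter-metabolite correlation networks. Passing recovery tests on
this generator therefore demonstrates the statistical machinery is correct
under its stated model, not that any real dataset satisfies that model.

Label-permutation nulls (`null_permutation_dataset`) jointly permute the
(capacity, age) pair across samples, preserving cell sizes exactly; speed
stays attached to its sample.

# Problem sizes used in the validation suite

The test suite validates statistical properties at deliberately chosen
sizes: permutation-test size and power use the study's own dimensions
($n = 34$, $J = 71$) with G = 99 permutations, 200 null and 50 planted
replicates; type-I error of the joint F-tests uses 2,000 simulated null
metabolites; end-to-end recovery uses 50 seeded replicates of the full
three-tissue study with 1.5-SD planted effects; FDR control uses 200
simulated screens with 90% nulls. These sizes give binomial standard errors
comfortably inside the asserted bands while keeping the whole suite
runnable on a laptop in well under half an hour.

# Known limitations

* $\lambda$ identification at $n = 34$ is weak (see above); the
  transform-spec table should be read as "an acceptable transformation",
  not "the transformation".
* Reported $Q^2$ depends on the cross-validation scheme; published values
  computed with an unknown scheme are comparable only qualitatively.
* The interaction contrast in the unbalanced 10/10/6/8 design has roughly
  half the precision of the main-effect contrasts; interaction-planted
  effects are correspondingly harder to attribute in the Venn partition.
* With correlated metabolites, VIP and univariate p answer different
  questions; the conjunction rule inherits the conservatism of both.
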