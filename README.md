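# aerometab

Statistical analysis of two-factor targeted metabolomics studies:
intrinsic aerobic capacity (high- vs. low-capacity runner rat lines,
HCR/LCR) crossed with age (young/old), profiled across serum, skeletal
muscle, and white adipose tissue (WAT). The package is aimed at
metabolomics analysts who need the complete multivariate + univariate
screening stack for this design with reproducible, file-based outputs.

## What it computes

For each tissue panel (samples × metabolites, strictly positive
abundances):

1. **Transformation/scaling** — per-metabolite Box-Cox transform
   ((x^λ − 1)/λ; ln x at λ = 0) selected on a λ grid under the
   design-residual criterion |skew| < 2 and |kurtosis| < 2 (residuals from
   the saturated capacity × age cell-means model), followed by
   unit-variance scaling with mean-centering.
2. **PLS-DA** — NIPALS partial least squares against the centered
   four-class (or two-class, or running-speed) response; R²X, R²Y;
   Q² = 1 − PRESS/SS from stratified 7-fold cross-validation;
   VIP_j = √(J·Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a); label-permutation
   validation (G = 200 per model) giving a permutation p-value and the
   R²/Q² intercepts of the permutation plot.
3. **Univariate models** — per metabolite, OLS on
   capacity + age + capacity×age (treatment coding, reference LCR/Young)
   with the 3-df joint F-test of the whole block; and a running-speed
   model with the 4-df joint F-test of the metabolite block (metabolite,
   metabolite×age, metabolite×capacity, metabolite×age×capacity),
   BH-FDR-corrected within tissue.
4. **Selection and Venn partition** — influential metabolites are those
   with VIP ≥ 1 **and** joint p < 0.05; each is attributed to a Venn
   region (capacity / age / interaction and their overlaps) by its
   per-term p-values, with direction arrows from coefficient signs
   ("up" = higher in HCR, or higher in old).
5. **Pathway over-representation** — one-sided hypergeometric test of the
   selected set against a user-supplied GMT library, with the measured
   panel as the background universe, BH-FDR across pathways.
6. **Synthetic data** — a generator emulating the canonical 34-animal
   unbalanced design (cells 10/10/6/8) and 89/71/71-metabolite panels,
   with log-normal abundances and planted capacity/age/interaction effects
   of known magnitude, for end-to-end validation with ground truth.

See `vignettes/aerometab-methods.Rmd` for the full methods account,
including every convention and design choice.

## Worked example

```r
library(aerometab)

# simulate the default factorial study (seeded, bit-reproducible)
sim <- simulate_study(simulation_config(seed = 7))
al  <- align(sim$matrices$serum, sim$design)

# Box-Cox + unit-variance scaling
pp  <- preprocess_matrix(al$matrix, al$design)

# four-class PLS-DA with permutation validation
Y    <- build_response(al$design, "four_class")
fit  <- fit_pls(pp$matrix$values, Y, A = 2)
perm <- permutation_validate(pp$matrix$values, Y, A = 2, G = 200,
                             folds = 7, seed = 7,
                             strata = attr(Y, "classes"))
perm
#> PermutationResult (G = 200): Q2 = 0.208, Q2 intercept = -0.200, p = 0.004975

# univariate screening and the selection/Venn report
uni  <- run_univariate_suite(pp$matrix, al$design)
sel  <- select_influential(fit$vip,
                           setNames(uni$group$joint_p, uni$group$metabolite))
part <- partition_venn(sel, uni$group)
part
#> VennPartition: 20 selected metabolite(s)
#>
#>        capacity_only             age_only     interaction_only
#>                    6                    5                    2
#>         capacity_age capacity_interaction      age_interaction
#>                    0                    5                    0
#>            all_three           joint_only
#>                    0                    2
```

Reading this output: the model separates the four groups better than 199
of 200 label permutations (p ≈ 0.005) and its Q² intercept is negative, so
the separation is not overfitting; 20 of 89 serum metabolites pass the
combined VIP ≥ 1 / joint p < 0.05 rule, and the partition attributes them
to capacity, age, and interaction regions with sign arrows in
`part$arrows`.

The same analysis runs end-to-end from a YAML config via `run_all()`
(artifacts written as CSV plus a run manifest), or from the command line:

```sh
Rscript inst/scripts/aerometab-cli.R run-all --config cfg.yaml --outdir out
```

Config keys (all optional; defaults shown in `validate_config(NULL)`):
`simulate`, `inputs.design`, `inputs.tissues.<name>`, `inputs.gmt`,
`thresholds.{vip,p,fdr}`, `pls.{components,folds,scheme,permutations}`,
`lambda_grid.{min,max,step}`, `missing.{policy,max_frac}`, `seed`,
`outdir`.

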