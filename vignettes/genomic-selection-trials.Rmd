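---
title: "Simulated conifer progeny trials: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated conifer progeny trials: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conifergs)
```

## What the package models

`conifergs` studies a practical question in tree breeding: **how many
markers does genomic selection need** before prediction accuracy stops
improving, and how does the answer depend on the family structure and
effective size of the training population? Because multi-decade conifer
trial data are not generally available, the package pairs the analysis
machinery (pedigree BLUP, RR-BLUP, cross-validation) with a simulator
that reproduces the *statistical* structure of two classical trial
designs:

* a **full-sib** partial diallel — 37 families drawn from 54 parents
  with deliberately uneven parent use, planted over 3 sites; status
  number (effective size) near 21;
* an **open-pollinated half-sib** trial — 25 seed parents whose pollen
  parents are unknown draws from a large wild pollen pool (default
  500), again over 3 sites; status number near 93–96.

Both scales are reduced by default to roughly 600 genotyped trees so a
complete study runs on a laptop; the family and site counts — which
drive the statistics — are kept at trial scale.

## The quantitative-genetic model

Phenotypes follow the standard multi-site individual-tree model. For
full-sib trials:

$$y = X\beta + Z_1 a + Z_2 sa + Z_3 s(rep) + Z_4 sf + Z_5 f + e$$

with fixed mean and site effects $\beta$; additive genetic values
$a \sim N(0, A\sigma^2_a)$ over the pedigree relationship matrix $A$;
a site $\times$ additive interaction $sa$; block-within-site effects
$s(rep) \sim N(0, I\sigma^2_{s(rep)})$; site $\times$ family and family
effects ($sf$, $f$, identity covariance); and residual
$e \sim N(0, I\sigma^2_e)$. The half-sib model drops the two family
terms. Narrow-sense heritability uses the design-specific ratios
implemented in `heritability()`; the block variance is excluded from
the denominator in both.

**The site $\times$ additive covariance.** With one tree per record
(each tree grows on exactly one site), an observation-level i.i.d.
$sa$ term is *exactly* confounded with the residual: the likelihood is
flat along $\sigma^2_{sa} + \sigma^2_e = \text{const}$ and neither
component is estimable. We therefore give $sa$ its field-standard
genetic meaning: additive covariance between trees of the **same**
site (the same-site block of $A$) and none across sites. This is the
separable G$\times$E structure under which relatives resemble each
other more on a shared site than across sites, and it makes every
component of the model identifiable. The generator realizes it by
drawing a fresh set of causal-effect deviations per site, so the
interaction is genuinely genetic rather than an arbitrary correlated
draw.

## The synthetic-data generator

* **Genome**: 12 chromosomes, 2,000 cM total — the conventional
  conifer map scale; marker positions uniform; 46,300 mapped loci by
  default, of which 300 are causal (QTLs).
* **Founders**: phased haplotypes in linkage equilibrium, allele
  frequencies uniform on [0.05, 0.95]. All descendant LD is created by
  co-segregation within families; there is no standing marker–QTL LD,
  so markers predict through relatedness and within-family linkage —
  the regime the emulated trials operate in.
* **Meiosis**: Haldane model (Poisson crossovers, no interference).
  The recombination fraction at 100 cM matches the map function
  closed form $0.5(1 - e^{-2})$ in the test suite.
* **Parent use**: full-sib family parents are sampled with weights
  $\propto e^{-0.07 \cdot \text{rank}}$. The skew constant was
  calibrated once, against the status-number target of the emulated
  full-sib trial (mean $N_s \approx 21.7$ over 30 draws), and is not a
  tuning knob of the experiments.
* **Effect scaling**: raw QTL effects are N(0, 1); a single constant
  rescales each realized component (additive, G$\times$E, block,
  family, residual) to its target variance *exactly*, so every
  replicate has exactly the intended heritability. This trades a
  little realism (components are no longer marginally $\chi^2$-noisy)
  for precise experimental control, which is what a simulator used to
  test estimators needs.
* **Open pollination**: each seed's pollen parent is an independent
  uniform draw from the pollen pool, recorded as *unknown* in the
  pedigree; the truth is kept separately for validation. Unknown
  parents enter all pedigree computations as unique unrelated
  founders.
* **Field layout**: balanced round-robin assignment to sites and
  blocks; fixed site effects default to $\{0, +0.5\sigma_e,
  -0.5\sigma_e\}$.
* **Default variances** $(\sigma^2_a, \sigma^2_{sa},
  \sigma^2_{s(rep)}, \sigma^2_{sf}, \sigma^2_f, \sigma^2_e) =
  (2, 1, 0.5, 0.5, 0.5, 5.5)$, i.e. $h^2 \approx 0.21$ under the
  full-sib formula — a mid-range value for growth traits; the trials'
  real components are not published, so these are the package's own
  choice and the experiments never depend on their exact values.

What the generator does **not** emulate: standing (ancestral) LD,
selection over generations, dominance/epistasis, missing or erroneous
genotypes, and spatial field trends. Conclusions from the synthetic
experiments therefore speak to relationship-driven prediction under
clean data, not to every property of a real trial.

## Estimation machinery

**ABLUP.** `build_mme()`/`solve_blup()` implement Henderson's
mixed-model equations with $A^{-1}\lambda$ penalties, solved by dense
Cholesky factorization — populations here are a few thousand
individuals, so sparse $A^{-1}$ machinery would be over-engineering.
Every pedigree member receives a breeding value, phenotyped or not.

**EM-REML.** `em_reml()` iterates the classical EM update on the
observation-level covariance. EM is attractive here because it is
monotone (the REML log-likelihood never decreases — asserted in the
tests at every iteration) and keeps components non-negative, but it
crawls along the flat directions this design genuinely has (additive
vs. family vs. site-family contrasts at 37 families). Each pair of EM
steps is therefore followed by a SQUAREM-style log-space extrapolation
that is accepted **only if it does not decrease the likelihood**, so
the monotonicity guarantee survives acceleration. Components are
floored at $10^{-8}\,\mathrm{var}(y)$; convergence is declared when
the largest relative EM-step change drops below `tol` (default 1e-6).

**RR-BLUP.** `fit_rrblup()` solves
$\hat g = (Z'Z + \lambda I)^{-1} Z'(y - 1\mu)$ with dosages centered
per marker and $\mu$ equal to the training mean (exactly the joint
solution for centered $Z$). When markers outnumber trees it switches
to the dual identity $\hat g = Z'(ZZ' + \lambda I)^{-1}(y - 1\mu)$,
which the tests pin to the explicit primal inverse at $10^{-8}$. The
ridge parameter $\lambda = \sigma^2_e / \sigma^2_g$ is re-estimated on
every training fold by REML through a single eigendecomposition of the
$n \times n$ kernel (`estimate_lambda()`), a one-dimensional search
over the variance ratio. No per-marker weights: shrinkage is uniform,
as the ridge model assumes.

**Cross-validation.** Genomic CV pools trees across sites, partitions
them into folds, re-centers markers and re-estimates $\lambda$ per
training set, and scores the Pearson correlation between held-out EBVs
and GEBVs. Internally the fold fits run in kernel (dual) form with an
exact rank-one correction for training-set centering, so cost is
independent of marker count; a test verifies fold-for-fold equality
with the explicit `fit_rrblup()`/`predict_gebv()` route. Degenerate
folds (constant predictions — e.g. masked trees with no relatives)
are recorded as missing and logged, never imputed or zeroed.

## The marker-density experiment

`run_marker_density_experiment()` filters the panel to markers with
observed heterozygosity below 0.40 (the screen applied to the exome
pools it emulates), samples random SNP subsets of each grid size
(default grid 200–50,000, 10 replicates), and runs replicated k-fold
CV per subset. Summaries reduce each marker replicate to its mean
accuracy and report mean/SD/SE over replicates; `doubling_factor()`,
`plateau_threshold()` (smallest grid point within `rel_tol` of the
best mean) and `design_accuracy_ratio()` condense the profile.

Two experimental-design choices deserve note:

* **Seeding**: one master seed spawns an independent child stream per
  (grid point, marker replicate) and per CV repeat, so any cell is
  reproducible in isolation and the full study is bit-reproducible.
* **Common random numbers**: CV partitions are shared across SNP-set
  totals within a marker replicate. The experiment exists to *compare*
  set totals; pairing the folds removes fold-sampling noise from that
  comparison, which matters near the plateau where true increments are
  of order $10^{-4}$ while unpaired fold noise is an order of
  magnitude larger.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run a scaled study chosen to
keep a complete run on one CPU pleasant while preserving the designs'
statistics: ~600 trees per design (37 × 16 full-sib, 25 × 24
half-sib), grid {200, 500, 1,000, 2,500, 5,000, 10,000, 20,000}, 5
marker replicates, 5 × 5-fold CV; variance-component recovery uses 12
replicate datasets of ~1,000 trees (37 × 27). Family count — not tree
count — dominates the sampling variance of variance components in
these designs, so replicate datasets buy more than larger single
datasets. The qualitative findings the scaled study reproduces
(accuracy rises with marker count; the full-sib design outperforms the
half-sib design at every set size; gains are negligible past ~10,000
markers; random same-size SNP sets vary little) are stable across
seeds; exact accuracies move at the second decimal.

## Known limitations

* EM-REML, even accelerated, converges slowly along genuinely flat
  likelihood ridges; single-dataset variance components for a
  37-family design carry large sampling error (±30–50% for
  $\sigma^2_a$). This is a property of the design, not the optimizer —
  averages over replicate datasets are unbiased and tight.
* The ABLUP cross-validation accuracy is an EBV–EBV correlation, as in
  operational practice. With relatives in both training and validation
  this is *not* an unbiased estimate of accuracy against true breeding
  values; with no relatives it is undefined (and reported missing).
* `estimate_lambda()` searches $\log_{10}\lambda \in [-8, 8]$;
  responses that are pure noise land on the upper boundary by design.
* Dense matrices throughout cap comfortable problem sizes at a few
  thousand individuals and ~50,000 markers.

The package's functions, file readers/writers and this vignette are
the intended interface; analyses are scripted from R (see
`scripts/acceptance.R` for a complete worked pipeline).
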