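---
title: "Methods: cord metabolome and BMI-trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cord metabolome and BMI-trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Childhood obesity that begins early tends to persist. If metabolites
measured in umbilical-cord plasma at birth carry information about a
child's *future* BMI trajectory, they could serve as very early risk
markers. `cordtraj` implements an analysis pipeline for prospective birth
cohorts that asks exactly this question: it classifies each child's
longitudinal BMI record from birth to adolescence into a small number of
clinically interpretable trajectory groups, organizes the cord metabolome
into co-abundance network modules, and tests modules and individual
metabolites for association with those groups, supplemented by a
time-window view that localizes when in childhood each metabolite's
association with BMI is strongest.

Cohort data of this kind are typically request-only, so the package ships
a seeded synthetic-cohort generator with known ground truth; every stage
of the pipeline is validated against what the generator planted.

# Trajectory classification

**Percentiles.** Raw BMI is age- and sex-dependent, so visits are first
converted to BMI-for-age percentiles (BMIPCT) with the LMS method: a
growth reference supplies, per sex and age, the Box-Cox power $L$, median
$M$ and coefficient of variation $S$, and
$z = ((\mathrm{BMI}/M)^L - 1)/(LS)$ (the $\log$ form as $L \to 0$;
the implementation switches at $|L| < 10^{-6}$, continuous to $10^{-8}$),
with $\mathrm{BMIPCT} = 100\,\Phi(z)$. Reference parameters are
interpolated linearly in age. Percentiles are defined only from age
2 years; younger visits are used on the raw-BMI side of the analysis
only. The reference table is a pluggable input; the package generates a
smooth synthetic one so nothing needs downloading.

**Time-windows.** Visits are irregular, so the age axis is partitioned
into disjoint half-open windows, each required to contain measurements
from at least 30 distinct children and to span at most 12 months. The
partition is built greedily over completed-month age groups, closing a
window at natural gaps in the visit schedule (3 or more empty months) or
once it reaches the target width implied by the window-count hint
(default 36 windows over birth-18 y, i.e. about 6 months). The number of
windows is therefore data-driven; on the default synthetic cohort about
20 BMI windows and 17 BMIPCT windows emerge. Per-child window averages
form the children-by-window matrix; interior gaps are filled with the
mean of the last and next observed values (whatever the gap length), and
leading/trailing gaps carry the nearest observed value outward. Edge
fills are a design choice the data do not pin down, so every cell's
provenance (`observed` / `interpolated` / `edge_filled`) is retained,
making sensitivity to the rule testable.

**Grouping.** k-means with $k = 2$ (25 restarts under a fixed seed)
splits children by overall percentile level; the higher-mean cluster is
deterministically relabeled cluster 1. A single PCA of the column-centred
matrix — computed jointly over all children, not per cluster — supplies
PC2, and each cluster is dichotomized at PC2 = 0, giving four groups.
Because eigenvectors have arbitrary sign, both PCs are oriented by
data-independent rules: PC1 correlates positively with row means; PC2's
mean loading over the earliest third of windows exceeds that over the
latest third. Under this orientation a child already at a high percentile
in the earliest observed windows scores positive on PC2, so the four
groups acquire fixed names: early-OWO (cluster 1, PC2 $\ge$ 0: high from
the start), late-OWO (cluster 1, PC2 < 0: rising later), NW-A and NW-B
(cluster 2). The joint-PCA choice is the one consistent with reporting a
single pair of variance fractions for PC1/PC2; a per-cluster variant
would change scores but not the construction.

**Collapse.** An exploratory screen regresses the four-level outcome
(reference NW-A) on each metabolite. When the NW-B-vs-NW-A contrast
yields no FDR-significant metabolite, the two normal-weight shapes are
collapsed into a single NW group and all main analyses use the three-level
outcome. The screen's decision is returned as a flag rather than applied
silently.

# Metabolite preprocessing

Three steps, in fixed order. (1) CV filter: metabolites whose coefficient
of variation, $100\,\mathrm{sd}/\mathrm{mean}$ over observed raw
intensities (sample SD, all samples), exceeds 20% *strictly* are
excluded. (2) Non-detects are imputed as half the minimum observed
intensity of that metabolite. (3) A rank-based inverse normal transform
maps each column onto normal quantiles, $\Phi^{-1}((r - c)/(n - 2c + 1))$
with Blom's offset $c = 3/8$ and average ranks for ties. The CV basis,
offset and threshold are parameters; their defaults are the conventional
choices, and the transform guarantees that downstream effect sizes are
per-SD-of-a-normal-scale quantities.

# Network modules

Modules are detected in the WGCNA tradition: unsigned Pearson adjacency
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$, topological overlap
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
(\min(k_i, k_j) + 1 - a_{ij})$, average-linkage clustering of
$1 - \mathrm{TOM}$, and a dendrogram cut with a minimum module size of
15; members of branches that complete above the cut, or of under-sized
branches, stay grey (unassigned). Colors follow the standard module
vocabulary (turquoise, blue, brown, ... in decreasing size order), so a
color name encodes the module's size rank. Each module is summarized by
its eigen-metabolite: PC1 of the standardized member columns, scaled to
unit variance and sign-oriented to correlate positively with the
member-average profile.

Numerical choices worth knowing:

* The soft power $\beta$ defaults to 7, the conventional choice for a
  panel of this size; `pick_power()` implements the scale-free plateau
  rule (smallest power whose signed fit index reaches 0.80 with an
  increment below 0.02) as an alternative.
* The cut is a *static* height on the $1-\mathrm{TOM}$ scale rather than
  an adaptive branch decomposition; with min-size filtering this recovers
  planted partitions exactly in validation and keeps null panels fully
  grey. The default height is 0.996: for weakly correlated modules
  ($|r| \approx 0.5$) within-module merges occur near
  $1 - |r|^\beta \approx 0.992$, so the cut must sit above that plateau,
  while merges between independent metabolites occur at essentially 1.
  A cut at 0.99 would bisect the plateau and make detection unstable.
* No post-hoc merging of modules by eigen-score correlation is applied.

# Association models

The three-level trajectory outcome is modelled with baseline-category
multinomial logistic regression (reference NW), fitted by Newton-Raphson
on the multinomial log-likelihood with step-halving; standard errors come
from the inverse observed information, and per-contrast Wald tests give
$\mathrm{OR} = e^\beta$ with 95% CI $e^{\beta \pm 1.96\,\mathrm{SE}}$.
Convergence requires a maximal score below $10^{-8}$ or a relative
log-likelihood change below $10^{-10}$; non-convergence and separation
($|\beta| > 20$) are flagged on the output rather than dropped. The fit
is validated against the closed-form saturated-table MLE and an
independent optimizer.

Models adjust for sex, race, preterm birth, maternal smoking, maternal
overweight/obesity and maternal education; explicit `Unknown` categories
are retained as their own dummy level so n is preserved. FDR control is
Benjamini-Hochberg within each declared family: the set of modules per
contrast, all tested metabolites per contrast, or the members of
significant modules (selected at unadjusted $p \le 0.05$ on either
contrast) for the follow-up table. Sex modification is screened by a
likelihood-ratio test comparing the model with exposure and
exposure-by-sex interaction against the model with neither
($2 \times (\text{levels} - 1)$ df).

# Time-window models

Within each window, OLS regresses window-averaged BMI on exposure, sex,
their interaction, the child's mean age in the window, and the covariate
set; only *observed* (never imputed) window values enter, since
regressing on imputed outcomes would manufacture information. Sex-specific
slopes ($\beta_F$; $\beta_M = \beta_F + \beta_{\text{int}}$) are
standardized by the within-sex SD of window BMI so effects are comparable
across ages with different BMI spread. The exposure's overall effect
(main + interaction) is screened by a 2-df LRT; BH families are
per-window. Models with fewer than 20 complete cases, a single sex, or a
rank-deficient design are flagged. Three sensitivity variants add one
adjuster — cesarean section, breastfeeding, or birthweight (skipped by
construction in the first, at-birth window).

# The synthetic cohort

The generator emulates a US urban, low-income, predominantly Black and
Hispanic birth cohort of about 900 children followed birth-18 y:

* **Classes.** early-OWO / late-OWO / NW with probabilities
  0.41 / 0.27 / 0.32. Mean percentile curves: NW flat at 40; early-OWO
  rising to 85 by age 4 then drifting to 90; late-OWO flat at 50 until
  age 6 then rising to 88 by age 12. Child-level intercept SD 5 and
  visit noise SD 4 percentile points; percentiles are mapped to raw BMI
  through the synthetic LMS reference, so trajectory truth lives on the
  same scale the pipeline clusters on.
* **Visits.** Dense in infancy (ten scheduled visits before age 2), then
  annual with jitter; 12% of visits are missed; every child is followed
  at least 10 years and a quarter to 18 y. This attrition is milder than
  severely attrited real cohorts on purpose: with early dropout the
  latent class of a short-record child is not identifiable by *any*
  method, and the validation suite is meant to measure the pipeline, not
  censoring. Passing recovery tests therefore says nothing about cohorts
  whose children leave before their trajectory shape is expressed.
* **Metabolome.** 395 metabolites: seven correlated blocks (two TAG-like,
  DAG-like, CE-like, plus three neutral blocks; within-block correlation
  $\rho = 0.5$) over 245 metabolites, 131 independent singles, and 19
  high-variance junk metabolites that the CV filter removes, leaving 376
  retained (194 on the C8-pos platform, 182 on HILIC-pos). Block latent
  factors shift by class: TAG/DAG-like $-0.25$ SD and CE-like $+0.25$ SD
  in early-OWO, half-sized shifts in late-OWO — effect sizes at which
  association power is realistic rather than trivial. Intensities are
  exponentiated; values below each metabolite's 2% quantile become
  non-detects.
* **Covariates.** Marginals near the emulated cohort (45% female, 60%
  Black, 18% preterm, 34% cesarean). Birthweight loads strongly on BMI
  near birth (correlation ~0.7, SD ~675 g) and directly on the TAG-like
  factor, so adjusting for it attenuates early-window metabolite effects
  — the mediator-like behaviour the sensitivity analysis probes — while
  cesarean and breastfeeding are generated independent of the metabolome
  and leave effects unchanged.

What the generator does **not** emulate: assay batch/drift structure,
skewed non-Gaussian metabolite tails beyond lognormality, informative
(outcome-dependent) dropout, measurement error in height/weight, and the
real cohort's exact demographic joint distribution. Conclusions from
passing tests are correspondingly scoped.

# Validation layout and problem sizes

The test suite builds all fixtures in code. The heavier checks use: the
default cohort (n = 900) for trajectory recovery (3-group agreement
$\ge$ 95%); $\rho = 0.7$ for exact planted-partition recovery (adjusted
Rand index 1) with $\rho = 0$ as the all-grey null; 200 replicates at
n = 900 for planted effect-direction power; 100 replicates of a reduced
null panel for type-I calibration at $p \le 0.05$; 500 small-sample
replicates for LRT uniformity; and 6 replicate cohorts at n = 600 for the
sensitivity-adjustment properties. These sizes were chosen so the full
suite completes in minutes while keeping Monte-Carlo error well inside
the asserted bands.

# Running the pipeline

`run_pipeline()` executes the full analysis (QC, percentiles, windows,
trajectory groups, modules, associations, sex-interaction screen,
window models, descriptives) from the four input tables and optionally
writes every stage table as delimited text plus a JSON parameter echo;
`validate_inputs()` checks schemas and id cross-references first.
`generate_cohort()` / `write_cohort()` produce the synthetic inputs. The
stage functions are exported individually, so the pipeline is equally
usable piecemeal; `pipeline_params()` collects every tunable parameter
(window constraints, seeds, power, minimum module size, CV threshold,
rank offset, covariate choice, FDR level, sensitivity adjuster) with the
defaults described above. By default the per-window stage runs on module
eigen-scores; set `window_exposures = "metabolites"` for the full
per-metabolite sweep, which is the expensive variant.

# Known limitations

* The window-construction rule (gap/target-width closure) and the edge
  imputation rule are reasonable but not unique; both are parameterized
  and provenance-tracked so their influence can be audited.
* The static dendrogram cut can split one true module into two (or leave
  weakly attached members grey) near the cut height; on real data,
  module counts should be read as resolution-dependent.
* Wald intervals are reported; profile-likelihood intervals would differ
  slightly for small cells.
* The four-group exploratory screen inherits small-group instability when
  NW-B is small; fits there may carry low-n warnings.
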