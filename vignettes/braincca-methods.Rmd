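---
title: "Cross-validated brain-behavior CCA: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated brain-behavior CCA: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

braincca implements a multivariate association analysis between two
high-dimensional data domains measured on the same subjects — structural
brain-network features and behavioral scores — organized around a single
question: how much of the linear coupling between the domains is carried by
one latent axis, and how strongly that axis tracks a hold-out variable
(age).  This vignette records the models the package fits, the parameters
that matter, what the synthetic-cohort generator does and does not emulate,
and the design decisions taken where the procedure was genuinely open.

## The analysis pipeline

The stages run in a fixed order (`run_pipeline()` wires them together):

1. **Network construction.** Per subject, a streamline-count matrix between
   brain parcels is converted to connection densities
   `C_d = 2 s_ij / (n_i + n_j)`, where `s_ij` counts streamlines terminating
   in both parcels and `n_i`, `n_j` are parcel voxel counts
   (`connection_density()`, `build_density_networks()`).  A consensus
   threshold removes every edge not present in a strict majority of subjects
   (`consensus_threshold()`); binary node degree on the surviving edges is
   the per-subject network feature vector (`node_degree()`).  Graph-level
   summaries (highest degree, edge density, binary global efficiency) and
   their quadratic lifespan trends on decade-bin means document the
   inverted-U aging pattern (`graph_summaries()`, `quadratic_trend()`).

2. **Feature preparation** (`filter_variables()`, `zscore_features()`,
   `deconfound()`, `nearest_spd_covariance()`, `pca_basis()`), in the fixed
   order filter → z-score → deconfound → (behavior only) nearest-SPD
   covariance → PCA.  Variables with any observation beyond 3 SD of their
   own mean, or missing in at least half the subjects, are dropped whole.
   Deconfounding regresses an intercept, the confounds (sex, height, weight,
   heart rate, systolic/diastolic blood pressure) and — in the
   age-deconfounded model variant — age out of every variable by OLS,
   keeping residuals.  The behavior covariance is estimated
   pairwise-complete and projected to the nearest symmetric
   positive-definite matrix before eigendecomposition; missing cells are
   mean-imputed (zero after standardization) only when projecting scores,
   the minimal-leverage choice.  The network matrix is complete by
   construction and uses standard (SVD) PCA.

3. **CCA** (`fit_cca()`): a standard canonical correlation analysis on the
   two PCA score matrices, solved by SVD of the whitened cross-covariance.
   The number of factor pairs is the smaller PCA dimension.  Canonical
   loadings are the correlations between each original normalized variable
   and each factor (`compute_loadings()`).

4. **Age correlation** (`age_correlation()`): OLS of age on the two
   first-axis factor-score columns; `r_age` is the square root of the model
   R², reported unsigned.  A bootstrap null test resamples factor rows with
   replacement against fixed ages (one-sided p), and a separate joint
   bootstrap gives the standard error (`bootstrap_null_p()`,
   `bootstrap_se()`).

5. **Cross-validation** (`repeated_kfold_cca()`): per repeat, a fresh random
   partition into k near-equal folds; each fold is hold-out-projected
   through preprocessing statistics, PCA components and CCA weights fitted
   on the other folds only, so every subject gets one hold-out estimate per
   repeat.  Hold-out loadings correlate the full-data normalized variables
   with the assembled hold-out factors.  Final estimates are element-wise
   medians across repeats with across-repeat SDs as standard errors.

6. **Dimension tuning** (`grid_search()`): the cross-validated first-axis
   `r_age` is evaluated on a grid of PCA component pairs and the argmax
   selected (ties toward smaller dimensions).  At full scale the
   grid has 99 × 99 = 9,801 cells; with 15,000 repeats per cell the
   bookkeeping counts 147,015,000 model evaluations (`grid_plan()`).

7. **Rich club** (`average_network()`, `rich_club_partition()`,
   `participation_coefficient()`, `loading_degree_association()`): the
   consensus-thresholded mean network is partitioned into a high-degree core
   (top `round(fraction * n)` nodes by min-max-normalized degree) and a
   periphery, and first-axis network loadings are related to degree by
   Spearman rank correlations with bootstrap inference.

8. **RSA on loadings** (`loading_dissimilarity()`, `module_average()`,
   `rsa_difference()`, `chord_data()`): every pair of variables (network and
   behavior stacked) is compared by `1 - |corr|` of their loading profiles
   across all canonical factors; the matrix is averaged within module pairs
   (ten network modules, then seven behavior domains), and the difference
   between the full model's and the age-deconfounded model's module matrices
   isolates the age-dependent structure.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_prop` (consensus) | 0.5 | edge kept iff nonzero in *more than* this fraction of subjects; presence in exactly half is removed |
| `outlier_sd` | 3 | per-variable z threshold; the variable, not the cell, is dropped |
| `min_presence` | 0.5 | missing fraction at/above which a variable is dropped |
| `n_comp` | (40, 38) at study scale | PCA dimensions (behavior, network); the grid search exists because this choice changes which axis CCA finds |
| `k`, `n_repeats` | 5, configurable | repeated k-fold design; 15,000 repeats at full (cluster) scale, 40–100 at desk scale (the estimator is a median, which stabilizes quickly) |
| `n_boot` | 10,000 | bootstrap replicates for p-values and SEs |
| `fraction` (rich club) | 54/376 | core proportion; reproduces a 54-of-376 core exactly |
| `percentile` (chord) | 75 | strict cut: only cells strictly above the 75th percentile survive |

## What the synthetic generator emulates

`cohort_spec()` defaults are the study conditions: 594 subjects with ages
balanced over seven decade bins spanning 18–88 years; 334 behavior variables
in seven domains; 376-node connectomes labeled with ten modules (seven
functional networks, hippocampus, amygdala, remaining subcortex).  A latent
axis — a standardized negative quadratic of age peaking at 40 years — drives
both domains: behavior variables load on it with couplings of mean magnitude
0.6 (about a quarter of each variable's variance, the size of age effect
typical of lifespan cognitive scores; half the couplings positive), and
expected streamline counts scale as `(1 + 0.3 * latent)`, which yields the
inverted-U degree trend through presence/absence of the weaker edges.
Confounds correlate with age at |r| ≤ 0.3 so that deconfounding cannot
silently absorb the axis of interest.  Missing cells are MCAR at 2%, five
variables are made >50% missing, and ten cells are pushed beyond 3 SD — the
material the filters must catch.

Residual noise in behavior and confound columns is drawn from a *bounded*
(uniform) distribution.  Normalized assessment scores and screened-cohort
vitals are range-limited; with Gaussian residuals at n = 594 the 3-SD rule
would flag most variables through ordinary tail draws, which is not what the
filter is for.  With bounded residuals the filter removes the planted junk
plus the most strongly age-skewed variables — about 13% of the table at
study scale, close to the screening rate the filter produced in the original
study design (54 of 388).

What the generator does **not** emulate: the marginal distributions of any
real variable, spatial structure of parcels, non-age sources of
brain-behavior coupling, non-MCAR missingness, or realistic streamline-count
overdispersion (counts are Poisson around the group topology, keeping
variance tied to the mean).  Passing tests therefore demonstrate that the
*procedure* recovers what was planted under the stated conditions — not that
real data satisfy those conditions.

`planted_axis_cohort()` is the calibration companion: it plants an exact
cross-domain canonical correlation `rho_cross` and an exact age-axis
correlation `r_age_latent` (the network domain carries the latent axis
exactly; the behavior domain an attenuated copy — with that asymmetry the
multiple correlation of age on the two axes equals `r_age_latent`
analytically).  Parameter-recovery tests run it at n = 600,
`rho_cross = 0.6`, `r_age_latent = 0.65` with 100 cross-validation repeats
and require recovery within ±0.05.

## Numerical choices

- **Consensus boundary:** "present in at least half" is implemented as a
  strict majority (`presence > 0.5 n`), so an edge in exactly half the
  subjects is removed; the corresponding rule zeroes mean-network edges at
  `presence <= 0.5 n`.
- **Nearest-SPD projection:** alternating symmetrization and eigenvalue
  flooring at 1e-10 ("positive definite" needs a strictly positive floor);
  an already-SPD matrix is returned unchanged, and non-convergence after 100
  sweeps is an error with diagnostics.
- **Sign conventions:** PCA components are oriented so their
  largest-magnitude element is positive; CCA weight pairs likewise, flipped
  jointly so canonical correlations stay positive; when age is available the
  first factor pair is oriented so its summed scores correlate non-negatively
  with age.  `r_age` is a square root of R² and hence unsigned regardless.
- **Fold alignment:** canonical factors have arbitrary sign and can permute
  across folds/repeats, so medians would be meaningless without alignment.
  Each repeat's assembled hold-out factors are greedily matched to the
  full-data reference model by |correlation| of factor columns (summed over
  the two domains) and sign-flipped jointly.  Alignment in factor-score
  space, rather than weight space, is deliberate: weights live in each
  fold's own PCA basis and are not comparable across folds.
- **Grid search nesting:** within each repeat/fold, preprocessing and PCA
  are fitted once at the largest requested dimension and component subsets
  are sliced from it — exact, because principal components are nested.
- **RSA correlation:** Pearson by default (loadings are continuous
  correlations).  Pearson absorbs flips of a whole variable's profile
  exactly (the |·|), and factor-*column* flips only up to the
  profile-centering term; an uncentered `"cosine"` option is exactly
  invariant to factor sign indeterminacy.
- **Percentile convention:** linear-interpolation sample quantiles (R type
  7); "below the top 75th percentile eliminated" is read as *keep strictly
  greater than* the percentile value, which makes the four-cell example
  (one survivor) exact.
- **Word-cloud scale:** the per-module positive and negative loading means
  (not sums) set the scale, with the summed-magnitude variant available by
  argument.
- **Participation coefficient:** the within/between connection-count ratio
  as literally defined, with `NA` (flagged) where a node has no cross-group
  connection; the standard within/total fraction is available by argument.
- **AICc:** `n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with k = 3 on the bin
  means, so at least five populated bins are required.

## Open design points, resolved

- **Quadratic trends on decade-bin means** (seven points), not raw subjects:
  the near-constant AICc values such fits produce are only plausible for a
  small fixed n, and binning matches how the lifespan figures are drawn.
  Raw-subject fits remain possible by calling `quadratic_trend()` with
  different binning.
- **Binary degree**, not strength: node-degree language and the default
  behavior of the standard toolbox favor counting surviving edges;
  efficiency is likewise computed on the binarized graph.
- **Rich-club fraction** defaults to 54/376 ≈ 14.4%: the printed core size
  (54) and periphery (322) are matched exactly, resolving the 14%-vs-15%
  ambiguity in favor of the counts.
- **M₂ and the quadratic axis:** age is removed *linearly* in the
  deconfounded model.  A quadratic-in-age latent axis therefore survives
  M₂ with a sizeable canonical correlation even though `r_age` collapses;
  only a cohort whose cross-domain coupling is linear in age (the
  `planted_axis_cohort(r_age_latent = 1)` setting) mirrors the full
  collapse of the first canonical correlation into the permutation null
  band.  Both behaviors are exercised in the test suite.
- **S_d orientation:** `rsa_difference()` returns `S_1 - S_2`.  Age-coupled
  module pairs are similar under the full model (small `S_1`) and decoupled
  after age removal (large `S_2`), so the age effect appears as the *most
  negative* cells of the brain-to-behavior block; the chord transform
  `1 - S_d` ranks exactly those pairs on top.  Tests assert this derived
  sign structure.
- **Bootstrap vs permutation:** the null test resamples regressor rows
  *with replacement* as described for the original procedure; a pure
  permutation variant is available (`method = "permute"`), and a separate
  `permutation_null_band()` serves the "inside the null band" check for the
  age-deconfounded model.
- **Selection bias:** choosing the grid cell by maximal cross-validated
  `r_age` and then reporting `r_age` from the same distribution is
  optimistically biased.  The package reproduces that procedure; nested
  cross-validation for unbiased post-selection inference is explicitly out
  of scope.

## Problem sizes used by the shipped checks

Unit tests run on cohorts of 60–300 subjects with 8–50 features per domain.
The property studies use: n = 600 with 100 repeats for parameter recovery;
500 simulations × 1,000 bootstrap replicates for type-I calibration (target
band 3–7% at α = 0.05); n = 400 with 15 repeats and five factors for the
age-deconfounding mirror.  `scripts/acceptance.R` runs the full pipeline at
the study conditions (594 × 334 behavior, 376-node connectomes) with 40
cross-validation repeats and 10,000-replicate bootstraps, which completes in
a few minutes on one CPU; the median-based estimators change negligibly
beyond tens of repeats, which is why the desk-scale repeat counts are
defensible stand-ins for the cluster-scale 15,000.

## Known limitations

- Linear, two-domain coupling only; no sparse/regularized/kernel CCA.
- Mean imputation of missing cells limits validity to low missingness; no
  multiple-imputation machinery.
- The rich-club analysis uses a fixed-fraction cutoff, not the rich-club
  coefficient curve against degree-preserving nulls.
- Graphical rendering is limited to the numeric tables behind the figures
  plus simple `autoplot()` methods; chord and word-cloud aesthetics are out
  of scope.
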