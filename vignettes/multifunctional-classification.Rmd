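---
title: "Multifunctional soil classification and indicator discovery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifunctional soil classification and indicator discovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfsoil)
```

## The problem

Mechanical site preparation (trenching, mounding, inversion) disturbs forest
soil before tree planting. Comparing disturbed plots to unlogged reference
forest one variable at a time usually shows nothing: within-treatment
variance swamps the treatment means. `mfsoil` implements the alternative,
*multifunctional* view: a soil sample is a whole profile of biogeochemical
descriptors — total C and N, pH, texture (sand/silt/clay), potential H2 and
CO uptake, potential CO2 production, and bacterial 16S rRNA gene abundance —
and samples are classified by the joint structure of that profile. The
resulting classes are then ranked by their deviation from the reference
condition and mined for bacterial indicator OTUs.

## The classification model

Given a composite-sample-by-variable table, the model is:

1. **Standardization.** Each variable is centred and divided by its sample
   SD (n−1). All downstream geometry lives in this z-space, which makes the
   classification invariant to affine rescaling of any input variable.
2. **UPGMA.** Average-linkage agglomeration of the Euclidean distance
   matrix. The implementation is in-package so that the tie-break is pinned
   (the pair whose smallest original sample indices are lexicographically
   least merges first); node heights are size-weighted average
   between-cluster distances and are monotone toward the root.
3. **SIMPROF.** A similarity-profile permutation test decides which nodes
   delineate real classes. For a node's samples, the observed profile is
   the sorted vector of pairwise Euclidean distances. Null profiles are
   built by permuting each variable independently across the node's
   samples; the expected profile is the pointwise mean of 999 null
   profiles, the statistic is π = Σ|observed − expected| over ranks, and
   its null distribution comes from 999 further profiles, with
   p = (1 + #{π* ≥ π}) / (1 + 999) so p can never be exactly zero.
   Groups of fewer than 3 samples are untestable (p = 1 by convention).
4. **Delineation.** Top-down traversal: test the root; on rejection
   (p ≤ 0.05) recurse into both children; a subtree that fails to reject —
   or is too small to test — becomes one class. α is deliberately not
   corrected across nodes (sequential stopping, standard SIMPROF practice).
5. **Disturbance ranking.** Classes carry Roman labels in dendrogram leaf
   order; separately, each class is ranked by the Euclidean distance of its
   centroid from the centroid of the reference samples in z-space.

Two reproducibility details are worth noting. Every node's test receives a
deterministic child seed, so a classification is a pure function of
(data, seed). And SIMPROF draws its per-variable permutations in
*sorted-variable-name* order, so the partition does not depend on the
column order of the input table — with an RNG stream consumed in input
order, reordering columns would silently change p-values.

### Power characteristics

SIMPROF permutes variables independently, so it detects *association
between variables across samples*. A class offset carried by only one or
two of ten descriptors is nearly invisible to it: permuting a single
bimodal variable reproduces the observed profile almost exactly. Deviations
spread across many descriptors — the situation the multifunctional concept
posits — are detected with high power. The synthetic defaults reflect this:
planted class effects touch 6–8 of the 10 descriptors.

## Descriptor screening

`pca_screen()` performs correlation PCA (eigen-decomposition of the
covariance of z, whose eigenvalues sum to the number of descriptors). Axes
with eigenvalue above the mean (Kaiser–Guttman) are flagged as meaningful.
Descriptors are flagged as *contributing* when their loading-vector length
in the displayed d-dimensional plane exceeds the equilibrium radius
sqrt(d/p); the plain ratio d/p is available behind a flag
(`equilibrium_radius(sqrt = FALSE)`) because the ratio form sometimes
circulates, but sqrt(d/p) is the defensible textbook definition for
unit-eigenvector loadings and is the default.

Univariate screens mirror standard practice: Shapiro–Wilk normality check,
log transforms for gas exchange rates and a square-root transform for
bacterial abundance, one-way ANOVA with Bonferroni-corrected pairwise
t-tests, and Pearson (or Spearman) correlations. One calibration note:
with ten variables screened at α = 0.05, a fully null dataset still has a
≈ 40% chance that *some* variable is nominally significant — the per-test
level is calibrated (and tested as such), but "no variable significant" is
a property of a single dataset, not a guarantee.

## Community analysis

OTU count tables are equalized by rarefaction without replacement to the
smallest library (one deterministic draw per seed, via `vegan::rrarefy`),
then filtered: with the default 0.005% fraction, an OTU needs at least
`floor(5e-5 × depth)` reads — 8 at a 166,040-read depth — in at least one
sample. The phrasing "per library" is genuinely ambiguous between a
per-sample and a table-total reading, so both are implemented
(`rule = "any_sample"`, the default, and `rule = "table_total"`); neither
is asserted as the original intent.

Alpha diversity is Shannon entropy in nats (consistent with index values
around 6 for communities of thousands of OTUs) and the ACE richness
estimator with the standard rare-group cutoff of 10; when every rare read
is a singleton ACE's sample coverage is zero and the estimator falls back
to Chao1 with a warning. Beta diversity is multivariate dispersion:
distance of each sample to its group centroid in the principal-coordinate
embedding (`vegan::betadisper`, centroid type).

## Constrained ordination

RDA regresses the Hellinger-transformed community matrix on standardized
environmental predictors and takes principal axes of the fitted values;
eigenvalues are on the variance scale so canonical plus residual
eigenvalues reproduce the total community variance (asserted to 1e−9 in
the tests, and cross-checked against `vegan::rda`, which serves as an
independent oracle, never as the implementation). Significance uses the
pseudo-F statistic with free row permutation of Y and the +1 p-value
convention; the permutation scheme is the simplest defensible default, and
residual permutation was consciously left out of scope for the initial
release.

Forward selection applies the double-stopping rule: the global model must
be significant, and a candidate (the one adding the most R²) is admitted
only if its marginal permutation test — computed by partial RDA, i.e. on Y
and the candidate residualized on the already-selected variables — is
significant *and* the cumulative adjusted R² does not exceed the global
model's adjusted R². One property of this rule deserves honesty: at the
step where the last truly relevant variable is considered, the comparison
of candidate-model and global-model adjusted R² is nearly a coin flip when
all remaining candidates are noise (the two quantities differ only through
the noise variables' residual absorption). This is inherent to the scope
rule, not an implementation artifact: the package's selections agree
seed-by-seed with `vegan::ordiR2step` on shared designs, which is the
property the tests pin down.

## Indicator OTUs

IndVal combines specificity A (an OTU's class-mean abundance divided by the
sum of class-mean abundances — mean-based, hence group-equalized) and
fidelity B (prevalence within the class). The statistic is the maximum over
classes of sqrt(A·B) (default) or A·B (classic); p-values come from 999
permutations of class labels with the +1 convention. Singleton classes are
processed but have essentially no permutation power (their `class_n` column
makes this visible). No multiplicity correction is applied by default —
with m null OTUs this implies ≈ 0.05·m false discoveries, which is the
honest behaviour of the uncorrected procedure; note that at 999
permutations the p-value floor of 1/1000 makes a Benjamini–Hochberg
correction over thousands of OTUs reject nothing, so raising the
permutation count is the only meaningful route to corrected inference.
Representative indicators — the highest-total-count significant indicator
per class, ties broken by identifier — and Spearman correlations of their
abundances against the environmental table complete the module.

## The synthetic-data generator

The generator emulates the study design end-to-end and is first-class,
tested code:

* **Design.** 3 blocks × 5 treatments (unlogged reference, simple and
  double trenching, inversion, mound) × 10 replicate samples, pooled into
  15 composites. Pooling is simulated as the arithmetic mean of replicate
  values, the numerical analogue of physically mixing soil.
* **Biogeochemistry.** Replicate values are truncated-normal draws
  (percentages in [0, 100], pH in [0, 14], rates and abundances ≥ 0) from
  treatment-level means and SDs. The shipped defaults describe an acidic
  boreal loamy sand (e.g. reference CO2 production 4.1 ± 1.3
  µmol g⁻¹ h⁻¹, H2 oxidation 6.3 ± 0.4 nmol g⁻¹ h⁻¹, 7.9 × 10⁹ 16S
  copies g⁻¹) and are generator seeds, not fitted parameters. Sampling is
  by inverse-CDF inversion rather than rejection: planted class effects
  can push a rate mean far below zero, where the truncated distribution
  concentrates at the bound and rejection sampling would never terminate.
* **Class structure.** A planted partition (sizes 1/2/3/9 over the 15
  composites, with the three reference composites forming the baseline
  class) shifts replicate-level means by class effects expressed in pooled
  (across-treatment mean) SDs, spread over 6–8 descriptors per disturbed
  class at 2–4 SD. Since composites average 10 replicates, composite-level
  noise is SD/√10, so these offsets separate classes by an order of
  magnitude more than the within-class spread. `simulate_study()` defaults
  to *uniform* treatment parameters when planting a partition: the shipped
  defaults' treatment-mean differences are individually non-significant, but at
  composite-level noise they are real multivariate structure that SIMPROF
  legitimately detects, and they would over-split the planted classes.
* **Gas series.** First-order decay (or linear growth) curves whose true
  rates invert the package's own unit conversion, so the flux module
  refits exactly the biogeochemical table's values up to measurement
  noise; uptake assays start from 2.5–3 ppmv with ≥ 5 points within 1 h,
  CO2 series use 4 points over 72 h.
* **Communities.** A shared log-normal community plus two planted
  rare-biosphere indicators per class (0.08% and 0.02% target relative
  abundance — below the 0.1% rare-biosphere ceiling, which the constructor
  enforces), present only in their class's samples; multinomial draws at a
  166,040-read depth.

What the generator does *not* emulate: spatial autocorrelation between
plots, within-treatment covariance among variables (no such covariance is
published, so replicate draws are independent across variables — a
deliberate simplification), sequencing error, chimeras, or taxonomy
assignment. Passing tests
therefore demonstrate correctness of the statistical machinery under a
clean factorial design, not robustness to the messiness of real field
data.

## Units, defaults, and numerical choices

| Parameter | Default | Meaning |
|---|---|---|
| SIMPROF permutations | 999 + 999 | expected profile + null distribution |
| RDA permutations | 1000 | pseudo-F null |
| IndVal permutations | 999 | label-shuffle null |
| α | 0.05 | all permutation tests |
| rarefaction depth | `"min"` | smallest library |
| filter fraction | 5e−5 (0.005%) | per-library read fraction |
| ACE rare cutoff | 10 | standard definition |
| incubation T, P | 298.15 K, 101325 Pa | microcosm conditions |
| bottle volume | 0.5 L nominal | headspace = bottle − soil/bulk density (1.0 g cm⁻³) |
| compensation point | 0 ppmv | configurable floor of the decay model |

Flux conversion uses the ideal-gas law with litres converted to m³:
n = χ·10⁻⁶ · P·V/(R·T). The uptake rate references the initial molar
quantity (k·n₀/m, the initial-rate convention); whether interval-averaged
rates would be preferable is not decidable from the assay description, so
the initial-rate convention is the exposed default.

Simulation sizes in the test suite — 200 runs for the two type-I
calibrations, 100 series for rate recovery, 50 seeds for class and
indicator recovery — were chosen to put the Monte-Carlo error comfortably
inside the assertion bands while keeping a full test run in minutes.

## Known limitations

* SIMPROF's power drops sharply when class structure lives in few
  variables (see above); this is a property of the test, inherited here.
* The uncorrected IndVal screen reports α-level false positives by design;
  with community-scale OTU counts the representative flag can land on such
  a false positive, so representatives should be read jointly with the
  indicator's abundance pattern (e.g. the class-restricted heatmap).
* Forward selection's adjusted-R² scope rule can decline the final true
  predictor (coin-flip behaviour at the boundary, matching the reference
  implementation).
* Rarefaction is a single draw; averaging over draws (or rarefaction-free
  approaches) is out of scope.
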