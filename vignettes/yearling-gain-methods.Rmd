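---
title: "Methods: genetic evaluation of yearling weight gain in dairy calves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic evaluation of yearling weight gain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(calfgrow)
```

## The trait and its editing rules

Commercial dairy herds weigh male and female calves repeatedly before
slaughter or first calving.  A weight `w` (kg) taken at age `a` (days) is
standardized to one year of age assuming a 35 kg birth weight:

    YG = 365 * (w - 35) / a + 35

so a record taken exactly at 365 d is returned unchanged and a record equal
to birth weight maps to 35 kg at any age.  `compute_yg()` implements this;
`apply_edits()` applies the editing rules in sequence: multiple-birth
calves deleted, calves with unknown sire or dam deleted, ages outside
150--500 d deleted, yearling gains outside 150--650 kg deleted, and at most
five records kept per animal (the four earliest plus the latest,
`cap_records_per_animal()`).  Both windows are treated as inclusive at
their bounds: the sources exclude records "prior to 150" days and gains
"<150 and >650", so strict violations only.  Each removal is counted in an
audit table whose rows always sum back to the input record count.

Contemporary groups are herd-year-season cells (`assign_hys()`): April
through September and October through March, the winter season labelled by
the calendar year of its October so that January--March births join the
previous October's cell and every cell is one contiguous half-year.  Cells
are kept separate per sex, which substitutes for a sex-of-calf fixed
effect.  Record-selection ties (equal weigh dates) are broken by input
order; these two conventions (winter labelling, tie-breaking) are our own
determinism choices where the verbal rules underdetermine the code.

## The repeatability animal model

Each edited record is modelled as

    yg = HYS + b1*sqrt(a) + b2*a + b3*a^2 + group + u + pe + e

with herd-year-season, the three age covariates and unknown-parent genetic
groups fixed, and animal additive-genetic `u ~ A * sigma2_a` and
permanent-environment `pe ~ I * sigma2_p` random; `e` is the residual.  Age
covariates are centred at 365 d (`sqrt(a) - sqrt(365)` etc.), which only
moves the intercept but conditions the equations; an EBV-invariance test
covers this.  `A` is the numerator relationship matrix; its inverse is
built directly by Henderson's rules with Mendelian-sampling variances
corrected for parental inbreeding (Meuwissen--Luo recursion,
`inbreeding()`), because an inbreeding-ignorant inverse is wrong whenever
matings of relatives occur and costs nothing extra at this scale.

Unknown parents are absorbed by genetic groups (`assign_groups()`): the
two-group policy (dam-only unknown vs sire unknown) used for variance
component estimation, and a many-group policy stratified by sex, birth-year
bin, missing-parent pattern and breed-of-sire for full evaluations.  The
year-bin boundaries of the many-group policy are not fully determined by
the sources, so they are a configurable policy (one bin per year, sparse
years merged to a minimum group size).  Two implementations of groups are
kept deliberately: phantom-parent (Quaas--Pollak) augmentation of the
A-inverse for evaluation, so group solutions share the additive block, and
expected-group-fraction covariates in the fixed part for REML, which keeps
`A` non-singular inside the likelihood.  One group is always confounded
with the contemporary-group mean, so the last group is constrained to zero
(reference); the birth-year base (`apply_base()`, mean EBV of a base
cohort set to zero) removes the resulting arbitrary level from reports.

The mixed-model equations are assembled sparsely (`mme_system()`,
`solve_mme()`) and solved by a sparse LDL' factorization; a
Jacobi-preconditioned conjugate-gradient path exists for systems too large
to factor.  Prediction-error variances come from the additive-block
diagonal of the inverse of the coefficient matrix, computed exactly by a
Takahashi selected-inversion kernel (C++) on the sparsity pattern of the
factor, and reliabilities are `1 - PEV / (sigma2_a (1 + F))` -- exact at
this scale, rather than the progeny-counting approximations used in
national systems.  Transmitting ability is half the EBV.

## Sex-heterogeneous variances

Male and female records differ in all three variance components.  The
combined-sex evaluation follows the published four-step procedure, realized
in its algebraically unambiguous weighted form (`scale_female_records()`):

1. single-sex REML gives male and female components;
2. female records are multiplied by `sqrt(A_m / A_f)` so both sexes share
   the male additive variance;
3. female permanent-environment and residual variances are carried forward
   multiplied by `A_m / A_f`;
4. each record enters the equations with weight
   `R_m / R_sex(scaled)` -- 1 for males,
   `(R_m A_f) / (R_f A_m)` for females -- on the common male residual
   scale, and the PE block keeps a sex-specific variance ratio.

The verbal description of step 3/4 can be read as augmenting diagonals by a
variance ratio or by its inverse; the per-record-weight formulation
sidesteps that ambiguity and is validated directly against a dense
generalized-least-squares oracle with heterogeneous residuals and
sex-specific PE variances.  When the two sexes share identical components
the whole procedure provably collapses to the homogeneous solve (tested to
1e-8), and the genetic correlation between the sexes is 1 by construction
in the simulator (one underlying breeding value scaled per sex), matching
the one-trait treatment of the analysis.

## REML

`reml_estimate()` maximizes the restricted likelihood of
`(sigma2_a, sigma2_p, sigma2_e)` using the sparse mixed-model equations:
the log-likelihood is evaluated through log-determinant identities on the
coefficient matrix (`|A|` itself is the product of Mendelian-sampling
variances, so it costs nothing), and the traces needed by the EM updates
and the gradient -- `tr(A^-1 C^aa)` and `tr(C^pp)` -- come from the same
Takahashi selected inverse as the PEVs.  Iterations start with a few EM
steps (guaranteed ascent; asserted per step in the tests) and switch to
average-information Newton steps with step-halving back toward the current
point whenever an update would leave the parameter space; a component that
collapses is pinned at a small positive bound and reported.  Convergence is
declared on relative parameter change below `tol` (default 1e-6); standard
errors come from the inverse average-information matrix at the optimum.
Starting values default to an equal three-way split of the phenotypic
variance; the estimation sources do not state theirs, and the optimum at
these data sizes is insensitive to the split.  Heritability is
`sigma2_a / total` and repeatability `(sigma2_a + sigma2_p) / total`.

The whole machinery is validated on small data against dense oracles: the
sparse likelihood equals the dense `V = ZGZ' + R` formula including the
constant, the analytic gradient matches numerical differentiation, EM never
decreases the likelihood, and AI and EM agree on the optimum, which also
dominates a surrounding likelihood grid computed densely.

## Trends and evaluation correlations

`genetic_trend()` regresses EBVs on birth date in fractional years
(365.25 d) from a configurable start date; the slope (kg/year) is invariant
to the genetic base.  `phenotypic_trend()` first selects, per animal, the
record with age closest to 365 d (ties to the earlier record) and regresses
those yearling gains on birth date.  `ebv_correlation()` compares two
evaluations over their common animals after a strict reliability filter;
whether the filter applies to the first table, both, or either is exposed
as a flag because published comparisons are ambiguous on this point.

## GWAS and GREML

The association module works on sire transmitting abilities.  Markers are
kept when genotyped in strictly more than 90% of the cohort
(`marker_qc()`); the cohort itself is bulls with genotypes, born from a
cutoff year, with evaluation reliability strictly above 0.5
(`select_cohort()`).  `assoc()` is the standard per-marker regression of
phenotype on allele dosage (missing dosages dropped per marker):
substitution effect, `R2` as squared correlation, two-sided t-test on
`n - 2` df.  Family structure is controlled non-parametrically:
`max_t_permutation()` permutes the phenotype against the genotypes and
records the maximum |t| per permutation; the genome-wide p-value is
`(1 + #{max >= observed}) / (n_perm + 1)` (the `+1` convention avoids
zero p-values), floored at `1/(n_perm + 1)`, with a Bonferroni adjustment
of the nominal p-values reported alongside since both corrections appear in
this literature.  Permuting the phenotype vector or the genotype rows gives
the same null; we permute the phenotype.  The default `n_perm` is 10,000
at desk scale; one million is supported and simply takes its time.

`build_grm()` is VanRaden method 1 with observed allele frequencies --
`W W' / (2 sum p(1-p))` with mean-imputed missing dosages -- the default
construction of the common GREML tools.  `greml()` fits
`var(ta) = G sigma2_g + I sigma2_e` with an intercept by exact REML through
the eigendecomposition of `G`, profiling the likelihood on the variance
ratio and maximizing in one dimension; the reported fraction is
`sigma2_g / (sigma2_g + sigma2_e)` with a delta-method standard error from
the observed information.  A non-PSD `G` is bent by an eigenvalue shift and
flagged.  A brute-force likelihood grid on a 50-bull instance reproduces
the optimizer's optimum to 1e-3.

## The simulator and what passing tests mean

`simulate_pedigree()` generates discrete generations: founders with unknown
parents, each dam mated to one random sire per generation (so broods are
full sibs), offspring assigned sex, herd and birth date at random;
optionally parent links are erased or multiple-birth flags set.
`simulate_true_values()` draws one breeding value per animal by the
pedigree recursion with Mendelian-sampling variance
`0.5 sigma2_a (1 - (F_s + F_d)/2)` -- the same inbreeding the estimation
side uses -- and expresses it per sex by scaling with
`sqrt(sigma2_a_sex / sigma2_a_male)`; permanent-environment values and
i.i.d. normal HYS effects (treated as fixed at estimation) complete the
latent surface.  `simulate_weight_records()` draws 1--5 weighings per
animal at ages uniform on [150, 500] d and stores weights that invert the
yearling-gain standardization, so the editing module reconstructs the
latent trait exactly when all random components are zeroed.

Defaults are the single-sex field-scale estimates (males 574/1030/497,
females 489/407/484 kg^2 for additive/PE/residual), sex means 461 and 337
kg, the published sex-specific age curves, and a records-per-animal
distribution matching the published record-count table.  Where the sources
are silent we fixed: HYS standard deviation 15 kg (a plausible
between-management spread, small against a ~45-55 kg phenotypic SD),
uniform ages at weighing, and uniform herd sizes.  The simulator has no
linkage disequilibrium, no selection across generations, no genotype
imputation and no measurement-error model for the scale itself, so passing
recovery tests demonstrates correctness of the estimation machinery under
the assumed model, not robustness to violations of it in field data.

`validation_config()` freezes the parameter-recovery conditions for the
combined-scale analysis: both sexes at the combined components
(591/622/488 kg^2), equal means, one common age curve, about 5,000 recorded
animals with two records each in ~50 HYS cells.  One common age curve is
deliberate: the recovery experiment simulates under the analysis model,
whereas the sex-specific default curves would add a sex-by-age interaction
the model does not fit and push it into the residual (~+100 kg^2,
empirically).  Problem sizes throughout the tests (a few thousand animals
for recovery, hundreds for calibration replicates, 200 replicate data sets
for family-wise-error calibration) were chosen as the smallest at which the
statistical assertions have comfortable power.

`simulate_genotypes()` draws independent Hardy--Weinberg SNPs and, for
causal markers, scales additive effects so marker `k` explains its
configured fraction of the phenotype's variance, rebuilding the phenotype
as marker terms plus the rescaled input remainder (total variance
preserved).  With no causal markers the input phenotype is returned
untouched, giving exact null calibration tests.

## Known limitations

Single-trait only; no genomic BLUP / single-step blending; no
Misztal--Wiggans-style approximate reliabilities (exact PEVs replace them
at desk scale, and they will not scale to millions of animals); the
iterative solver returns no PEVs; permutation is the only family-structure
control in the GWAS (no GRM-adjusted mixed-model association, mirroring the
analysis this package re-implements); and published correlations of
yearling gain with milk, fertility, conformation and calving traits require
the proprietary national evaluations and are out of scope -- the generic
`ebv_correlation()` report is the supported interface for such comparisons.
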