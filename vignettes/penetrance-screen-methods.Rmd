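---
title: "Screening for modifiers of incomplete penetrance: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for modifiers of incomplete penetrance: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penescreen)
```

## The scientific problem

PLN:c.40_42delAGA (p.Arg14del) is a Dutch founder deletion in phospholamban
that confers a high risk of dilated/arrhythmogenic cardiomyopathy — yet a
substantial fraction of carriers never develop signs or symptoms. In a
population biobank, carriers identified irrespective of clinical presentation
can be split by symptom status and compared against the symptom-free general
population, turning incomplete penetrance itself into the phenotype. The
package implements that design end to end: four-group classification,
kinship-aware trait screening with permutation-based false-discovery control,
directional confirmation, founder-haplotype dissection, a genome-wide
logistic scan with an LD-confound screen, imbalance-calibrated rare-variant
burden tests, and polygenic-score interaction models. Because real carrier
cohorts of this kind are held under restricted access, every stage is driven
by a synthetic-cohort generator with a recorded ground truth.

## Group classification and the crude odds ratio

A participant is *symptomatic* if any configured self-reported symptom
(heart failure, heart attack, infarct, treated for arrhythmia) or
ECG sign (low voltages, negative T, ventricular tachycardia, ventricular
extrasystole, atrial fibrillation) is positive at either the baseline or
the follow-up visit; carriers are additionally checked against a cardiac
cause of death. Missing flags count as "not reported": questionnaire
non-response cannot assert disease, and carriers with no observed flag at
all are listed in the report instead of being silently classified. Crossing
symptom status with carrier status yields the four analysis groups; the
crude odds ratio of symptoms given carriage
`(sympt. carriers / asympt. carriers) / (sympt. non-carriers / asympt. non-carriers)`
is reported with a Wald interval on the log scale, with the
Haldane-Anscombe correction when a cell is empty.

## The kinship mixed model

Founder variants travel in families, and family membership also shifts
quantitative traits, so every trait comparison uses

\[
Y \sim \mathrm{age} + \mathrm{age}^2 + \mathrm{sex} + \mathrm{PC}_{1..4}
      + \mathrm{outcome} + u,\qquad
u \sim N(0,\, 2\Phi\,\sigma^2_g),\quad e \sim N(0,\, \sigma^2_e I),
\]

where \(\Phi\) is the pairwise kinship matrix (pedigree-derived here;
self-kinship 1/2) and `outcome` codes the contrasted groups. The fitter
exploits the block structure of \(2\Phi\): unrelated families contribute
independent blocks, so the one-time eigendecomposition costs a few small
symmetric eigenproblems rather than an \(O(n^3)\) factorization. After
rotation into the eigenbasis the model is a weighted regression whose
weights depend on the single variance ratio
\(\lambda = \sigma^2_g/\sigma^2_e\); the restricted likelihood is profiled
over \(\log_{10}\lambda\) on a grid spanning \([-10, 10]\) with Brent
refinement (tolerance 1e-8), and the boundary \(\sigma^2_g = 0\) is kept
when the grid end wins. REML rather than ML is used for the variance
components, and the outcome coefficient is tested with a Wald t statistic —
the same quantities (beta, SE) that kinship-LMM tools such as `lmekin`
report. With \(2\Phi = I\) the fit collapses to OLS, which the tests verify
to 1e-6, and on family-structured null traits the suite verifies the
motivating contrast: naive OLS z statistics inflate (\(\lambda_{GC} >
1.05\)) while the mixed model stays calibrated.

## The two-step screen and permutation q-values

Step 1 compares every trait between asymptomatic carriers and asymptomatic
non-carriers. Step 2 takes each step-1 hit through two confirmation
contrasts: a genuine protective factor must shift in the *same* direction
when asymptomatic carriers are compared with symptomatic carriers, and show
*no* difference (two-sided p > 0.05, unadjusted) or an opposite one between
symptomatic carriers and asymptomatic non-carriers — a shift present in all
carriers is a direct variant effect, not a modifier.

Multiplicity over the correlated trait panel is handled by permutation.
Each permutation shuffles the trait vector across participants while
kinship, PCs, age, sex and the group label stay attached to the
participant; the same shuffles are reused across traits with identical
missingness patterns so that the null preserves the between-trait
correlation. Age and sex remain linked to the participant rather than
travelling with the trait: they are participant attributes, and permuting
them would break the covariate adjustment itself.

Two q-value estimators are implemented on the pooled permutation null:

* `storey` (default): the plug-in false-discovery rate
  \(q(p) = \frac{\#\{p^{perm} \le p\}/B}{\#\{p^{obs} \le p\}}\),
  monotonized by a running maximum from the smallest p, with a zero pooled
  count replaced by one (so the smallest attainable q is 1/B). This is the
  estimator used by the default screen and is what the FDR-calibration
  tests certify.
* `pooled_p`: the pooled empirical p-value, \(\#\{p^{perm}\le p\}/(BT)\).
  This variant reproduces the behaviour of screens whose reported q-values
  track the corresponding p-values almost exactly; it is a per-test
  quantity, not an FDR, and is provided for comparability.

The permuted fits reuse the observed trait's REML variance-ratio estimate
(plug-in weights), so each permutation costs one weighted projection
instead of a fresh profile optimization — roughly a 200-fold saving at
B = 200. Because the observed and permuted p-values pass through exactly
the same plug-in Wald machinery, the approximation cancels to first order
in the q-value ratio; the null-calibration tests (uniform permutation p,
mean false-discovery fraction below nominal) measure precisely this
pipeline and pass under it.

Sensitivity analyses repeat step 1 on rank-based inverse-normal transformed
traits (Blom offset: \(\Phi^{-1}((r - 3/8)/(n + 1/4))\), average ranks for
ties) and on an age/sex-matched 1:4 case-control subset built by greedy
nearest-age matching without replacement, scarcest stratum first —
deterministic and auditable.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` defaults are the study conditions of the motivating cohort
and are not tuning knobs:

* 36,339 participants, founder allele frequency 0.1% (so ~74 carriers),
  half the cohort in 2–3-generation families; the founder allele is seeded
  into family founders with a probability calibrated against the pedigree's
  expected transmission count and then dropped Mendelianly, which
  reproduces the observed clustering (singleton carriers plus families of
  two or three carriers).
* symptom status is logistic in age (slope 0.03/yr) with a carrier log-OR
  of ln 9; the intercept is calibrated numerically against the realized age
  mix so that non-carrier prevalence hits 5.7%. Only the marginal carrier
  OR and prevalence are published quantities; the age slope is a
  population-epidemiology magnitude chosen once.
* traits have baseline mean/SD per age and sex, a pedigree-heritable factor
  (default \(h^2 = 0.3\)) and an individual-level factor shared across
  traits (default 0.2) producing realistic between-trait correlation. The
  residual SDs of the four key ECG traits (HR 11.7 bpm, QRS 12.3 ms,
  lnSDNN 0.65, lnRMSSDc 0.62) were back-derived once from the published
  screen standard errors at the 48-vs-34,201 design
  (SD = SE / sqrt(1/48 + 1/34201)) and fixed before any acceptance testing.
* carrier deletion-chromosomes share one ancestral haplotype over a span of
  766 kb left / 604 kb right of the variant; a configurable subset of
  recombinant carriers truncates it at recorded breakpoints, with either a
  random or a complementary tail.
* genome-wide background variants are unlinked (optionally with discrete
  two-population structure for the PC tests); LD exists only inside the
  founder region, which is the only place the analyses use it.

Deliberately absent: coalescent realism, genome-wide LD, imputation error
(INFO scores are carried but default to 1), age-dependent trait
trajectories, and ascertainment. Passing tests therefore demonstrate that
the *procedures* behave as specified under known truth — calibration,
recovery, invariances — not that they would be robust to every property of
real biobank data.

### Simulation sizes used by the test suite

The screen's standard error is governed almost entirely by the small
carrier group: moving from 34,201 to ~3,950 non-carriers changes
SE = SD·sqrt(1/48 + 1/n) by 0.5%. The package's validation suite therefore
holds the carrier group at the cohort scale (~75 carriers, ~48
asymptomatic) and scales the non-carrier group to ~4,000, with B = 200
permutations and 50 replicate seeds; burden calibration runs at the full
stated imbalance (40 cases vs 20,000 controls, shared permutation pool);
the null genome scan uses 5,000 variants, and the genomic-inflation
comparison draws 6,000 independent family-structured null traits (the
median-based inflation factor has sampling SE of roughly 1.25/sqrt(T), so
thousands of traits are needed to resolve a ±0.05 band). These are the
package's
own choices of simulation size and are recorded here so results can be
reproduced exactly.

### What recovery to expect at the published design point

At the published effect sizes and dispersions the expected step-1 Wald
statistics are about 3.2 (QRS −5.7 ms), 3.8 (HR +6.41 bpm) and 2.3
(lnSDNN −0.216). Under the default Storey plug-in q at 0.05 over 38 traits,
a trait needs z above roughly 2.9–3.0 to be declared, so replicate-to-
replicate recovery is high for HR, moderate for QRS, and low for lnSDNN —
the weakest published hit was itself a marginal observation, and no
FDR-controlling procedure recovers a z = 2.3 effect in most replicates.
The acceptance machinery measures and reports these recovery rates as they
are rather than loosening thresholds; single-study significance and
replication frequency are different quantities, and the package's job is to
compute both honestly.

## Founder-haplotype expansion

Working only on the deletion-bearing phased chromosome of each carrier, the
window around the variant grows one eligible variant at a time, strictly
alternating sides (left first; on symmetric fixtures the order is
irrelevant, and the alternation is recorded for asymmetric ones). Adding a
variant refines the partition of carriers into haplotype groups; when an
addition shrinks the modal group by more than the split threshold, that
side freezes and the offending variant is excluded from the reported
window. Two eligibility profiles mirror the two published scans: common
variants (population MAF ≥ 0.01, threshold 3) for the longest shared
haplotype, and rare variants (carrier-haplotype minor allele count ≥ 4,
threshold 10) for haplotype groups that could separate symptomatic from
asymptomatic carriers; the latter groups are compared against symptom
status with a 2×k chi-square (no continuity correction), replaced by a
Monte-Carlo permutation p when an expected cell drops below 1. The span is
reported variant-to-variant and, when a gene interval is supplied, relative
to the gene.

## Genome-wide scan, LD-confound screen, burden tests

The scan fits `logit(outcome) ~ age + sex + PC1 + dosage` per variant on an
unrelated subset (kinship pruning at 0.125: within-group pairs drop the
younger member, then controls related to cases are removed — deterministic
and order-invariant), with group-specific MAF filters (> 0.1 in carriers,
> 0.05 in non-carriers) and INFO > 0.4. Mixed-model GWAS is deliberately
not used at this imbalance (tens of cases against tens of thousands of
controls); plain ML with separation flagging is used, and regional
inference is calibrated by permutation instead.

Variants associated merely because they tag the founder haplotype are
screened by regressing −log10(p) on r² with the founder variant among
variants at p ≤ 5e-4; a variant is flagged an independent suggestive signal
only if it sits off that line (externally studentized residual > 3) *and*
is essentially unlinked (r² < 0.1). Both constants are configurable; the
rule is a deterministic stand-in for what is otherwise a visual judgement.

Regional rare-variant tests collapse qualifying variants (MAF ≤ 0.05 or
≤ 0.01, INFO > 0.8) into a per-participant minor-allele count and fit the
scan's logistic model. The reported p-value comes from outcome-label
permutations of a covariate-adjusted score statistic: under 40 cases vs
20,000 controls the asymptotic Wald p is anticonservative, and label
permutation restores uniformity (the suite verifies this with a pooled
Kolmogorov-Smirnov test). The permutation null model depends only on the
shuffled labels and the covariates, not on the region, so a pool of
permuted-label null fits is shared across regions; regions are independent
given the pool, and the discreteness floor is 1/(B+1). A variance-component
(SKAT-style) omnibus is intentionally out of scope; the burden-plus-
permutation route answers the same question — which regions associate —
with machinery that is fully auditable here. Regions significant at
2.5e-6 are split into ten equal-bp segments (remainder to the last) and
each segment retested.

## Polygenic scores

Scores are weighted sums of effect-allele dosages over variants matched on
position with exact or swapped alleles (swap flips the dosage);
strand-ambiguous palindromic variants are dropped, as are variants on
excluded chromosomes — excluding the founder variant's chromosome rebuilds
the score free of founder-haplotype contamination, and excluding every
weighted chromosome is an error rather than a silent zero score. Bayesian
shrinkage of the weights is upstream of this package; the weight table is
taken as given. Group association uses `PGS ~ age + sex + outcome` with the
score entered as a continuous percentile of the standardized score or as a
top/bottom-quintile indicator, with permutation q-values pooled across
scores. The interaction model,
`trait ~ age + sex + group + PGS + PGS:group` (reference: asymptomatic
non-carriers), reports a Wald test per PGS-by-group term, per-group partial
correlations of score and trait residualized on age and sex, and a
rank-normalized refit; PGS:age and PGS:sex product terms are omitted by
default (the group term is the scientific question), and groups under three
complete observations are reported untestable rather than estimated.

## Numerical and degenerate-input conventions

* Coordinates are 1-based and closed, as in VCF; window arithmetic is in bp.
* Missing phenotype sentinel in text files: empty field or `NA`; written
  back as `NA`. QC bounds are strict (value > bound removed), values are
  blanked but rows never dropped, and traits observed in fewer than 25
  asymptomatic carriers leave the panel before testing.
* Dosage hard-calls round to the nearest genotype within ±0.3 (with a 1e-9
  tolerance for binary floating point at the band edge), otherwise missing.
* The REML profile keeps the better of the Brent optimum and the best grid
  point, so a boundary optimum (no family variance) is representable.
* Ties: rank-normalization uses average ranks; control matching breaks age
  ties by participant ID; unrelated-subset pruning breaks age ties by
  dropping the lexicographically later ID.
* Zero cells: crude OR applies the Haldane-Anscombe correction with a
  warning; burden permutation p-values have floor 1/(B+1); empirical
  q-values replace a zero pooled count by one.

## Known limitations

The generator's LD model is minimal, so the LD-confound screen is tested on
constructed fixtures rather than emergent LD. The plug-in permutation
weights are an approximation whose error is second-order for the q-values
but would matter if permutation fits were compared across very different
variance ratios. Power calculators use expected-cell Wald approximations
and drift for designs whose smallest expected cell is below a few tens —
the simulation oracle in the test suite shows agreement within 1% once
cells are adequate, and the calculators warn and return missing on
degenerate designs. Sample-size scaling of the validation suite is
justified above; none of the suite's conclusions depend on the full 36,339.
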