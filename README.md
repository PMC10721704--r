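# penescreen

Screening for phenotypic and genetic modifiers of incomplete penetrance in
carriers of a founder variant.

Some carriers of highly penetrant cardiomyopathy variants — the motivating
case is PLN:c.40_42delAGA (p.Arg14del), a Dutch founder deletion in
phospholamban — never develop signs or symptoms. In a population biobank,
carriers ascertained irrespective of clinical status can be crossed with
symptom status to form four groups (asymptomatic/symptomatic x
carrier/non-carrier), and "what keeps a carrier healthy" becomes a testable
phenotype. `penescreen` implements that analysis chain as reusable R
functions for statistical geneticists and cardiogenetics researchers:

* four-group classification from questionnaire symptoms, ECG signs and
  cause of death (`assign_groups()`, `crude_or()`);
* a kinship-aware trait screen: for each quantitative trait the linear
  mixed model

  `Y ~ age + age² + sex + PC1..PC4 + outcome + u`, `u ~ N(0, 2Φ σ²_g)`,

  fitted by REML via a block eigendecomposition of twice the pedigree
  kinship matrix `Φ`, with permutation-based empirical q-values over the
  correlated trait panel and directional confirmation across the remaining
  group contrasts (`run_screen()`);
* the founder-haplotype window-expansion algorithm on phased carrier
  chromosomes, with MAF/MAC eligibility profiles and split thresholds
  (`expand_shared_haplotype()`);
* a logistic genome-wide scan on an unrelated subset
  (`logit(outcome) ~ age + sex + PC1 + dosage`) with group-specific MAF and
  INFO filters, plus a founder-LD confound screen that separates signals
  merely tagging the founder haplotype from independent ones
  (`gwas_scan()`, `ld_confound_screen()`);
* rare-variant burden tests whose p-values are calibrated by outcome-label
  permutation, which keeps them uniform under extreme case-control
  imbalance (`burden_test()`);
* polygenic-score computation from per-variant weight tables (with allele
  matching and chromosome exclusion), group association, and PGS-by-group
  interaction models (`score_pgs()`, `pgs_trait_interaction()`);
* a family-structured synthetic-cohort generator with recorded ground truth
  (`simulate_cohort()`) and analytic power calculators for the design
  (`power_carrier_design()`, `power_gwas()`).

Real cohorts of this design are held under restricted access, so the
generator is a first-class component: its defaults reproduce the study
conditions (36,339 participants, 0.1% founder allele frequency with
Mendelian transmission in families, background symptomatic prevalence 5.7%,
carrier odds ratio 9, a shared founder haplotype of 766 + 604 kb), and the
whole pipeline runs end to end against it.

## Worked example

Simulate a cohort at the study conditions with protective effects injected
into asymptomatic carriers (QRS −5.7 ms, HR +6.41 bpm, lnSDNN −0.216), the
non-carrier arm scaled to ~4,000, and run the screen:

```r
library(penescreen)

cfg <- sim_config(n_individuals = 4000, founder_allele_freq = 0.0095,
                  group_effects = protective_trait_effects(),
                  n_genome_variants = 150, n_region_variants = 12,
                  seed = 2024)
sim    <- simulate_cohort(cfg)
groups <- assign_groups(sim$cohort)
table(groups$group)
#> asymptomatic_noncarrier  symptomatic_noncarrier    asymptomatic_carrier
#>                    3681                     237                      49
#>     symptomatic_carrier
#>                      33

crude_or(groups)[c("or", "ci", "p")]
#> $or  10.5        $ci  6.6 16.6        $p  1.66e-23

kin <- pedigree_kinship(sim$fam)
pcs <- genotype_pcs(sim$genome, 4)
scr <- run_screen(sim$cohort, groups, kin, pcs = pcs, B = 200, seed = 1)
scr$step1[!is.na(scr$step1$q) & scr$step1$q <= 0.05,
          c("trait", "beta", "se", "p", "q")]
#>   trait  beta   se        p      q
#> 1    HR  6.20 1.72 0.000307 0.0100
#> 2   QRS -5.68 1.76 0.001269 0.0175
scr$step2[, c("trait", "beta_ac_sc", "p_ac_sc", "beta_sc_an", "p_sc_an",
              "verdict")]
#>   trait beta_ac_sc p_ac_sc beta_sc_an p_sc_an   verdict
#> 1    HR       8.07 0.00506     -1.814   0.384 confirmed
#> 2   QRS      -7.40 0.00550      0.996   0.641 confirmed
```

The realized carrier odds ratio (10.5) sits within sampling error of the
generating value 9 at ~82 carriers. The screen recovers the injected HR and
QRS shifts at q ≤ 0.05 (B = 200 permutations) and confirms both directions:
the effect persists when asymptomatic carriers are compared with
symptomatic carriers (`beta_ac_sc`, same sign) and is absent between
symptomatic carriers and asymptomatic non-carriers (`p_sc_an` > 0.05), the
signature that distinguishes a modifier from a direct variant effect. The
weaker lnSDNN effect (expected Wald z ≈ 2.3 at this design) is recovered
only in a minority of replicates — see the methods vignette
(`vignettes/penetrance-screen-methods.Rmd`) for the power analysis behind
that statement and for every modelling choice and default.

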