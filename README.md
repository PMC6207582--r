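# spatkin

Fine-scale spatial genetic structure (FSGS), dispersal-kernel estimation and
demographic-thinning simulation for stage-structured plant populations
genotyped at codominant microsatellite (SSR) loci.

## The problem

Conifers that regenerate on coarse woody debris (CWD — fallen logs, stumps)
establish their seedlings on a small, patchy set of "safe sites".  Limited
seed dispersal onto few establishment sites concentrates maternal sib
families in space and creates FSGS: a decline of kinship with distance among
young plants.  Whether that structure survives into the mature stage depends
on demographic thinning — inbreeding-related mortality, stochastic loss, and
the wholesale destruction of establishment sites by disturbance.  `spatkin`
provides the full analytical chain for asking these questions with mapped,
stage-structured SSR genotypes:

* **Kinship and FSGS.**  The Loiselle kinship coefficient
  `F_ij = (Q_ij - Q_m) / (1 - Q_m)`, estimated per locus as

  ```
  F_ij(l) = [ Σ_a (p_ia - p_a)(p_ja - p_a) + Σ_a p_a(1-p_a)/(n_l - 1) ] / Σ_a p_a(1-p_a)
  ```

  with allele doses `p_ia ∈ {0, ½, 1}` and reference frequencies `p_a` from a
  mature-tree gene pool augmented with one gene copy per cohort-unique
  allele.  Distance-class correlograms with location-permutation envelopes,
  the regression slope `b_F` of `F_ij` on `ln d` (delete-one-locus jackknife
  SE), and the FSGS intensity `Sp = b_F / (F_1 - 1)`.
* **Inbreeding.**  Individual `F_is` (kinship between the two genes within an
  individual) with a gene-copy re-pairing permutation test; Weir–Cockerham
  `F_IS`; a null-allele EM estimator and a joint maximum-likelihood
  `(f, null-frequency)` estimate.
* **Diversity and differentiation.**  Observed heterozygosity, Nei unbiased
  gene diversity, rarefied allelic richness, pairwise Weir–Cockerham theta
  with permutation tests, Monte-Carlo exact HWE tests, genotypic LD tests,
  and the Evanno delta-K table for choosing the number of genetic clusters.
* **Dispersal.**  Neighborhood-model (parentage mixture) maximum likelihood
  for seed and pollen exponential-power kernels
  `P(r) = b / (2π a² Γ(2/b)) · exp(-(r/a)^b)` with seed/pollen immigration,
  a dbh fecundity effect, zero selfing, and null-allele-aware genotype
  transition probabilities; mean dispersal distance
  `d = a Γ(3/b) / Γ(2/b)`.
* **Thinning simulations.**  Removal of the most inbred offspring, repeated
  random removal, and eradication of the most heavily colonised logs, each
  followed by FSGS recomputation without an external reference.
* **Synthetic data.**  A spatially explicit generator (plot, logs, mature
  stand, offspring produced under the same dispersal mixture the likelihood
  fits, labelled sib families) so that every estimator is testable against
  known truth.

## Worked example

Simulate a CWD-limited cohort under strong seed-dispersal limitation
(5 m kernel scale, 30 % seed immigration), then measure its FSGS against the
augmented mature reference:

```r
library(spatkin)

cfg       <- sim_config(seed_kernel = c(a = 5, b = 1), m_s = 0.3, m_p = 0.5,
                        rng_seed = 42)
land      <- generate_landscape(cfg)           # 112 logs in a 200 x 250 m plot
mature    <- generate_mature_population(cfg)   # 123 mature trees, 11 SSR loci
offspring <- simulate_offspring_nm(cfg, mature, land)
offspring
#> genotype_dataset: 369 individuals, 11 loci
#>   stages: seedling=179, sapling=190, juvenile=0, mature=0
#>   plot: 200 x 250 m

ref <- build_reference_frequencies(mature, offspring)
fsgs_summary(offspring, stage = "seedling", ref = ref, n_perms = 499,
             rng_seed = 1)
#> FSGS summary (n = 179):
#>   F_1 = 0.0445 (p = 0.004)
#>   b_F = -0.0072 (SE 0.0010, p = 0.002)
#>   Sp  = 0.0075
```

`F_1` is the mean kinship among seedlings within 10 m of each other — well
above zero, and `b_F` is significantly negative: kinship decays with log
distance, i.e. the cohort carries FSGS.  `Sp = 0.0075` puts the intensity in
the range reported for wind-dispersed trees.  The same cohort is also
measurably inbred:

```r
ft <- mean_fis_test(offspring, stage = "seedling", ref = ref, n_perms = 499,
                    n_stages_for_bonferroni = 2, rng_seed = 2)
#> mean F_is = 0.170 (Bonferroni-adjusted p = 0.004)
```

The first correlogram rows show where the signal lives (counts are pairs per
10-m class; p-values are two-sided permutation tests):

```
  lo hi n_pairs mean_fij     p
   0 10     237   0.0445 0.004
  10 20     288   0.0394 0.004
  20 30     434   0.0250 0.004
  30 40     649   0.0141 0.332
```

Dispersal kernels and immigration are fitted with
`fit_neighborhood_model(offspring, mature)`, and the thinning experiments run
with `thin_by_inbreeding()` / `thin_random()` / `thin_by_cwd()` +
`thinning_fsgs_report()`.  `run_pipeline()` orchestrates the whole chain from
a YAML/list config and writes TSV/JSON reports.  See the methods vignette
(`vignettes/spatkin-methods.Rmd`) for the statistical details and design
choices.

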