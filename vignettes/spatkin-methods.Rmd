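---
title: "Methods and design choices in spatkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in spatkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`spatkin` analyses fine-scale spatial genetic structure (FSGS) in mapped,
stage-structured populations typed at codominant SSR loci, estimates seed and
pollen dispersal kernels with a neighborhood (parentage mixture) model, and
runs demographic-thinning simulations.  This vignette records the statistical
models, their assumptions, the tunable parameters, and the design decisions
that were genuinely open.

## Data model

A `genotype_dataset` holds individuals with a growth stage (`seedling`,
`sapling`, `juvenile`, `mature`), plot-local coordinates in metres (origin at
a plot corner, all distances Euclidean), an optional log identifier
(`cwd_id`) for individuals established on coarse woody debris, dbh (cm) and
age, plus two allele matrices.  Invariants are enforced at construction:
mature trees have dbh ≥ 20 cm, juveniles 5–20 cm, and seedlings/saplings must
carry a `cwd_id`.  A locus is either typed (two alleles) or missing; every
estimator drops a missing locus pairwise, which keeps per-locus estimators
unbiased at the cost of slightly heterogeneous information across pairs.
Allele codes are opaque integer labels; no fragment-size semantics are
assumed.

## Kinship and FSGS

### Estimator

The kinship coefficient between individuals *i* and *j* is estimated per
locus as

$$F_{ij}(l) = \frac{\sum_a (p_{ia}-p_a)(p_{ja}-p_a) + c_l}
                  {\sum_a p_a(1-p_a)},
\qquad c_l = \frac{\sum_a p_a(1-p_a)}{n_l - 1},$$

with allele doses $p_{ia}\in\{0,\tfrac12,1\}$ and reference frequencies
$p_a$ carried by an `allele_freq_table` with $n_l$ gene copies.  Multilocus
values average locus values weighted by $w_l = \sum_a p_a(1-p_a)$.  The
finite-reference correction $c_l$ is **on by default** (matching standard
kinship software); it vanishes for an infinite ("known") reference, which is
how the sib-family calibration is run.  Loci monomorphic in the reference
are excluded; alleles absent from the reference contribute dose terms with
$p_a = 0$ only through the individual side.  Individual inbreeding $F_{is}$
uses the same estimator with the individual's two gene copies as the two
gene samples.

The reference population for stage-level FSGS is the mature stand,
*augmented* by one gene copy of every allele seen only in the younger
cohorts, so rare immigrant alleles get a small positive reference frequency.
The thinning analysis instead uses each dataset's own frequencies (no
external reference, no augmentation), under which the weighted mean of all
pairwise $F_{ij}$ is ≈ 0 by construction — an invariant the tests check.

### Correlogram, slope, Sp

Pairs are binned into half-open distance classes (default 20 × 10 m,
0–200 m).  The permutation null shuffles individual *locations* jointly (one
permutation of ids applied to the coordinate set), which preserves the
distance matrix's geometry; class means are recomputed per permutation,
giving per-class 2.5/97.5 % envelopes and two-sided rank p-values with the
+1 correction (minimum attainable p is $1/(R+1)$).  Whether published
envelopes of this kind are per-class or family-wide is generally ambiguous;
per-class percentiles are implemented and reported as such.

$b_F$ is the OLS slope of pairwise $F_{ij}$ on $\ln d$ over **all** pairs
with $d > 0$; coincident pairs (same point or log) stay in the first
distance class but are excluded from the regression because $\ln 0$ is
undefined.  The SE is a delete-one-locus jackknife (≥ 2 polymorphic loci
required) — a locus-resampling convention for slope uncertainty; the
significance test is one-sided (observed more negative) against the
location-permutation null.  FSGS intensity is $Sp = b_F/(F_1-1)$ with $F_1$
the first-class mean kinship; the identity $Sp\,(F_1-1)=b_F$ holds to
machine precision in every report.

The mean-$F_{is}$ permutation test re-pairs gene copies at random among the
stage's individuals locus by locus (preserving allele counts and the
missing-data pattern); p is one-sided (observed higher), with an optional
Bonferroni multiplier for the number of stages tested.  Cluster membership
for the within-cluster kinship summary uses the strict inequality
$Q > 0.9$, as membership thresholds are conventionally quoted.

## Diversity statistics

Per stage: observed heterozygosity; Nei unbiased gene diversity
$H_S = \frac{n_l}{n_l-1}(1-\sum_a p_a^2)$; rarefied allelic richness
$R_S = \sum_a [1 - \binom{N_l-N_{la}}{g}/\binom{N_l}{g}]$ at a standard gene
count $g$ (defaulting to the smallest typed gene count over loci and
stages); Weir–Cockerham $f$ and two-sample $\theta$ from variance
components summed over loci before the ratio, with one-sided permutation
tests that reassign individuals to groups.  The HWE test is a Monte-Carlo
exact test: the statistic is the conditional probability of the genotype
array given allele counts (Levene), the null is built by shuffling gene
copies into random diploid pairings — same target distribution as
Markov-chain samplers, simpler to verify by enumeration on small tables
(the tests do exactly that).  Linkage disequilibrium uses a genotypic
G-statistic with one locus permuted among individuals.

## Null alleles

The per-locus model has visible-allele frequencies $p_a$, a null frequency
$\rho$ ($\sum_a p_a + \rho = 1$), inbreeding $f$, and an
amplification-failure rate $\beta$: a visible/null heterozygote reads as a
visible homozygote, a null homozygote reads as missing.
`null_allele_em()` (single locus, $f = 0$) estimates $(p, \rho, \beta)$ by
EM to tolerance $10^{-8}$ (cap 10 000 iterations, error on
non-convergence).  `fis_null_joint_ml()` profiles a *shared* $f$ across
loci, maximising each locus's $(p,\rho)$ by EM inside a coarse grid +
golden-section search over $f \in [0, 0.9]$ (boundary solutions flagged).

Two identifiability facts shaped this design.  First, with a free per-locus
$\beta$ the joint model is unidentifiable: nulls and inbreeding inflate
homozygote classes in the same allele-frequency-proportional way, and the
missing class — the only separator — is absorbed by $\beta$.  The joint
estimator therefore fixes $\beta = 0$ (real amplification failures then
inflate $\rho$ slightly; the single-locus EM keeps $\beta$ free).  Second,
even with $\beta = 0$, $f$ and $\rho$ sit on a nearly flat likelihood ridge
when *every* locus carries the same null burden; the estimator is validated
on heterogeneous designs (several null-free loci pinning $f$), which is
also the situation in real SSR panels, where typically a minority of loci
carry appreciable nulls.  The joint estimate is a point-estimate
approximation of Bayesian null-aware inbreeding estimators, not a posterior.

## Neighborhood dispersal model

Per offspring $o$ the likelihood is

$$L_o = m_s B(g_o) + (1-m_s)\sum_j \psi_j\Big[m_p\,T(g_o\mid g_j,\text{bg})
+ (1-m_p)\sum_{k\ne j}\phi_{jk}\,T(g_o\mid g_j,g_k)\Big],$$

with mother weights $\psi_j \propto e^{\gamma z_j} P_s(d_{oj})$ over all
mature trees, father weights $\phi_{jk} \propto e^{\gamma z_k} P_p(d_{jk})$
over $k \ne j$ (selfing is structurally zero), $z$ standardised dbh, and
2-D exponential-power kernels
$P(r) = \frac{b}{2\pi a^2\Gamma(2/b)} e^{-(r/a)^b}$ evaluated in log space
via `lgamma`.  Kernel values enter the weights un-normalised over the plot
and are re-normalised across candidates: the within-plot normaliser cancels
in categorical weights, and immigration absorbs out-of-plot mass.
Fecundity is $e^{\gamma z}$ — the exponential-linear form keeps fecundity
positive and makes $\gamma$ a log-linear effect.  Mothers are treated as
unknown (both parents inferred), matching the mapped-offspring,
unmapped-pedigree design.

Genotype transition probabilities work on *observed* genotype classes,
marginalising null-allele masking: a parent observed $aa$ is true $aa$ with
posterior $p_a/(p_a+2\rho)$ and $a$/null otherwise; untyped parent loci
transmit a population gamete; an offspring's observed $aa$ sums the true
$aa$ and $a$/null routes; missing offspring loci are skipped.  The
immigrant gene pool defaults to the augmented mature frequencies (with the
same per-locus nulls) and is configurable.  Offspring whose genotype is
impossible under every component contribute through the background term
when $m_s > 0$, otherwise the log-likelihood is flagged $-\infty$.

Optimisation runs Nelder-Mead on a transformed scale — logit for $m_s, m_p$,
log for $a_s, a_p$, a logistic map of $b$ into $[0.05, 20]$ (keeping
$\Gamma$ arguments finite), identity for $\gamma$ — from a default start
plus jittered multi-starts (default 3, seeded).  SEs come from the inverse
observed information (finite-difference Hessian on the transformed scale,
delta method back); mean distances $d = a\,\Gamma(3/b)/\Gamma(2/b)$ and
their SEs by the delta method.  Information-based rather than bootstrap SEs
are a deliberate choice: the parameter-recovery experiments show the
transformed-scale Wald intervals are well calibrated at the problem sizes
used.  Boundary immigration estimates ($m \to 0, 1$) are flagged; with
fully immigrant data the kernel parameters are unidentified and their SEs
blow up accordingly.

The heavy, parameter-independent part — the Mendelian transition table for
every (mother, father, offspring) triple — is precomputed once
(`nm_precompute()`, ~50 MB for 123 × 123 × 400) and each likelihood
evaluation reduces to one vectorised product over that table, so a full fit
at 400 offspring takes on the order of a minute.

## Synthetic data generator

`sim_config()` defaults encode the study conditions the package is designed
around: a 200 × 250 m plot, 112 fallen logs (≥ 20 cm basal diameter,
lengths 5–30 m, uniform placement and orientation, clipped to the plot),
123 mature trees (uniform or Thomas-clustered; dbh = 20 cm + gamma(2, 15)
excess, i.e. mean ≈ 50 cm — the source system reports no dbh distribution,
so this is a stated assumption, not a claim about the site), 11 SSR loci
with 3–46 Dirichlet-sampled alleles, per-locus null frequencies uniform on
[0, 0.18], 1 % random missingness, offspring cohorts of 179 seedlings and
190 saplings established only on logs (establishment point uniform over
logs; a soil-establishment toggle exists but defaults off), seed kernel
(a = 3.823, b = 0.571), pollen kernel (a = 81.816, b = 3.097), seed/pollen
immigration 0.744/0.866, fecundity exponent γ = 1.2, selfing 0.  The
immigrant gene pool is a Dirichlet perturbation of the local frequencies
with divergence 0.02 (concentration $(1-d)/d$), since no external-pool
frequencies are available.  Everything is reproducible under `rng_seed`,
and true genotypes + pedigree ride along as attributes.

Mother and father sampling uses **exactly** the categorical weights the
likelihood uses, so the generator and the fitted model coincide and
parameter recovery is a self-consistent experiment.  What the generator
does *not* emulate: multi-year overlapping reproduction, spatial genetic
structure among the mature trees themselves, log decay dynamics, and
survival processes.  Consequently a single simulated generation under the
default (fat-tailed, high-immigration) kernels carries much weaker FSGS
than a real multi-cohort population under the same parameters — passing
tests demonstrate estimator correctness, not that the defaults reproduce
any particular field correlogram.

## Thinning simulations

From a pooled offspring set (default 369): (1) keep the 123 individuals
with lowest $F_{is}$ — ranked against the augmented mature reference, the
reference under which inbreeding was measured before "deaths" are imposed,
even though the survivors' FSGS statistics then drop the reference;
(2) 10 uniform random subsets of 123 without replacement; (3) remove all
offspring on the top-k most-colonised logs (k = 1..5) and on every log
with > 8 offspring (strict inequality).  Ties at rank boundaries break by
stable id/log-id order — a documented convention where no rule is
prescribed.  Each surviving dataset gets mean $F_{is}$ (one-sided
permutation p), $F_1$, $b_F$ (one-sided p), and Sp, all against its own
allele frequencies.

## Validation design and problem sizes

The test suite validates every estimator against an independent route:
brute-force loop implementations (kinship, Weir–Cockerham $f$ and θ),
exhaustive enumeration (rarefaction over all $\binom{N}{g}$ subsamples;
the HWE exact distribution on a 5-individual table), closed forms
(kernel identities, $d = 2a$ at $b = 1$), `lm()` on pair values for the
regression slope, and generative simulations with known truth (sib-family
kinship 0.125/0.25; inbreeding recovery; null-frequency recovery ±0.03 at
n = 500).  Quadrature checks of the mean dispersal distance integrate in
$u = (r/a)^b$ space, where adaptive quadrature is accurate across
$b \in [0.2, 5]$ (the raw radial integrand at $b = 0.2$ has mass out to
~10⁷ m).

Three simulation experiments use deliberately chosen sizes:

* *Parameter recovery*: 5 replicate fits at 400 offspring, 123 mature
  trees, 11 loci with nulls and missing data, truth
  $(m_s{=}0.5, a_s{=}10, b_s{=}1, m_p{=}0.5, a_p{=}40, b_p{=}1,
  \gamma{=}1)$; coverage of transformed-scale 95 % CIs is pooled over the
  7 × 5 intervals and required ≥ 90 % — per-parameter coverage over 5
  replicates would be a Bernoulli(≈0.95) sample too small to bound
  meaningfully.
* *Permutation calibration*: 100 replicates of a four-stage HWE design
  (30 individuals/stage, 6 loci) with 200 permutations per test; p-values
  are pooled across stages (400 for the $F_{is}$ test) and across
  correlogram distance classes (1000), so the 5 % ± 2 % band is several
  binomial SEs wide.  Measured rates land near 5.3 % and 5.7 %.
* *Thinning*: the scenarios are validated in a limited-dispersal regime
  (seed kernel a = 5 m, b = 1; $m_s = 0.3$) in which a single simulated
  generation carries strong FSGS; all 17 scenario datasets retain a
  significantly negative $b_F$ while inbred-removal drives mean $F_{is}$
  negative — the qualitative pattern demographic-thinning hypotheses
  predict to erase, and don't.

## Known limitations

* The joint $(f, \text{null})$ estimator is a profile-ML point estimate
  with $\beta = 0$; in panels where every locus carries similar null
  burdens it is weakly identified and should be read with its boundary
  flag.
* The neighborhood model conditions on observed genotype classes and skips
  missing offspring loci; informative missingness from null homozygotes is
  ignored (a ≤ ~2 % effect at the default null frequencies).
* Dispersal kernels are fixed to the exponential-power family; no
  competing families, no full parentage lists.
* The generator is single-generation; it cannot, by design, reproduce
  FSGS that arises from multi-cohort accumulation or from structure among
  the mothers.
* The admixture clustering itself (MCMC) is out of scope; its output
  (Q-matrices, run log-probabilities) is consumed via `read_structure_q()`
  and `evanno_delta_k()`.
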