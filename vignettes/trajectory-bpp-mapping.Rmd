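---
title: "Mapping genes with longitudinal phenotypes via trajectory subgroup posterior probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping genes with longitudinal phenotypes via trajectory subgroup posterior probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajbpp)
```

## The problem

Association studies usually test disease susceptibility at a single time
point. Severity and progression phenotypes — blood pressure over repeated
exams, spine curvature in scoliosis, declining renal function — are
longitudinal, and the signal of interest is often *which trajectory an
individual is on*, not any single measurement. trajbpp implements a
two-stage strategy:

1. **Cluster** the repeated measurements into latent trajectory subgroups
   with a group-based trajectory model (a finite mixture of polynomial
   growth curves).
2. **Test** each SNP against the Bayesian posterior probability (BPP) of
   belonging to the clinically relevant subgroup — the subgroup with the
   most extreme fitted value at the last time point — as a quantitative
   trait (population samples), or against its dichotomized version
   (family-based transmission test).

Power is evaluated with a replicate-set procedure: each set pairs one
discovery with two confirmatory phenotype replicates over fixed genotypes,
and a gene scores YES for a set only when every replicate shows a
qualifying marker inside the gene.

## The trajectory mixture model

Individual $i$ in latent subgroup $j$ has

$$y_{it} = \sum_{d=0}^{o_j} \beta_{jd}\, t^d + \gamma^\top x_{it} +
\varepsilon_{it}, \qquad \varepsilon_{it} \sim N(0, \sigma^2),$$

with subgroup probabilities $\pi_j$ and a residual SD $\sigma$ shared
across subgroups (the group-based trajectory convention; a group-specific
$\sigma$ is deliberately not offered because the shared-variance model is
what keeps small subgroups estimable at these sample sizes). The
individual-level density is the product over that individual's *observed*
visits — missing visits simply contribute nothing, and no imputation is
performed. The BPP is the posterior membership probability

$$\mathrm{BPP}_{ij} = \frac{\pi_j f_{ij}}{\sum_m \pi_m f_{im}}.$$

The likelihood is plain Gaussian: the trait is treated as uncensored.

### Estimation

`fitMixture()` runs EM with an exact M-step — weighted least squares for
the polynomial (and covariate) coefficients, closed-form updates for
$\pi$ and $\sigma$ — so the observed-data log-likelihood is non-decreasing
across iterations (asserted by the test suite on the stored trace).
Convergence is declared when the log-likelihood changes by less than
`tol = 1e-8`, with a cap of 500 iterations; a run that exhausts the cap is
flagged non-converged. Restarts initialize from k-means on the
per-individual mean values, with randomly perturbed assignments for later
restarts, and the best converged restart wins. $\sigma$ is floored at
`1e-6` times the pooled trait SD to rule out degenerate zero-variance
spikes. During optimization $\pi$ lives on a multinomial-logit scale, so
the simplex constraint is never active.

Coefficient p-values come from the numerical observed information
(central-difference Hessian of the log-likelihood in the packed
parameterization) with standard-normal Wald tests. With only $T$ distinct
visit times a polynomial of degree $\ge T$ is unidentifiable; the fitter
pins those coefficients at zero and their (undefined) Wald p-values are
treated as non-significant by the pruning rule. This matters in the
default three-visit design, where the "all-cubic" first run is effectively
quadratic.

### Two-run order pruning and BIC selection

`selectModel()` follows the two-run protocol for each $k = 1..k_\max$:
fit with cubic polynomials in every subgroup, then reduce each subgroup's
order to the highest degree whose coefficient is still significant at the
5% level (never removing the intercept; order 0 if no degree survives),
and refit. Covariates, when requested, enter only at the final fit. The
model with the highest BIC wins, with

$$\mathrm{BIC} = \log L - \tfrac{p}{2}\,\log N,$$

$N$ the number of *individuals* (an observation-count variant sits behind
`mixControl(bicN = "observations")`). Ties break toward smaller $k$.
Covariate coefficients are group-specific by default (`"shared"` is a
config option), and the default time scale is the visit index 0, 1, 2 —
age enters as a covariate, not as the clock. Both choices were genuinely
open; group-specific coefficients are the more flexible default and the
visit-index clock keeps polynomial coefficients comparable across
individuals of different ages.

## The derived phenotype

`pickRelevantSubgroup()` ranks subgroups by their fitted polynomial at the
last time point, covariates held at reference level zero (how covariates
should enter a "predicted" value is unspecified in the protocol; the
reference-level convention makes the ranking a property of the trajectory
shapes alone). Ties abort with an error listing the tied subgroups — there
is no defensible automatic tie-break. For declining phenotypes,
`direction = "lowest"` selects the other extreme.

`dichotomize()` maps BPP > 0.5 to affected and BPP < 0.5 to unaffected;
exactly 0.5 is labelled affected (inclusive upper rule, configurable via
`boundary =`). In practice the BPP distribution is sharply bimodal for
well-separated subgroups — the test suite requires less than 10% of mass
in [0.2, 0.8] — so the boundary case is essentially theoretical, and the
affected set is invariant under any strictly monotone transform of the
BPP. A Box-Cox normalization (`transformTrait()`, profile-likelihood
$\hat\lambda$) is available but off by default: with a bimodal trait the
regression results are insensitive to it.

## Association tests

- **Population arm**: per-SNP simple linear regression of the BPP trait on
  dosage, two-sided Wald $t$ on $n-2$ df, with Benjamini–Hochberg FDR
  q-values (`waldScan()`).
- **Family arm, quantitative**: the same Wald statistic, with an empirical
  p-value from shuffling trait values *within families* (structure
  preserved), using the add-one estimator
  $(1 + \#\{|t^*| \ge |t|\})/(B+1)$ so p-values are never zero
  (`qfamPermTest()`, `qfamScan()`).
- **Family arm, dichotomous**: the transmission disequilibrium test on the
  dichotomized BPP: transmissions of the coded allele from heterozygous
  parents to affected offspring are counted over all extractable trios and
  $\chi^2 = (b-c)^2/(b+c)$ is referred to $\chi^2_1$ (`tdtTest()`). Trios
  with missing genotypes are dropped per SNP; Mendelian-inconsistent trios
  are skipped and tallied. Locus-heterogeneity extensions of the TDT are
  out of scope — the underlying comparison found no statistical difference
  between such an extension and standard tests on these phenotypes — so
  the classical b/c TDT with permutation correction stands in.
- **Multiple testing in the family arm**: max-statistic permutation
  (`permCorrectFamily()`): per permutation, transmissions are
  re-randomized ($b^* \sim \mathrm{Bin}(b+c, 1/2)$ per SNP) or traits
  re-shuffled within families, and the maximum statistic over SNPs is
  recorded. Corrected p-values therefore dominate the pointwise empirical
  ones by construction.

Dependence among relatives inside a family is absorbed by the permutation
null rather than modelled (mixed-model association is out of scope).

## Replicate-set power

`buildReplicateSets()` draws each set's replicate ids without replacement
*within* the set; sets are independent, so ids recur across sets (with a
pool of 200 and 100 sets of 3 they must). `geneHit()` supports both
criteria: `alpha_threshold` (some in-gene SNP with $p \le \alpha$; family
convention) and `top_percent` (some in-gene SNP ranked within the top
$x\%$ of all SNPs tested in that replicate's analysis run — the ranking
universe is the analysis run, not the genome, matching a
region-of-interest design; minimum-rank tie handling). A set is YES for a
gene only if all three replicates hit; per-gene power is the YES fraction,
total power the mean over non-null genes, and null regions (no simulated
functional loci) estimate empirical type-I error.
`compareConditions()` runs a *paired* t-test over genes between two
conditions (covariates vs none); pairing over genes is the natural choice
since both conditions score the same genes, and an unpaired variant sits
behind `paired = FALSE`. Constant differences yield a reason code instead
of a statistic.

Gene coordinates are 1-based inclusive in memory; BED input/output is
0-based half-open and converted on read/write.

## The synthetic cohort generator

The reference data (simulated systolic blood pressure for 850 members of
20 extended pedigrees plus 157 unrelated individuals, 3 visits, 200
replicates) are access-restricted, so `simConfig()` +
`simulateGenotypes()` + `simulatePhenotypeReplicate()` emulate their
*shape*:

- **Pedigrees**: 20 three-generation families of 42 (founder couple, 5
  children married to founder spouses, 6 grandchildren per couple) plus
  157 unrelated singletons. Founder genotypes are Binomial(2, MAF) in
  linkage equilibrium; descendants are gene-dropped, so the data are free
  of Mendelian errors by construction. Genotypes are fixed across
  replicates.
- **Trajectory truth**: three subgroups with linear blood-pressure-like
  trajectories (intercepts 112/128/148 mmHg, slopes 0.5/1.5/3.5 per
  visit), $\pi = (0.55, 0.35, 0.10)$ — a small high-pressure subgroup of
  10%, comparable to the ~9% high subgroup reported for the reference
  analyses — and $\sigma = 10$ mmHg, which leaves genuine overlap between
  adjacent subgroups (population SBP residual variation of this order is
  realistic, and without overlap the BPP would carry no graded
  information).
- **Covariates**: age (baseline ~ N(45, 10) years, +2.5 per visit, +0.25
  mmHg/yr), smoking (24% prevalence, +4 mmHg), antihypertensive
  medication (log-odds higher in the high subgroup, −8 mmHg), sex (+3
  mmHg for males). Covariates and noise are re-drawn per replicate;
  genotypes are not.
- **Genetic effects**: each causal gene carries one causal SNP by default.
  In `level-shift` mode the centered causal burden adds a constant shift
  to every visit, scaled so the gene's share of total trait variance hits
  its `causalVE` target (headline gene 6%, mirroring the strongest gene
  in the reference data); the scaling uses the realized burden variance,
  and the test suite verifies the realized share by a same-seed
  with/without-effect decomposition. In `group-logit` mode the burden
  shifts the log-odds of high-subgroup membership instead — a
  misspecification stressor, since the analysis model assumes nothing
  about how genotype enters.

What the generator does **not** emulate: linkage disequilibrium (SNPs are
independent; an LD chain was considered and left out because power, not
fine-mapping, is the test surface), sequence-level variation, imputation
artifacts, and whatever generative model actually produced the reference
phenotypes. Passing tests therefore show that the pipeline recovers
effects *of the kind it models* at realistic sizes — not that it would
reproduce the reference study's exact power table.

## Numerical choices and degenerate inputs

- EM tolerance 1e-8 on the log-likelihood change; 500-iteration cap;
  non-convergence is an error in the first (pruning) run and a flagged
  result elsewhere.
- $\sigma$ floor: 1e-6 × pooled trait SD.
- WLS via normal equations (designs are tiny and well-scaled), with a QR
  fallback and previous-iterate rescue for singular weight patterns.
- Observed-information Hessian inverted with a Moore–Penrose fallback for
  near-singular fits; undefined standard errors yield NA p-values.
- Empirical p-values use the add-one estimator; permutation comparisons
  use a 1e-12 slack so ties count as exceedances.
- Constant genotypes give NA p-values with a reason code rather than an
  error; fewer than 3 complete pairs is an error.
- BPP exactly 0.5 labels affected; out-of-range BPPs are an error.

## Problem sizes used by the test suite

The suite runs the full method at deliberately scaled sizes chosen to keep
the statistical checks sharp: 50 datasets of N = 600 for subgroup-count
recovery; 2000 SNPs (Wald), 5000 sets of 3000 trios (TDT null law) and
500 SNPs × 999 permutations (within-family calibration) for the null
checks; and an end-to-end grid of three effect sizes (1%, 6%, 20% variance
explained) on 300 unrelated individuals, 6 replicates and 8 sets per
condition. The acceptance script runs 6 pedigrees + 300 unrelated, 60
SNPs, 12 replicates and 8 sets per arm. At these scales the family-arm
TDT has few informative affected-offspring trios and its power is
expected to sit near zero under the level-shift generator; the
population arm retains moderate power for the 6% gene.

## Known limitations

- The BPP trait is a *derived* quantity: its association power depends on
  how strongly the causal mechanism moves subgroup membership. A level
  shift far smaller than the subgroup separation barely moves the BPP,
  attenuating power relative to testing the raw trait.
- Mixture Wald p-values rely on regular asymptotics that weaken when
  subgroups nearly coincide or a mixing proportion approaches zero.
- Overfitted $k$ frequently fails the 1e-8/500-iteration convergence rule
  (slow likelihood crawl along a ridge); `selectModel()` treats such k as
  failed candidates, which in practice also keeps the BIC race honest.
- No LD, no X-chromosome rules, no binary PLINK formats, no mixed-model
  kinship correction.
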