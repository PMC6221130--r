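---
title: "Assortative mating as a bias source in Mendelian randomization: the model behind triomr"
author: "triomr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assortative mating as a bias source in Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomr)
```

## The problem

Mendelian randomization (MR) uses germline genetic variants as instrumental
variables for a modifiable exposure $X$ to estimate its causal effect on an
outcome $Y$. The design rests on the variants being independent of
confounders and affecting $Y$ only through $X$. Nonrandom spouse pairing
breaks the first part in a subtle way: if people with high $X$ tend to marry
people with high $Y$ (*cross-trait* assortative mating), then mothers'
exposure-associated alleles become correlated with fathers'
outcome-associated alleles, and the offspring inherit both. In the offspring
generation the exposure score is then genuinely associated with the genetic
component of $Y$ through a path that has nothing to do with a causal effect
of $X$, and a standard MR analysis reports a nonzero effect where none
exists.

`triomr` provides (i) a forward-in-time simulator of mother–father–offspring
trios under configurable assortment patterns, (ii) the trio-based estimators
that detect and remove this bias, and (iii) a Monte-Carlo harness that
measures bias, false-rejection rate and power over replicated scenarios.

## The generative model

Founders carry `n_snps_X` biallelic SNPs with direct effects on $X$ (the GX
set) and `n_snps_Y` SNPs with direct effects on $Y$ (GY), unlinked, with
effect-allele frequencies drawn once per scenario from
$\mathrm{Uniform}(\texttt{maf\_low}, \texttt{maf\_high})$ (default 0.1–0.5)
and haplotypes drawn under Hardy–Weinberg and linkage equilibrium.
Phenotypes follow

$$X = \delta_X Z_X + \sqrt{c}\,U + e_X, \qquad
  Y = \beta_{XY} X + \delta_Y Z_Y + \sqrt{c}\,U + e_Y,$$

where $Z_X$ is the unweighted effect-allele count over GX,
$\delta_X = \sqrt{h^2_X / \mathrm{var}_0(Z_X)}$ with
$\mathrm{var}_0(Z_X)=\sum_k 2p_k(1-p_k)$ the theoretical founder variance,
$U \sim N(0,1)$ is a shared confounder contributing a fraction $c$
(`confounder_share`, default 0.2) of phenotypic variance, and the error
variances are chosen so founder phenotypes have unit variance. $\delta_X$
and $\delta_Y$ are *structural* constants: under assortment the realized
genetic and phenotypic variances drift upward while $\delta$ stays fixed,
so realized heritabilities exceed their nominal values slightly — a known
property of phenotypic assortment models, and deliberately not corrected.

Two defaults deserve comment because no external source pins them down.
The frequency band 0.1–0.5 covers common variants as used in typical
genome-wide scores; the bias of interest is driven by the total score
variance, not the panel composition, and the harness verifies that
empirically (instrument-count invariance). The confounder share 0.2 makes
naive observational estimation visibly confounded while leaving most
variance to genetics and noise; because $U$ is independent of all
genotypes, it affects the precision of estimators but not assortment bias
itself. Both remain configurable.

### Assortment

Assortment is phenotype-driven through noisy *proxies*: each person's
sorting proxy equals the phenotype plus Gaussian noise scaled so that
$\mathrm{cor}(X, X_P) = P$. $P \in (0,1]$ is the single knob for assortment
strength; everything else that goes into partner choice is absorbed in the
proxy noise. Random mating is expressed as pattern `none`, not as $P = 0$.

Pairing mimics a bidirectional market: couples are formed at random, split
at random into two equal sets, and within each set the women and men are
sorted and matched rank-for-rank — in one set women sort on the trait-A
proxy and men on the trait-B proxy, in the other the roles are swapped
(for single-trait assortment both sexes sort on the same proxy in both
sets). Within a set the Spearman correlation of the paired sorting proxies
is exactly 1; the phenotypic spouse correlation is then governed entirely
by $P$. At $P = 0.7$ the realized cross-spouse correlation
$\mathrm{cor}(X_m, Y_f)$ is about 0.26, i.e. plausible strengths of
assortment ($P \approx 0.4$–$0.7$) correspond to observable spouse
correlations of roughly 0.1–0.3. The harness records the realized spouse
correlations of every run so this mapping can always be recomputed.

### Generations

Each couple has two children (one daughter, one son), keeping population
size and sex balance constant; the next generation re-assorts and mates.
"One generation of assortment" means founders paired assortatively and
their offspring analyzed. The population is closed: no migrants enter, and
sibling pairing in later generations is not explicitly forbidden (its
probability is negligible at the default 40,000 couples). This
closed-population rule is an assumption — other constructions (e.g. fresh
unrelated migrants each generation) would damp the build-up of genetic
variance and yield somewhat smaller multigeneration biases. Under it,
genetic variance and the spouse-genotype correlation grow over generations
and the MR bias accumulates with shrinking increments.

For every mating, one allele per SNP per parent is transmitted with
probability 1/2; the other allele is recorded (implicitly, as parent
genotype minus transmitted) as *nontransmitted*. The analyzed trio takes
one of the two children at random.

## Estimators

All estimation is proper two-stage least squares (`fit_2sls()`): the
coefficient covariance accounts for first-stage estimation error rather
than treating predicted exposures as data, with an optional
heteroskedasticity-robust (HC1) variant for real-data use.

Per-SNP instrument weights are the slopes of simple regressions of
offspring exposure on offspring genotype, estimated in a random half (A) of
the trios; scores are built in the other half (B), which avoids overfitting
the instrument to the analysis sample. `build_scores()` refuses to score
the training half unless explicitly overridden. The weighted allele score
is $S=\sum_k \omega_k g_k$, with the identical weights applied to parental
genotypes ($S^m, S^f$) and to the parents' nontransmitted haplotypes
($W^m, W^f$).

* **tsls1** — plain allele-score MR: $Y$ on $X$, instrument $S$, no
  covariates. Biased under cross-trait assortment.
* **tsls2** — adds $S^m$ and $S^f$ as exogenous covariates in both stages.
  Conditioning on the parents' measured instrument genotypes blocks the
  backdoor path opened by assortment, so only the instrument SNPs (not all
  genetic influences) need to be measured — in the offspring *and* the
  parents. The joint 2-df Wald test of the parental-score coefficients in
  the outcome equation is the assortment test; the signed coefficients
  indicate its direction.
* **tsls3** — three endogenous regressors (offspring, mother, father
  exposure phenotypes) instrumented by $S$, $W^m$, $W^f$. The offspring
  coefficient is the causal effect; the parental coefficients estimate
  direct (dynastic) parental effects, and their joint Wald test doubles as
  an assortment/dynastic-effect detector. Requires parental exposure
  phenotypes (available in simulation; must be supplied in real data).

For summary statistics the package provides fixed-effect IVW, MR-Egger
(weights $1/SE(\hat\beta_Y)^2$, multiplicative residual dispersion floored
at 1, no SIMEX), the weighted median (cumulative-weight midpoint
interpolation at 50%, parametric-bootstrap SE) and the mode-based estimate
(Gaussian kernel, bandwidth $\varphi$ times the modified Silverman rule
$0.9\min(\mathrm{sd},\mathrm{mad})J^{-1/5}$, $\varphi = 1$, weighted form
by default, bootstrap SE). These estimators assume instrument-specific
pleiotropy patterns; assortment shifts *all* Wald ratios coherently, so
none of them is robust to it, and Cochran's Q sees no heterogeneity. The
extra diagnostic that does see it is the correlation test between exposure
and outcome allele scores built from disjoint SNP sets
(`score_correlation_test()`). Summary statistics are one-sample by default
(exposure and outcome regressions in the same half); a two-sample mode
(independent halves) sits behind a flag since the one- vs two-sample choice
is a genuine design fork.

For user-supplied trio tables without phase, nontransmitted counts are
inferred by Mendelian logic; the only indeterminate configuration (all
three members heterozygous) receives the expected value 1/2 and is counted
per trio.

## The Monte-Carlo harness

`run_scenario()` derives one seed per replicate from the master seed
(`seed + 40003·replicate` modulo $2^{31}-1$), so every replicate is
reproducible in isolation and results are independent of execution order or
worker count. Failures are recorded per replicate, never fatal.
`summarize_scenario()` reports mean estimate, bias, empirical SE (SD over
replicates), mean model SE, false rejection (95% CIs excluding the truth),
power (CIs excluding zero) and the assortment-test rejection rate, plus the
Monte-Carlo SE of the bias.

Preset grids mirror the study designs: `table1` (one-generation cross-trait
grid over $P$, $h^2_Y$, instrument size and GY size), `table2` (random
mating with a true effect of 0.05), `figure2`, `figure3` (one to nine
generations), and auxiliary-trait suites in which the assorted traits are
genetically correlated with $X$ and/or $Y$ through *horizontal* pleiotropy
(a loading on the genetic score shared by all variants of a set) or
*vertical* pleiotropy (a loading on the phenotype). In the auxiliary-trait
presets the loadings are 1 with unit noise, chosen so the assorted trait is
appreciably but not perfectly genetically correlated with the focal traits;
the default strength for those suites and for `figure3` is $P = 0.7$, the
upper end of the plausible range above.

Replicate counts are configurable; defaults of 500 (one-generation
scenarios) and 200 (nine-generation scenarios) put the Monte-Carlo SE of a
bias estimate near 0.001, an order of magnitude below the tolerances of
interest. The nine-generation property check inside the test-suite uses
5,000 couples rather than 40,000 — the accumulation *shape* (monotone, with
shrinking increments) does not depend on population size, while the
headline bias *values* are always computed at the full 40,000. Likewise the
nine-generation headline runs carry 10 rather than 50 GY SNPs: the
outcome's genetic variance is calibrated to $h^2_Y$ regardless of how many
variants carry it, so the bias is invariant to GY panel size (the
one-generation grid verifies the analogous instrument-size invariance
explicitly, and we checked the nine-generation invariance empirically:
0.125 with either panel).

## Numerical and implementation notes

* The haplotype-draw, meiosis and trio-assembly kernels are written in C++
  (Rcpp) and consume R's Mersenne–Twister stream via `unif_rand`, so all
  results are governed by `set.seed()`. Fair coins and Bernoulli draws
  slice the 32 random bits of each uniform (with exact boundary refinement
  for the Bernoulli thresholds), which matters at 10⁷ meioses per
  replicate.
* 2SLS is solved by QR projection; rank deficiency of the instrument set or
  of the projected design raises a typed identification error rather than
  producing unstable estimates. Degenerate inputs (monomorphic SNPs in
  weight training, zero exposure associations in Wald ratios, constant
  exposure associations in Egger) are reported and handled explicitly.
* Confidence intervals are normal-theory ($\pm 1.96\,SE$) throughout;
  weighted-median and MBE standard errors come from a parametric bootstrap
  of the summary statistics (1,000 draws by default, reducible).
* Per-SNP weights are re-estimated in every replicate, so weight noise is
  part of the Monte-Carlo variance, as it would be in practice.

## What the simulations do and do not show

The simulator produces unlinked common variants with purely additive
effects, Gaussian phenotypes, a single shared confounder and
phenotype-proxy assortment with a fixed strength each generation. Real data
add linkage disequilibrium, rare variants, non-additive effects,
socially/geographically structured homogamy that is not phenotype-driven,
dynastic effects, and secular changes in assortment. Passing the package's
checks therefore demonstrates the internal logic of assortment bias and its
trio-based correction under this model — not that a particular empirical
spouse correlation is caused by assortment, nor the magnitude of bias in
any specific real cohort. The multigeneration bias values additionally
depend on the closed-population rule described above.

## A worked example

```{r example, eval = FALSE}
library(triomr)

cfg <- scenario_config(
  n_trios = 40000, n_snps_X = 50, n_snps_Y = 10,
  h2_X = 0.5, h2_Y = 0.5, beta_XY = 0, P = 1,
  assortment = assortment_spec("cross_trait", "X", "Y"),
  n_instrument_snps = 10)

records <- run_scenario(cfg, n_reps = 100, methods = c("tsls1", "tsls2"),
                        seed = 101)
summarize_scenario(records)
```

Under the strongest cross-trait assortment the plain allele-score estimator
shows a bias of about +0.13 with every 95% CI excluding the true null,
while the parental-score-adjusted estimator is unbiased with a ~5% false
rejection rate and its assortment test rejects in essentially every
replicate.
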