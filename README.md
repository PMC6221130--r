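# triomr

Forward-in-time simulation of assortative mating in mother–father–offspring
trios, and trio-based Mendelian-randomization (MR) estimators that detect and
correct the bias it induces.

## The problem

MR estimates the causal effect of an exposure *X* on an outcome *Y* using
germline variants as instruments. Cross-trait assortative mating — e.g. high-*X*
women preferentially partnering high-*Y* men — correlates the mother's
exposure-associated alleles with the father's outcome-associated alleles.
Offspring inherit both, so in the analyzed generation the exposure allele score
is associated with the genetic component of *Y* through a non-causal path, and
plain MR is biased. Because every instrument is shifted coherently, the
standard pleiotropy-robust toolbox (IVW, MR-Egger, weighted median, mode-based
estimate, Cochran's Q) neither avoids nor detects the bias. Genotyping the
*parents* of study subjects does both.

## The model and estimators

The simulator draws unlinked biallelic SNP panels GX and GY, builds phenotypes

&nbsp;&nbsp;*X* = δ_X·Z_X + √c·U + e_X,&nbsp;&nbsp;&nbsp;
*Y* = β_XY·X + δ_Y·Z_Y + √c·U + e_Y,

with δ_X = √(h²_X / var₀(Z_X)) calibrated so the narrow-sense heritability of
the unit-variance founder phenotype is h²_X (var₀(Z_X) = Σ 2p(1−p)), pairs
spouses by rank-matching noisy phenotype proxies with cor(X, X_P) = P via a
bidirectional two-set sorting scheme, transmits one allele per SNP per parent
to each of two children, and iterates over generations in a closed population.

Estimation is two-stage least squares with a split-half weighted allele score
(weights trained in one random half, scores built in the other):

* `tsls1` — plain allele-score MR (biased under cross-trait assortment);
* `tsls2` — parental allele scores as covariates in both stages; their joint
  2-df Wald test is a test for the presence and direction of assortment bias;
* `tsls3` — offspring, mother and father exposures instrumented by the
  offspring score and the parents' *nontransmitted* allele scores, separating
  the causal effect from parental (dynastic) effects.

Summary-data estimators (IVW, MR-Egger, weighted median, MBE), heterogeneity
diagnostics and an exposure/outcome score-correlation test are included, as are
delimited-text readers/writers for trio tables, weights and summary statistics,
a YAML scenario-configuration format, and a CLI (`inst/cli/triomr`) with
`simulate`, `estimate` and `experiment` subcommands.

## A worked example

```r
library(triomr)

cfg <- scenario_config(
  n_trios = 40000, n_snps_X = 50, n_snps_Y = 10,
  h2_X = 0.5, h2_Y = 0.5, beta_XY = 0, P = 1,
  assortment = assortment_spec("cross_trait", "X", "Y"),
  n_instrument_snps = 10)

summarize_scenario(run_scenario(cfg, 100, c("tsls1", "tsls2", "tsls3"),
                                seed = 101))
```

```
Scenario summary (true beta = 0)
 method n_reps mean_estimate      bias mcse_bias empirical_se mean_model_se
  tsls1    100      0.127190  0.127190  0.002316      0.02316       0.02192
  tsls2    100     -0.002019 -0.002019  0.003471      0.03471       0.03184
  tsls3    100     -0.002455 -0.002455  0.003461      0.03461       0.03160
 false_rejection power assort_rejection
            1.00  1.00               NA
            0.06  0.06                1
            0.07  0.07                1
mean between-spouse correlations: XX = 0.200, XY = 0.519, YX = 0.521, YY = 0.200
```

Read: under maximal cross-trait assortment (P = 1) and *no* true causal effect,
plain allele-score MR reports ≈ +0.13 (in phenotype-SD units) and rejects the
true null in every replicate, while both trio-adjusted estimators are unbiased
with ≈5% false rejection — and their assortment test fires in 100% of
replicates. The realized between-spouse correlations (cor(X_m, Y_f) ≈ 0.52
here) are reported for every scenario so assortment strength can be mapped to
observable spouse correlations.

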