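# muqtl — mixture-of-uniforms shrinkage for QTL mapping and genomic prediction

`muqtl` implements Bayesian variable selection for dense SNP panels with a
**mixture-of-uniforms (MU)** prior on marker effects — a step-function
spike-and-slab. It targets two audiences at once: quantitative geneticists
mapping QTL, who need calibrated evidence per marker, and breeders doing
genomic prediction, who need accurate genomic estimated breeding values
(GEBV). Both run off the same saturated regression

```
Y_kj = alpha + sum_m beta_m x_kjm + u_k + e_kj,    e_kj ~ N(0, sigma^2)
```

with every SNP in the model simultaneously and, optionally, a random
full-sib family effect `u_k ~ N(0, sigma_u^2)`. Each effect gets the MU
prior

```
p(beta_m) = p0 * 1/(2b) * I(-b,b)(beta_m)
          + (1-p0)/2 * 1/(l-b) * [ I[-l,-b](beta_m) + I[b,l](beta_m) ]
```

so "no association" is the explicit event `|beta_m| < b` with prior
probability `p0`, and the Bayes factor for marker inclusion is posterior
odds over prior odds `(1-p0)/p0` — rigorous hypothesis testing inside a
shrinkage model, with Kass–Raftery categories on the `2 ln BF` scale.

The package provides:

* a single-site **Gibbs sampler** (`run_gibbs()`) whose marker conditionals
  are three-component truncated-normal mixtures, with an O(N) incremental
  residual per update (compiled core);
* a deterministic **GEM fixed-point estimator** (`gem_fit()`) iterating the
  fully conditional expectations — seconds instead of hours, bit-exactly
  reproducible;
* **inference**: inclusion probabilities, Bayes factors, evidence
  categories, posterior QTL count `N_Q`, marker heritability `h_M^2`,
  per-marker %PVE, and consensus mean-rank aggregation across chains run
  under different priors (`marker_report()`, `mean_rank_consensus()`,
  `chain_comparison()`);
* **prediction**: GEBV, accuracy/rank/bias metrics, 10-fold
  cross-validation with family-aware fold schemes, SIS pre-screening and
  "poor man's model averaging" of GEBV across prior specifications
  (`run_cv()`, `average_gebv()`, `sis_select()`);
* **prior calibration** from expected heritability
  (`prior_h2_std()`, `prior_h2_unstd()`, `prior_mean_nq()`);
* a pedigree-aware **simulator** (`simulate_population()`) — sire × dam
  matings, full-sib families, Haldane recombination over an equidistant SNP
  map, additive QTL and known true breeding values — so the whole stack is
  testable end to end without external data;
* readers for delimited genotype/phenotype/family tables and the PLINK RAW
  additive-dosage dialect, plus a command-line front end
  (`inst/scripts/muqtl-cli.R` with subcommands `simulate`, `gibbs`, `gem`,
  `bf`, `predict`, `cv`).

## Worked example

Simulate a desk-scale population (540 training individuals in 90 full-sib
families, 500 SNP on 2 chromosomes, 10 additive QTL, heritability 0.30),
map QTL with the sampler, then predict the next generation:

```r
library(muqtl)
sim <- simulate_population(qtlmas_like_preset("desk", seed = 42))
#> mu_sim: 540 training + 540 validation individuals, 500 markers, 10 QTL (realized h2 = 0.310)

std   <- standardize_fit(sim$panel, sim$phen)   # mean 0, variance 1, training scale kept
spec  <- mu_prior_spec(p0 = 0.99, b = 0.01, l = 1)
chain <- run_gibbs(std$panel, std$phen, spec,
                   cfg = gibbs_config(n_iter = 20000, burn_in = 2000,
                                      thin = 20, seed = 1))
rep <- marker_report(chain, maf = panel_maf(sim$panel), var_y = 1)
head(rep[order(-rep$two_ln_bf),
         c("marker", "p_incl", "two_ln_bf", "category", "beta_mean", "pve")], 5)
#>     marker    p_incl two_ln_bf    category  beta_mean      pve
#> 49   snp49 0.9994444  24.18021 very strong  0.2436293 2.951721
#> 120 snp120 0.9933333  19.19813 very strong -0.2162004 2.221930
#> 240 snp240 0.9922222  18.88759 very strong  0.2026542 1.381845
#> 478 snp478 0.9900000  18.38048 very strong -0.2081122 2.229471
#> 115 snp115 0.9788889  16.86348 very strong  0.2018605 2.009643
```

All five top-ranked markers are true simulated QTL (`sim$truth`): the
`2 ln BF` column is the evidence scale (`> 10` = "very strong"), `p_incl`
the posterior probability that the effect escapes the spike, and `pve` the
marker's share of phenotypic variance in percent. The whole-model
summaries recover the simulated architecture:

```r
marker_h2(chain, var_y = 1)$mean   # heritability captured by markers
#> 0.287                            # truth: 0.30
nq_summary(chain)$mean             # posterior QTL count (10 simulated)
#> 8.4
```

The GEM estimator gives near-identical effect estimates in milliseconds,
and its GEBV predict the unphenotyped validation generation well:

```r
fit <- gem_fit(std$panel, std$phen, spec)
#> converged in 16 iterations (final deviation 2.11e-05, tol 5.02e-05)
g <- gebv(fit$state$beta, sim$panel_validate, scaling = std$scaling)
c(accuracy   = accuracy_tbv(g, sim$truth$tbv_validate),
  top_decile = top_decile_rank_corr(g, sim$truth$tbv_validate),
  bias       = bias(g, sim$truth$tbv_validate))
#>   accuracy top_decile       bias
#>      0.812      0.529      0.870
```

Accuracy is the Pearson correlation between GEBV and true breeding values;
`top_decile` is the Spearman correlation among the 10% best animals (the
selection candidates); bias is the slope of TBV on GEBV (1 = unbiased).
Because results depend on the prior, run several specifications
(`run_gibbs_chains()` with a list of specs), compare them with
`chain_comparison()`, rank markers by `mean_rank_consensus()` and average
GEBV with `average_gebv()`.

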