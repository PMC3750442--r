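---
title: "Mixture-of-uniforms shrinkage: model, algorithms and design choices"
author: "muqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-of-uniforms shrinkage: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muqtl)
```

## The model

`muqtl` fits the saturated marker regression

$$
Y_{kj} \;=\; \alpha + \sum_{m=1}^{M} \beta_m x_{kjm} + u_k + \varepsilon_{kj},
\qquad \varepsilon_{kj} \sim N(0, \sigma^2),
$$

for individual $j$ in full-sib family $k$, where $x_{jm}$ is the genotype
dosage at SNP $m$ (coded $-1/0/1$, or standardized to mean 0 and variance 1)
and $u_k \sim N(0, \sigma_u^2)$ is an optional random family effect
absorbing polygenic resemblance between full sibs. All markers enter the
model simultaneously; identifiability comes from a shrinkage prior on each
effect, the mixture of three uniforms (MU):

$$
p(\beta_m) \;=\; p_0 \cdot \frac{1}{2b}\,I_{(-b,b)}(\beta_m) \;+\;
\frac{1-p_0}{2} \cdot \frac{1}{l-b}\left[ I_{[-l,-b]}(\beta_m) +
I_{[b,l]}(\beta_m) \right].
$$

This step function is a spike-and-slab: mass $p_0$ sits on the narrow spike
$(-b, b)$ — effects too small to matter — and the rest is spread flat over
the two slabs up to the hard limit $l$. Unlike most shrinkage priors the MU
family makes the null hypothesis explicit: the event
$S_m = I_{[b,l]}(|\beta_m|)$ ("marker $m$ is associated") has prior
probability exactly $1 - p_0$, which is what makes Bayes factors
well-defined without indicator variables in the likelihood.

### Hyper-parameters

| parameter | meaning | unit | typical values |
|---|---|---|---|
| `p0` | prior probability of no association | — | 0.9–0.9999 |
| `b`  | border between negligible and relevant effects | trait units (or sd after standardization) | 0.001–0.036 |
| `l`  | hard cap on the absolute effect | trait units | `sd(Y)`, i.e. 1 on the standardized scale; 2 for conservative use |
| `c`  | prior variance of the intercept | trait$^2$ | $10^6$ (effectively flat) |
| `s, r` (and `s_u, r_u`) | inverse-gamma shape/rate for $\sigma^2$ ($\sigma_u^2$) | — | 0.01 each |

With $s = r = 0.01$ the variance priors have no mean, but a mode at
$r/(s+1) = 1/101$; they approach the scale-invariant $1/\sigma^2$ prior as
both tend to 0. The intercept variance `c` deliberately does not scale with
$\sigma^2$.

### Calibrating the prior through heritability

Under Hardy–Weinberg and linkage equilibrium with QTL at marker positions,
a common prior effect variance implies a heritability. For the MU prior,

$$
\mathrm{Var}(\beta_m) = \tfrac{1}{3}\!\left[\, b^2 + l(l+b)(1-p_0) \,\right],
\qquad
h^2 = \frac{2\,\mathrm{Var}(\beta_m) \sum_m f_m(1-f_m)}{V_P}
\;\;\xrightarrow{\text{standardized }x}\;\;
\frac{\mathrm{Var}(\beta_m)\, M}{V_P}.
$$

`prior_h2_std()` and `prior_h2_unstd()` return these values unclipped —
values far above 1 are diagnostic of an over-dispersed prior rather than an
error, and prior specifications that imply "impossible" heritabilities can
still predict well:

```{r}
sapply(list(mu_prior_spec(0.99, 0.01, 1), mu_prior_spec(0.999, 0.001, 1),
            mu_prior_spec(0.9999, 0.008, 2)),
       function(s) prior_h2_std(s, M = 5894))
```

## Estimation

### Gibbs sampler

`run_gibbs()` is a systematic-scan single-site sampler. The conditional
posterior of one effect, given everything else, is a Gaussian likelihood
$N(\tilde\mu_m, \tau_m^2)$ — with $\tilde\mu_m = x_m^\top r_m / x_m^\top x_m$
computed from the partial residual $r_m$ and
$\tau_m^2 = \sigma^2 / x_m^\top x_m$ — multiplied by the step prior. That
product is a three-component mixture of truncated normals, one component per
prior interval, with weights proportional to the step height times the
Gaussian mass on the interval (`trunc_mixture()`). The intercept and family
effects have conjugate normal conditionals, the variances conjugate
inverse-gamma conditionals with shapes $s + N/2$ and $s_u + K/2$.

Numerical choices, all fixed and tested:

* Component weights are computed in log space with complementary-CDF forms
  in the far tails; the weights remain normalized for $|\tilde\mu_m|$ a
  thousand conditional standard deviations from the support. If all three
  log-masses underflow, mass falls back to the component containing (or
  nearest) $\tilde\mu_m$.
* Truncated-normal draws use the inverse CDF on the log scale of the
  nearer tail, with uniforms clamped to $[10^{-15}, 1-10^{-15}]$ so a
  draw can never return $\pm\infty$.
* The residual vector is maintained incrementally (each marker update is
  $O(N)$) and periodically compared against a fresh recomputation; the
  largest deviation observed is reported in the chain metadata and kept
  below $10^{-8}$ in tests.
* Update order is a fixed sweep: $\alpha$, then $\beta_1 \ldots \beta_M$ in
  marker order, then $u_1 \ldots u_K$, $\sigma_u^2$, $\sigma^2$.
* Initialization: $\alpha = \bar y$, $\beta = 0$, $u = 0$,
  $\sigma^2 = \mathrm{var}(y)/2$, $\sigma_u^2 = \mathrm{var}(y)/100$.
  One seeded RNG per chain; `run_gibbs_chains()` offsets the base seed by
  the chain index.

Defaults mirror a production association scan (220 000 iterations, 20 000
burn-in, thinning 20); the tests and examples use much shorter chains.

### GEM fixed-point estimation

`gem_fit()` replaces every Gibbs draw by the fully conditional
*expectation* — the weighted truncated-normal mixture mean for each
$\beta_m$ (not the mode: for a two-sided mixture they differ), the
conditional normal mean for $\alpha$, and the inverse-gamma mean
$\mathrm{rate}/(\mathrm{shape}-1)$ for $\sigma^2$ — and iterates to a fixed
point. Convergence is declared when the sum of absolute parameter changes
in one sweep drops below $(M + 2) \times 10^{-7}$ (the per-parameter
tolerance times the parameter count; family effects add $K + 1$ when
enabled, but are excluded by default as their contribution to prediction is
negligible and they cannot be transferred to individuals outside the
training families). "Sum of deviations" is implemented as the absolute-value
norm. The iteration is RNG-free and bit-reproducible; it may converge to a
local optimum, so multi-start from perturbed initializations is left to the
user.

## Inference

Per-marker evidence is summarized by the posterior inclusion probability
$\hat p_m = \Pr(b \le |\beta_m| \le l \mid \text{data})$ (the boundary
$|\beta_m| = b$ counts as included), clipped to $[1/(2T),\, 1 - 1/(2T)]$
over $T$ stored draws so odds stay finite, and the Bayes factor

$$
\mathrm{BF}_m = \frac{\hat p_m / (1 - \hat p_m)}{(1-p_0)/p_0},
$$

categorized on the $2\ln \mathrm{BF}$ scale: $(0,2]$ barely worth
mentioning, $(2,6]$ positive, $(6,10]$ strong, $>10$ very strong (the
intervals are right-closed, so exactly 6 is "positive"). Because Bayes
factor *magnitudes* move substantially with the prior while their
*ranking* is comparatively stable, `mean_rank_consensus()` ranks markers by
descending $2\ln\mathrm{BF}$ within each chain (average ranks on ties) and
averages ranks across chains; `chain_comparison()` quantifies the two
effects separately (Spearman correlations above the diagonal, mean
$2\ln\mathrm{BF}$ ratios below).

Whole-model summaries: the QTL count $N_Q = \sum_m S_m$ per draw, and the
marker heritability $h_M^2 = 1 - (\sigma^2 + 2\sigma_u^2)/\mathrm{var}(Y)$
(the family variance enters twice because full sibs share half their
additive genetic variance). Per-marker variance shares use
$\%\mathrm{PVE}_m = 2\,\mathrm{MAF}_m(1-\mathrm{MAF}_m)\,
E_{\text{post}}(\beta_m^2)/\mathrm{var}(Y)$ — the posterior mean of
$\beta_m^2$, not the squared mean — and do not sum to $h_M^2$ because LD
covariances between markers are not in the sum.

## Prediction

`gebv()` scores individuals by $\sum_m \hat\beta_m x_{im}$ ($\hat\beta$ =
posterior means for MCMC, the point estimate for GEM); family effects are
never included. When the model was fitted on standardized data the
held-out panel is standardized with the *training* means and sds and the
score is rescaled by the training phenotype sd. `run_cv()` implements
10-fold cross-validation with three fold schemes — whole families per fold,
sibs spread across folds, or plain random — refitting standardization (and
optionally SIS pre-screening) inside every training fold. A `leaky_sis`
switch reproduces screening on all individuals before cross-validation,
which leaks validation information and tends to inflate accuracy; it exists
for comparability, not for use. Accuracy is `cor(GEBV, TBV)` when truth is
known, otherwise `cor(GEBV, y)/sqrt(h2)`; bias is the slope of regressing
the target on GEBV; `top_decile_rank_corr()` uses the
$\lceil N/10 \rceil$ individuals with the largest TBV (stable tie order).
Combining GEBV across prior specifications is an unweighted mean
(`average_gebv()`) — equal weight per specification.

## The simulator

`simulate_population()` emulates a multi-generation breeding design:
founder haplotypes drawn per marker at frequencies uniform on
`founder_maf_range` (founders in linkage equilibrium), then gene dropping
through a sire × dam pedigree — each sire mated to several dams, each
mating producing one full-sib family — with Haldane (no-interference)
recombination, $r = (1 - e^{-2d})/2$ at map distance $d$ Morgans,
chromosome starts assorting independently. Additive QTL at marker
positions define $\mathrm{TBV}_i = \sum_q a_q x_{iq}$, and the residual
variance is solved so the training-generation heritability matches
`target_h2` exactly in expectation. Validation generations carry TBV but
no phenotype. Two presets:

* `qtlmas_like_preset("full")`: 15 sires × 10 dams × 10 offspring
  (families of 10, 1500 per generation), 3 training + 3 validation
  generations, 6 chromosomes × 1000 SNP at 0.1 cM, 50 QTL, $h^2 = 0.30$.
* `qtlmas_like_preset("desk")`: 15 sires × 6 dams × 6 offspring (540
  training individuals in 90 families), 1 + 1 generations, 2 chromosomes ×
  250 SNP at 1 cM, 10 QTL of equal magnitude and random sign restricted to
  markers with founder-generation MAF ≥ 0.2, $h^2 = 0.30$. This is the
  configuration the test suite exercises end to end; the wider marker
  spacing keeps population LD short-ranged so single-marker signals stay
  localized at this reduced map length.

What the simulator deliberately does **not** emulate: ancestral LD between
founders (all LD is generated by the pedigree itself), dominance,
epistasis, imprinting, genotyping error and missingness, or a skewed
effect-size distribution. Passing recovery tests on these data therefore
demonstrates correctness of the machinery under a well-specified additive
model — not performance on real LD structures.

## Behavior at reduced sample sizes — known limitations

Several full-scale results change character at desk scale (hundreds rather
than thousands of individuals), and the test suite documents them rather
than hiding them:

* **$h_M^2$ is biased downward.** QTL whose single-marker evidence cannot
  overcome the spike leave their variance in $\sigma^2$, so
  $h_M^2 = 1 - \sigma^2/\mathrm{var}(Y)$ underestimates the simulated
  heritability, strongly so for conservative priors ($p_0 = 0.999$).
  Ranking-based QTL identification is far more robust than the variance
  decomposition at this scale.
* **The family effect competes with markers.** With the polygenic term
  enabled on desk-scale data, $\sigma_u^2$ absorbs between-family genetic
  variance of undetected QTL and the $2\sigma_u^2$ penalty pushes $h_M^2$
  down further; with no family-environment component in the generator the
  no-polygenic model is the well-specified analysis and is the default.
* **Averaging GEBV across priors is not uniformly better.** When all
  specifications perform comparably (the full-scale regime) the combined
  estimate matches or beats the best single one; when conservative
  specifications are clearly weaker (small $N$), the unweighted average
  sits between the best and worst single specifications. The same
  qualitative split shows up between the two data scales studied with this
  model family.

## Problem sizes used by the automated checks

The test suite validates the conditional distributions against adaptive
quadrature (50+ randomized instances, $10^{-6}$), the sampler against a
dense 2-D brute-force posterior ($N = 20$, $M = 2$, grid cells aligned to
the prior's discontinuities), GEM against Gibbs posterior means
($504 \times 300$, correlation $\ge 0.95$), desk-scale recovery with four
chains of 20 000 iterations, null calibration on $500 \times 500$
zero-signal data, and the cross-validation machinery with the GEM fitter.
These sizes are the package's reference configurations for routine,
repeatable verification; the full-scale preset reproduces the published
design dimensions when more compute is available.
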