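#' Mixture-of-uniforms (MU) prior specification
#'
#' The MU prior on a marker effect is a step-function spike-and-slab: mass
#' `p0` spread uniformly over the spike `(-b, b)` and mass `1 - p0` split
#' evenly over the two slabs `[-l, -b]` and `[b, l]`. The three
#' hyper-parameters have direct interpretations: `p0` is the prior
#' probability that a marker is not associated (`|beta| < b` counts as a
#' negligible effect), `b` is the effect-size border separating negligible
#' from relevant effects, and `l` caps the absolute effect size; effects
#' beyond a few phenotypic standard deviations are implausible, so `l` is
#' typically set to `sd(Y)` on the raw scale or 1-2 on the standardized
#' scale.
#'
#' @param p0 prior spike mass, in (0, 1).
#' @param b spike half-width (effect-size border), `0 < b < l`.
#' @param l effect-size limit, `l > b`.
#' @return An object of class `mu_prior_spec`.
#' @export
mu_prior_spec <- function(p0, b, l) {
  stopifnot(is.numeric(p0), is.numeric(b), is.numeric(l),
            length(p0) == 1L, length(b) == 1L, length(l) == 1L)
  if (!(p0 > 0 && p0 < 1)) stop("p0 must lie strictly in (0, 1)")
  if (!(b > 0 && l > b)) stop("need 0 < b < l")
  structure(list(p0 = p0, b = b, l = l), class = "mu_prior_spec")
}

#' @export
print.mu_prior_spec <- function(x, ...) {
  cat(sprintf("MU prior: p0 = %g, b = %g, l = %g (spike mass %g on (-%g, %g))\n",
              x$p0, x$b, x$l, x$p0, x$b, x$b))
  invisible(x)
}

#' Hyper-parameters shared by the sampler and the GEM estimator
#'
#' @param c prior variance of the common intercept (flat for the default
#'   `1e6`; the intercept variance does not scale with the residual
#'   variance).
#' @param s,r shape and rate of the inverse-gamma prior on the residual
#'   variance. With `s = r = 0.01` the prior has no mean or variance but its
#'   mode exists at rate/(shape + 1) = 1/101; as both tend to 0 it approaches the
#'   scale-invariant improper prior `1 / sigma^2`.
#' @param s_u,r_u same for the family-effect variance.
#' @param include_polygenic include the random full-sib family effect?
#' @return An object of class `hyper_config`.
#' @export
hyper_config <- function(c = 1e6, s = 0.01, r = 0.01, s_u = 0.01, r_u = 0.01,
                         include_polygenic = FALSE) {
  stopifnot(c > 0, s > 0, r > 0, s_u > 0, r_u > 0)
  structure(list(c = c, s = s, r = r, s_u = s_u, r_u = r_u,
                 include_polygenic = isTRUE(include_polygenic)),
            class = "hyper_config")
}

#' MU prior density
#'
#' Returns `p0 / (2b)` inside the spike `(-b, b)`, `(1 - p0) / (2 (l - b))`
#' on the slabs `[-l, -b]` and `[b, l]`, and 0 outside `[-l, l]`. The
#' boundary points `|beta| = b` belong to the slabs (closed slab intervals,
#' open spike), matching the inclusion indicator `S = I([b,l])(|beta|)`.
#'
#' @param beta effect size(s) at which to evaluate the density.
#' @param spec a [mu_prior_spec()].
#' @return Density value(s).
#' @export
mu_pdf <- function(beta, spec) {
  stopifnot(inherits(spec, "mu_prior_spec"))
  h_spike <- spec$p0 / (2 * spec$b)
  h_slab <- (1 - spec$p0) / (2 * (spec$l - spec$b))
  a <- abs(beta)
  out <- numeric(length(beta))
  out[a < spec$b] <- h_spike
  out[a >= spec$b & a <= spec$l] <- h_slab
  out
}

#' Draw from the MU prior
#'
#' Samples the mixture component (spike with probability `p0`, each slab
#' with probability `(1 - p0) / 2`) and then a uniform value within it.
#'
#' @param spec a [mu_prior_spec()].
#' @param n number of draws.
#' @return Numeric vector of `n` i.i.d. draws.
#' @export
mu_sample <- function(spec, n) {
  stopifnot(n >= 1)
  comp <- sample.int(3L, n, replace = TRUE,
                     prob = c(spec$p0, (1 - spec$p0) / 2, (1 - spec$p0) / 2))
  lo <- c(-spec$b, -spec$l, spec$b)[comp]
  hi <- c(spec$b, -spec$b, spec$l)[comp]
  stats::runif(n, lo, hi)
}

#' Closed-form variance of the MU prior
#'
#' `Var(beta) = (1/3) [ b^2 + l (l + b) (1 - p0) ]`.
#'
#' @param spec a [mu_prior_spec()].
#' @return The prior variance of a single marker effect.
#' @export
mu_variance <- function(spec) {
  (spec$b^2 + spec$l * (spec$l + spec$b) * (1 - spec$p0)) / 3
}

#' Prior heritability implied by the MU prior, unstandardized genotypes
#'
#' Under Hardy-Weinberg and linkage equilibrium with QTL at marker
#' positions, the narrow-sense heritability implied by a common prior effect
#' variance is `h2 = 2 Var(beta) sum_m f_m (1 - f_m) / V_P` for -1/0/1
#' genotype codes. The value is deliberately not clipped: calibrations can
#' imply "heritabilities" above 1, which is itself diagnostic of an
#' over-dispersed prior.
#'
#' @param spec a [mu_prior_spec()].
#' @param allele_freqs per-marker allele frequencies in (0, 1).
#' @param V_P phenotypic variance.
#' @return Implied prior heritability (unclipped, in `(0, Inf)`).
#' @export
prior_h2_unstd <- function(spec, allele_freqs, V_P) {
  stopifnot(all(allele_freqs >= 0), all(allele_freqs <= 1), V_P > 0)
  2 * mu_variance(spec) * sum(allele_freqs * (1 - allele_freqs)) / V_P
}

#' Prior heritability implied by the MU prior, standardized genotypes
#'
#' With every marker column scaled to variance 1 the relationship collapses
#' to `h2 = Var(beta) * M / V_P`.
#'
#' @param spec a [mu_prior_spec()].
#' @param M number of markers.
#' @param V_P phenotypic variance (1 for a standardized phenotype).
#' @return Implied prior heritability (unclipped).
#' @export
prior_h2_std <- function(spec, M, V_P = 1) {
  stopifnot(M >= 1, V_P > 0)
  mu_variance(spec) * M / V_P
}

#' Prior mean of the QTL count
#'
#' The number of markers with `|beta| >= b` has a binomial prior with mean
#' `M (1 - p0)`.
#'
#' @param spec a [mu_prior_spec()].
#' @param M number of markers.
#' @return `M * (1 - p0)`.
#' @export
prior_mean_nq <- function(spec, M) {
  stopifnot(M >= 1)
  M * (1 - spec$p0)
}

#' Rescale a prior specified in phenotypic-sd units to the standardized scale
#'
#' When `b` and `l` are chosen in units of the raw phenotype (e.g.
#' `l = sd(Y)`), fitting on standardized data requires dividing both by
#' `sd(Y)`; a limit set to one phenotypic standard deviation becomes
#' `l = 1`.
#'
#' @param spec a [mu_prior_spec()] on the raw phenotype scale.
#' @param y_sd the phenotype standard deviation used for standardization.
#' @return The rescaled `mu_prior_spec`.
#' @export
rescale_spec <- function(spec, y_sd) {
  stopifnot(y_sd > 0)
  mu_prior_spec(spec$p0, spec$b / y_sd, spec$l / y_sd)
}
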