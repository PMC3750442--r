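# Fully conditional distributions of the MU marker-regression model.
#
# These R implementations are the reference surface: they are exercised
# directly by quadrature-based tests and mirror, line for line, the compiled
# sweep used by run_gibbs()/gem_fit(). All tail probabilities are handled in
# log space so that weights stay well defined for |mu_tilde| up to thousands
# of conditional standard deviations.

# log(Phi(b) - Phi(a)) for scalar a < b, stable in both tails
log_pnorm_diff <- function(a, b) {
  if (a > 0) {
    la <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(b, lower.tail = FALSE, log.p = TRUE)
    la + log1p(-exp(lb - la))
  } else {
    lb <- stats::pnorm(b, log.p = TRUE)
    la <- stats::pnorm(a, log.p = TRUE)
    lb + log1p(-exp(la - lb))
  }
}

# mean of N(mu, tau^2) truncated to [lo, hi]
truncnorm_mean <- function(mu, tau, lo, hi) {
  a <- (lo - mu) / tau
  b <- (hi - mu) / tau
  lZ <- log_pnorm_diff(a, b)
  if (!is.finite(lZ)) return(min(max(mu, lo), hi))
  m <- mu + tau * (exp(stats::dnorm(a, log = TRUE) - lZ) -
                   exp(stats::dnorm(b, log = TRUE) - lZ))
  if (!is.finite(m)) m <- min(max(mu, lo), hi)
  min(max(m, lo), hi)
}

# inverse-CDF draw from N(mu, tau^2) truncated to [lo, hi]; uniforms clamped
# to [eps, 1 - eps] so tail truncations never return +-Inf
r_truncnorm <- function(mu, tau, lo, hi) {
  eps <- 1e-15
  u <- min(max(stats::runif(1), eps), 1 - eps)
  a <- (lo - mu) / tau
  b <- (hi - mu) / tau
  if (a >= 0) {
    la <- stats::pnorm(a, lower.tail = FALSE, log.p = TRUE)
    lb <- stats::pnorm(b, lower.tail = FALSE, log.p = TRUE)
    lq <- la + log1p(-u * (-expm1(lb - la)))
    x <- mu + tau * stats::qnorm(lq, lower.tail = FALSE, log.p = TRUE)
  } else if (b <= 0) {
    lbm <- stats::pnorm(-b, lower.tail = FALSE, log.p = TRUE)
    lam <- stats::pnorm(-a, lower.tail = FALSE, log.p = TRUE)
    lq <- lbm + log1p(-u * (-expm1(lam - lbm)))
    x <- mu - tau * stats::qnorm(lq, lower.tail = FALSE, log.p = TRUE)
  } else {
    p <- stats::pnorm(a) + u * (stats::pnorm(b) - stats::pnorm(a))
    p <- min(max(p, eps), 1 - eps)
    x <- mu + tau * stats::qnorm(p)
  }
  min(max(x, lo), hi)
}

#' Construct the truncated-normal mixture conditional of a marker effect
#'
#' Combining the conditional Gaussian likelihood `N(mu_tilde, tau^2)` of a
#' single effect with the step-function MU prior yields a three-component
#' mixture of truncated normals, one component per prior interval, with
#' weights proportional to the prior step height times the normal mass on
#' the interval.
#'
#' @param mu_tilde,tau conditional likelihood location and scale.
#' @param spec a [mu_prior_spec()].
#' @return An object of class `truncnorm_mixture` with fields `mu_tilde`,
#'   `tau`, `intervals` (3 x 2 matrix: spike, negative slab, positive slab),
#'   `weights` (normalized) and `log_heights`.
#' @export
trunc_mixture <- function(mu_tilde, tau, spec) {
  stopifnot(inherits(spec, "mu_prior_spec"), tau > 0)
  intervals <- rbind(spike = c(-spec$b, spec$b),
                     slab_neg = c(-spec$l, -spec$b),
                     slab_pos = c(spec$b, spec$l))
  lh <- c(log(spec$p0) - log(2 * spec$b),
          rep(log1p(-spec$p0) - log(2 * (spec$l - spec$b)), 2L))
  lw <- vapply(1:3, function(j) {
    lh[j] + log_pnorm_diff((intervals[j, 1] - mu_tilde) / tau,
                           (intervals[j, 2] - mu_tilde) / tau)
  }, numeric(1))
  mx <- max(lw)
  if (!is.finite(mx)) {
    # all three components numerically vanished: fall back to the component
    # containing (or nearest to) mu_tilde
    j <- if (mu_tilde > spec$b) 3L else if (mu_tilde < -spec$b) 2L else 1L
    w <- c(0, 0, 0); w[j] <- 1
  } else {
    w <- exp(lw - mx)
    w <- w / sum(w)
  }
  structure(list(mu_tilde = mu_tilde, tau = tau, intervals = intervals,
                 weights = w, log_heights = lh, spec = spec),
            class = "truncnorm_mixture")
}

#' Analytic mean of a truncated-normal mixture
#'
#' @param mix a [trunc_mixture()].
#' @return The weighted sum of the component truncated-normal means.
#' @export
mixture_mean <- function(mix) {
  stopifnot(inherits(mix, "truncnorm_mixture"))
  sum(vapply(1:3, function(j) {
    if (mix$weights[j] == 0) return(0)
    mix$weights[j] * truncnorm_mean(mix$mu_tilde, mix$tau,
                                    mix$intervals[j, 1], mix$intervals[j, 2])
  }, numeric(1)))
}

#' Conditional posterior probability of inclusion
#'
#' @param mix a [trunc_mixture()].
#' @return `P(|beta| >= b)` under the mixture, i.e. the total slab weight.
#' @export
mixture_prob_slab <- function(mix) {
  stopifnot(inherits(mix, "truncnorm_mixture"))
  mix$weights[2] + mix$weights[3]
}

#' Draw from a truncated-normal mixture
#'
#' Picks a component by its weight, then an inverse-CDF truncated-normal
#' draw within it; the result always lies in `[-l, l]`.
#'
#' @param mix a [trunc_mixture()].
#' @param n number of draws.
#' @return Numeric vector of draws.
#' @export
sample_trunc_mixture <- function(mix, n = 1L) {
  stopifnot(inherits(mix, "truncnorm_mixture"))
  comp <- sample.int(3L, n, replace = TRUE, prob = mix$weights)
  vapply(comp, function(j) {
    r_truncnorm(mix$mu_tilde, mix$tau, mix$intervals[j, 1], mix$intervals[j, 2])
  }, numeric(1))
}

# residual excluding nothing: y - alpha - X beta - u[fam]
model_residual <- function(state, X, y, fam = NULL) {
  e <- y - state$alpha - as.vector(X %*% state$beta)
  if (!is.null(fam) && length(state$u) > 0) e <- e - state$u[fam$family_of]
  e
}

#' Full conditional of a single marker effect
#'
#' With partial residual `y - alpha - X[,-m] beta[-m] - u`, the
#' conditional likelihood of `beta_m` is Gaussian with location
#' `mu_tilde = x_m . r / x_m . x_m` and scale `tau^2 = sigma2 / x_m . x_m`;
#' multiplied by the MU prior this gives a three-component truncated-normal
#' mixture.
#'
#' @param m marker index.
#' @param state list with `alpha`, `beta`, `sigma2` and optionally `u`.
#' @param X genotype matrix (N x M).
#' @param y phenotype vector.
#' @param spec a [mu_prior_spec()].
#' @param fam optional [family_map()] when the state carries family effects.
#' @return A [trunc_mixture()].
#' @export
full_conditional_beta <- function(m, state, X, y, spec, fam = NULL) {
  xx <- sum(X[, m]^2)
  if (xx <= 0) stop("degenerate marker: column ", m, " is identically zero")
  e <- model_residual(state, X, y, fam)
  r <- e + X[, m] * state$beta[m]
  mu_tilde <- sum(X[, m] * r) / xx
  tau <- sqrt(state$sigma2 / xx)
  trunc_mixture(mu_tilde, tau, spec)
}

#' Full conditional of the intercept
#'
#' @inheritParams full_conditional_beta
#' @param c prior variance of the intercept.
#' @return List with `mean` and `var`:
#'   `var = (N / sigma2 + 1 / c)^-1`, `mean = var * sum(r_alpha) / sigma2`
#'   where `r_alpha` excludes the intercept from the fit.
#' @export
full_conditional_alpha <- function(state, X, y, c = 1e6, fam = NULL) {
  e <- model_residual(state, X, y, fam)
  r_alpha <- e + state$alpha
  v <- 1 / (length(y) / state$sigma2 + 1 / c)
  list(mean = v * sum(r_alpha) / state$sigma2, var = v)
}

#' Full conditional of one family effect
#'
#' @inheritParams full_conditional_beta
#' @param k family index.
#' @return List with `mean` and `var`:
#'   `var = (N_k / sigma2 + 1 / sigma2_u)^-1`,
#'   `mean = var * sum_(j in k) r_kj / sigma2` with the residual excluding
#'   `u_k`.
#' @export
full_conditional_u <- function(k, state, X, y, fam) {
  if (is.null(fam) || length(state$u) == 0)
    stop("family effects are not enabled in this state")
  e <- model_residual(state, X, y, fam)
  members <- fam$family_of == k
  rsum <- sum(e[members]) + sum(members) * state$u[k]
  v <- 1 / (sum(members) / state$sigma2 + 1 / state$sigma2_u)
  list(mean = v * rsum / state$sigma2, var = v)
}

#' Full conditional of the residual variance
#'
#' @inheritParams full_conditional_beta
#' @param s,r inverse-gamma prior shape and rate.
#' @return List with `shape = s + N/2` and `rate = r + SSE/2` of the
#'   conditional inverse-gamma distribution.
#' @export
full_conditional_sigma2 <- function(state, X, y, s = 0.01, r = 0.01,
                                    fam = NULL) {
  e <- model_residual(state, X, y, fam)
  list(shape = s + length(y) / 2, rate = r + sum(e^2) / 2)
}
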