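# Small in-code fixtures shared across test files.

# deterministic integer genotype matrix with controllable allele frequencies
make_panel <- function(n = 40, m = 12, coding = "centered", seed = 42,
                       freqs = NULL) {
  set.seed(seed)
  if (is.null(freqs)) freqs <- runif(m, 0.2, 0.5)
  X <- sapply(freqs, function(f) rbinom(n, 2L, f))
  # guarantee polymorphism
  X[1, X[1, ] == 0 & colSums(X) == 0] <- 1L
  if (coding == "centered") X <- X - 1L
  genotype_panel(X, coding = coding)
}

# tiny regression data with a known strong effect at marker 1
make_signal_data <- function(n = 120, m = 8, effect = 0.8, seed = 11) {
  set.seed(seed)
  panel <- make_panel(n, m, coding = "centered", seed = seed)
  y <- effect * panel$dosage[, 1] + rnorm(n)
  list(panel = panel, phen = phenotype_set(y))
}

# quadrature oracle: posterior moments of one effect under
# N(mu_tilde, tau^2) likelihood x MU prior, via adaptive quadrature over the
# three prior intervals separately
quad_beta_posterior <- function(mu_tilde, tau, spec) {
  ints <- rbind(c(-spec$b, spec$b), c(-spec$l, -spec$b), c(spec$b, spec$l))
  piece <- function(fun, lo, hi) {
    for (tol in c(1e-12, 1e-10, 1e-8)) {
      out <- tryCatch(stats::integrate(fun, lo, hi, rel.tol = tol,
                                       abs.tol = 1e-300),
                      error = function(e) NULL)
      if (!is.null(out)) return(out$value)
    }
    stats::integrate(fun, lo, hi)$value
  }
  dens <- function(b) dnorm(b, mu_tilde, tau) * mu_pdf(b, spec)
  z <- sapply(1:3, function(j) piece(dens, ints[j, 1], ints[j, 2]))
  m1 <- sapply(1:3, function(j) piece(function(b) b * dens(b),
                                      ints[j, 1], ints[j, 2]))
  list(mean = sum(m1) / sum(z), p_slab = (z[2] + z[3]) / sum(z),
       weights = z / sum(z))
}
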