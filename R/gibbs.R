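#' Gibbs run settings
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before storage (`burn_in < n_iter`).
#' @param thin store every `thin`-th post-burn-in iteration.
#' @param seed RNG seed for the chain.
#' @param fix_alpha,fix_sigma2 optional fixed values; when supplied the
#'   corresponding parameter is held constant instead of being updated
#'   (used for controlled validation runs against brute-force posteriors).
#' @param check_every verify and refresh the running residual against a full
#'   recomputation every this many iterations (0 disables).
#' @return An object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 220000L, burn_in = 20000L, thin = 20L,
                         seed = 1L, fix_alpha = NULL, fix_sigma2 = NULL,
                         check_every = 1000L) {
  stopifnot(burn_in < n_iter, thin >= 1, n_iter >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 fix_alpha = fix_alpha, fix_sigma2 = fix_sigma2,
                 check_every = as.integer(check_every)),
            class = "gibbs_config")
}

#' Run the single-site Gibbs sampler
#'
#' Systematic-scan Gibbs sampler for the marker regression
#' `y = alpha + X beta + Z u + e` with the MU prior on each `beta_m`,
#' a flat-ish normal prior on `alpha`, i.i.d. `N(0, sigma2_u)` full-sib
#' family effects `u_k` (optional) and inverse-gamma priors on the two
#' variance components. Each sweep updates `alpha`, then `beta_1..beta_M`
#' in marker order, then `u_1..u_K`, `sigma2_u` and `sigma2`, maintaining
#' the residual vector incrementally so a marker update costs O(N).
#'
#' @param panel a [genotype_panel()]; columns are used as-is, so standardize
#'   or center beforehand as appropriate for the prior scale.
#' @param phen a [phenotype_set()].
#' @param spec a [mu_prior_spec()].
#' @param hyper a [hyper_config()]; set `include_polygenic = TRUE` together
#'   with `fam` to add the family effect.
#' @param cfg a [gibbs_config()].
#' @param fam optional [family_map()].
#' @return An object of class `mu_chain` holding the thinned post-burn-in
#'   draws: `beta` (T x M), `alpha`, `sigma2`, `sigma2_u`, `u` (T x K),
#'   inclusion indicators `S` (T x M, `S[t,m] = 1` iff
#'   `b <= |beta[t,m]| <= l`), the prior `spec`, the `config` and run meta.
#' @export
run_gibbs <- function(panel, phen, spec, hyper = hyper_config(),
                      cfg = gibbs_config(), fam = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(phen, "phenotype_set"),
            inherits(spec, "mu_prior_spec"), inherits(hyper, "hyper_config"),
            inherits(cfg, "gibbs_config"))
  X <- panel$dosage
  y <- phen$y
  if (nrow(X) != length(y))
    stop(sprintf("panel has %d individuals but phenotype has %d",
                 nrow(X), length(y)))
  polygenic <- hyper$include_polygenic
  if (polygenic && is.null(fam))
    stop("include_polygenic = TRUE requires a family_map")
  if (!is.null(fam) && length(fam$family_of) != length(y))
    stop("family_map length does not match the number of individuals")
  K <- if (polygenic) length(fam$sizes) else 0L
  fidx <- if (polygenic) fam$family_of else integer(0)

  # default initialization; overridden parameters are pinned
  alpha0 <- if (is.null(cfg$fix_alpha)) mean(y) else cfg$fix_alpha
  sigma20 <- if (is.null(cfg$fix_sigma2)) stats::var(y) / 2 else cfg$fix_sigma2
  sigma2u0 <- stats::var(y) / 100

  set.seed(cfg$seed)
  t0 <- proc.time()[["elapsed"]]
  out <- gibbs_mu_cpp(X, y, fidx, K, spec$p0, spec$b, spec$l, hyper$c,
                      hyper$s, hyper$r, hyper$s_u, hyper$r_u, polygenic,
                      cfg$n_iter, cfg$burn_in, cfg$thin,
                      alpha0, rep(0, ncol(X)), rep(0, max(K, 1L)),
                      sigma20, sigma2u0,
                      is.null(cfg$fix_alpha), is.null(cfg$fix_sigma2),
                      cfg$check_every)
  elapsed <- proc.time()[["elapsed"]] - t0
  S <- abs(out$beta) >= spec$b & abs(out$beta) <= spec$l
  storage.mode(S) <- "integer"
  colnames(out$beta) <- panel$marker_ids
  colnames(S) <- panel$marker_ids
  structure(list(beta = out$beta, alpha = out$alpha, sigma2 = out$sigma2,
                 sigma2_u = out$sigma2_u, u = out$u, S = S, spec = spec,
                 hyper = hyper, config = cfg, marker_ids = panel$marker_ids,
                 polygenic = polygenic,
                 meta = list(seed = cfg$seed, elapsed_sec = elapsed,
                             max_resid_dev = out$max_resid_dev,
                             n_stored = nrow(out$beta))),
            class = "mu_chain")
}

#' @export
print.mu_chain <- function(x, ...) {
  cat(sprintf(
    "mu_chain: %d stored draws x %d markers (p0=%g, b=%g, l=%g%s)\n",
    nrow(x$beta), ncol(x$beta), x$spec$p0, x$spec$b, x$spec$l,
    if (x$polygenic) ", polygenic" else ""))
  invisible(x)
}

#' Run several independent Gibbs chains
#'
#' Chains differ only in their seed (chain id offsets the base seed) and,
#' optionally, in their prior specification: supply one spec to replicate
#' chains under identical priors, or a list of specs (recycled over chains)
#' for a sensitivity sweep.
#'
#' @param panel,phen,hyper,cfg,fam as in [run_gibbs()].
#' @param specs a single [mu_prior_spec()] or a list of them.
#' @param n_chains number of chains; defaults to `length(specs)`.
#' @return A list of `mu_chain` objects.
#' @export
run_gibbs_chains <- function(panel, phen, specs, hyper = hyper_config(),
                             cfg = gibbs_config(), fam = NULL,
                             n_chains = NULL) {
  if (inherits(specs, "mu_prior_spec")) specs <- list(specs)
  if (is.null(n_chains)) n_chains <- length(specs)
  lapply(seq_len(n_chains), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    run_gibbs(panel, phen, specs[[(i - 1L) %% length(specs) + 1L]],
              hyper = hyper, cfg = cfg_i, fam = fam)
  })
}

#' Persist / restore a chain
#'
#' Chains are stored as a single serialized container (one array per
#' parameter group); per-marker posterior summaries intended for human
#' consumption are written separately by [write_marker_report()].
#'
#' @param chain a `mu_chain`.
#' @param path file path.
#' @return `read_chain` returns the restored `mu_chain`.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "mu_chain"))
  saveRDS(chain, path)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  chain <- readRDS(path)
  stopifnot(inherits(chain, "mu_chain"))
  chain
}
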