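#' Genomic estimated breeding values
#'
#' `GEBV_i = sum_m beta_hat_m x_im`. When the effects were estimated on
#' standardized data, supply the training `scaling_record`: the held-out
#' panel is standardized with the *training* means/sds and the score is
#' scaled by the training phenotype sd so GEBV are on the original
#' phenotype scale (up to an additive constant, which no accuracy, rank or
#' slope metric depends on). Family effects are never part of the GEBV.
#'
#' @param beta_hat effect vector (posterior means for MCMC, point estimates
#'   for GEM).
#' @param panel a [genotype_panel()] whose coding matches the fit (enforced
#'   through `scaling` when the fit was standardized).
#' @param scaling optional `scaling_record` from [standardize_fit()].
#' @return Numeric vector of breeding values, one per individual.
#' @export
gebv <- function(beta_hat, panel, scaling = NULL) {
  stopifnot(inherits(panel, "genotype_panel"),
            length(beta_hat) == ncol(panel$dosage))
  if (is.null(scaling)) {
    if (panel$coding == "standardized" && is.null(panel$col_means))
      stop("standardized panel without scaling statistics")
    return(as.vector(panel$dosage %*% beta_hat))
  }
  stopifnot(inherits(scaling, "scaling_record"))
  if (panel$coding == "standardized")
    stop("supply the unstandardized panel together with the scaling record")
  Xs <- sweep(sweep(panel$dosage, 2L, scaling$x_means), 2L,
              scaling$x_sds, "/")
  as.vector(Xs %*% beta_hat) * scaling$y_sd
}

#' Accuracy against true breeding values
#'
#' Pearson correlation between GEBV and TBV.
#'
#' @param gebv,tbv numeric vectors of equal length (>= 3).
#' @return Pearson correlation.
#' @export
accuracy_tbv <- function(gebv, tbv) {
  stopifnot(length(gebv) == length(tbv), length(gebv) >= 3L)
  if (stats::sd(gebv) == 0 || stats::sd(tbv) == 0)
    stop("degenerate input: zero variance")
  stats::cor(gebv, tbv)
}

#' Cross-validation accuracy from phenotypes
#'
#' Without true breeding values, the correlation between GEBV and the
#' observed phenotype is divided by the square root of the trait
#' heritability to estimate the accuracy of the GEBV themselves.
#'
#' @param gebv predicted breeding values.
#' @param phenotype observed phenotypes of the same individuals.
#' @param h2 trait heritability, in (0, 1].
#' @return `cor(gebv, phenotype) / sqrt(h2)`.
#' @export
accuracy_cv <- function(gebv, phenotype, h2) {
  stopifnot(length(gebv) == length(phenotype))
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must lie in (0, 1]")
  stats::cor(gebv, phenotype) / sqrt(h2)
}

#' Spearman rank correlation in the top decile
#'
#' Selects the `ceiling(N/10)` individuals with the largest TBV (ties
#' broken by stable index order) and returns the Spearman correlation of
#' their GEBV with their TBV — a measure of how well selection candidates
#' are ordered among themselves.
#'
#' @param gebv,tbv numeric vectors (>= 10 individuals).
#' @return Spearman rank correlation on the top decile.
#' @export
top_decile_rank_corr <- function(gebv, tbv) {
  n <- length(tbv)
  stopifnot(length(gebv) == n, n >= 10L)
  top <- order(tbv, decreasing = TRUE)[seq_len(ceiling(n / 10))]
  stats::cor(gebv[top], tbv[top], method = "spearman")
}

#' Bias of GEBV as a regression slope
#'
#' Least-squares slope of regressing the target (TBV, or phenotype in
#' cross-validation) on the GEBV; 1 means unbiased.
#'
#' @param gebv predicted breeding values (non-degenerate).
#' @param target TBV or phenotype.
#' @return The regression coefficient.
#' @export
bias <- function(gebv, target) {
  stopifnot(length(gebv) == length(target))
  v <- stats::var(gebv)
  if (v == 0) stop("degenerate input: GEBV have zero variance")
  stats::cov(gebv, target) / v
}

#' Build a 10-fold cross-validation plan
#'
#' Three schemes: `"family_blocked"` keeps every full-sib family intact in
#' one fold (families dealt round-robin after a seeded shuffle, so fold
#' sizes are balanced — 450 families of 10 give 45 whole families per
#' fold); `"within_family"` spreads the members of each family over
#' distinct folds (requires family sizes <= `n_folds`); and
#' `"random_individual"` ignores families.
#'
#' @param fam a [family_map()].
#' @param scheme fold scheme, see above.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed; the same seed yields the identical plan.
#' @return An object of class `cv_plan` with `fold_of` (fold index per
#'   individual), `scheme`, `n_folds`, `seed`.
#' @export
make_cv_plan <- function(fam, scheme = c("family_blocked", "within_family",
                                         "random_individual"),
                         n_folds = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(fam, "family_map"), n_folds >= 2L)
  n <- length(fam$family_of)
  set.seed(seed)
  fold_of <- integer(n)
  if (scheme == "family_blocked") {
    K <- length(fam$sizes)
    fam_fold <- integer(K)
    fam_fold[sample.int(K)] <- rep_len(seq_len(n_folds), K)
    fold_of <- fam_fold[fam$family_of]
  } else if (scheme == "within_family") {
    if (max(fam$sizes) > n_folds)
      stop(sprintf("family of size %d cannot be spread over %d folds",
                   max(fam$sizes), n_folds))
    for (k in seq_along(fam$sizes)) {
      members <- which(fam$family_of == k)
      fold_of[members] <- sample.int(n_folds, length(members))
    }
  } else {
    fold_of[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  }
  structure(list(fold_of = fold_of, scheme = scheme,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Average GEBV across prior specifications
#'
#' Elementwise arithmetic mean — "poor man's model averaging" with equal
#' weight on every prior specification.
#'
#' @param per_spec_gebv list of equal-length GEBV vectors.
#' @return The combined GEBV vector.
#' @export
average_gebv <- function(per_spec_gebv) {
  stopifnot(is.list(per_spec_gebv), length(per_spec_gebv) >= 1L)
  len <- vapply(per_spec_gebv, length, 1L)
  stopifnot(all(len == len[1L]))
  rowMeans(do.call(cbind, per_spec_gebv))
}

#' Sure independence screening of markers
#'
#' Ranks markers by the absolute marginal Pearson correlation between their
#' dosage column and the phenotype, after removing markers with
#' `MAF <= min_maf`, and returns the top `k`. The ranking is nested: the
#' top 1000 of a ranking are a subset of its top 10000.
#'
#' @param panel a [genotype_panel()] (raw or centered coding).
#' @param y phenotype vector.
#' @param k number of markers to keep.
#' @param min_maf MAF floor applied before screening (default 0.05).
#' @return List with `marker_ids`, `idx` (column indices into the input
#'   panel) and `abs_cor`.
#' @export
sis_select <- function(panel, y, k, min_maf = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"),
            nrow(panel$dosage) == length(y))
  maf <- panel_maf(panel)
  pool <- which(maf > min_maf)
  if (k > length(pool))
    stop(sprintf("k = %d exceeds the %d markers passing the MAF screen",
                 k, length(pool)))
  ac <- abs(suppressWarnings(stats::cor(panel$dosage[, pool, drop = FALSE],
                                        y)))[, 1L]
  ac[is.na(ac)] <- 0
  ord <- pool[order(ac, decreasing = TRUE)]
  idx <- ord[seq_len(k)]
  list(marker_ids = panel$marker_ids[idx], idx = idx,
       abs_cor = abs(suppressWarnings(stats::cor(panel$dosage[, idx,
                                                              drop = FALSE],
                                                 y)))[, 1L])
}

#' 10-fold cross-validated genomic prediction
#'
#' For each fold, the remaining folds form the training set: markers that
#' are monomorphic within the training fold are dropped for that fold,
#' standardization (genotypes and phenotype) is fitted on the training fold
#' only, one model per prior specification is fitted (GEM by default;
#' Gibbs posterior means optionally) and GEBV are predicted for the
#' held-out individuals using the training scaling. Optionally markers are
#' pre-screened by SIS within each training fold — or, to reproduce
#' screening performed on the full data before cross-validation (which
#' leaks validation information and inflates accuracy), on all individuals
#' via `leaky_sis = TRUE`.
#'
#' @param panel a [genotype_panel()] (raw or centered coding).
#' @param phen a [phenotype_set()] on the original scale.
#' @param specs list of [mu_prior_spec()]s on the standardized scale.
#' @param plan a [make_cv_plan()].
#' @param fitter `"gem"` (default) or `"gibbs"`.
#' @param h2 trait heritability used to convert phenotype correlations to
#'   accuracies.
#' @param hyper a [hyper_config()] (family effects are not used in
#'   cross-validated prediction).
#' @param sis_k optional SIS pre-selection count per fold.
#' @param sis_maf MAF floor for SIS.
#' @param leaky_sis perform SIS once on all individuals instead of within
#'   each training fold.
#' @param gibbs_cfg a [gibbs_config()] used when `fitter = "gibbs"`.
#' @param gem_tol,gem_max_iter GEM settings.
#' @return An object of class `cv_report`: `gebv` (N x n_specs matrix),
#'   `combined` (averaged GEBV), `metrics` (accuracy and bias per spec and
#'   combined), `plan`, `specs`.
#' @export
run_cv <- function(panel, phen, specs, plan, fitter = c("gem", "gibbs"),
                   h2, hyper = hyper_config(), sis_k = NULL, sis_maf = 0.05,
                   leaky_sis = FALSE, gibbs_cfg = gibbs_config(),
                   gem_tol = 1e-7, gem_max_iter = 2000L) {
  fitter <- match.arg(fitter)
  stopifnot(inherits(plan, "cv_plan"),
            length(plan$fold_of) == length(phen$y))
  if (inherits(specs, "mu_prior_spec")) specs <- list(specs)
  n <- length(phen$y)
  G <- matrix(NA_real_, n, length(specs))
  global_sis <- if (!is.null(sis_k) && leaky_sis)
    sis_select(panel, phen$y, sis_k, sis_maf)$idx else NULL

  for (fold in seq_len(plan$n_folds)) {
    val <- which(plan$fold_of == fold)
    trn <- which(plan$fold_of != fold)
    if (length(val) == 0L) next
    p_trn <- subset_individuals(panel, trn)
    keep <- if (!is.null(global_sis)) global_sis
            else if (!is.null(sis_k))
              sis_select(p_trn, phen$y[trn], sis_k, sis_maf)$idx
            else seq_len(ncol(panel$dosage))
    # drop markers monomorphic within the training fold
    sds <- apply(p_trn$dosage[, keep, drop = FALSE], 2L, stats::sd)
    keep <- keep[sds > 0]
    p_trn <- genotype_panel(p_trn$dosage[, keep, drop = FALSE],
                            panel$marker_ids[keep], panel$chrom[keep],
                            panel$pos_cM[keep], coding = panel$coding)
    p_val <- genotype_panel(panel$dosage[val, keep, drop = FALSE],
                            panel$marker_ids[keep], panel$chrom[keep],
                            panel$pos_cM[keep], coding = panel$coding)
    std <- standardize_fit(p_trn, phenotype_set(phen$y[trn]))
    for (si in seq_along(specs)) {
      bh <- if (fitter == "gem") {
        gem_fit(std$panel, std$phen, specs[[si]], hyper = hyper,
                tol_per_param = gem_tol, max_iter = gem_max_iter)$state$beta
      } else {
        cfg <- gibbs_cfg
        cfg$seed <- gibbs_cfg$seed + fold
        colMeans(run_gibbs(std$panel, std$phen, specs[[si]], hyper = hyper,
                           cfg = cfg)$beta)
      }
      G[val, si] <- gebv(bh, p_val, scaling = std$scaling)
    }
  }
  combined <- average_gebv(lapply(seq_along(specs), function(i) G[, i]))
  metr <- do.call(rbind, lapply(seq_along(specs), function(i) {
    data.frame(spec = sprintf("p0=%g,b=%g", specs[[i]]$p0, specs[[i]]$b),
               accuracy = accuracy_cv(G[, i], phen$y, h2),
               bias = bias(G[, i], phen$y))
  }))
  metr <- rbind(metr, data.frame(spec = "combined",
                                 accuracy = accuracy_cv(combined, phen$y, h2),
                                 bias = bias(combined, phen$y)))
  structure(list(gebv = G, combined = combined, metrics = metr,
                 plan = plan, specs = specs, fitter = fitter, h2 = h2),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold %s, fitter %s, h2 = %g\n",
              x$plan$n_folds, x$plan$scheme, x$fitter, x$h2))
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}
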