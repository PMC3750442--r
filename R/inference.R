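#' Posterior inclusion probability of a marker
#'
#' Fraction of stored draws with `b <= |beta_m| <= l`. Because a
#' finite-sample frequency can hit 0 or 1 while the underlying posterior
#' probability is interior, the estimate is clipped to
#' `[1/(2T), 1 - 1/(2T)]` (T = stored draws) before odds are formed.
#'
#' @param chain a `mu_chain`.
#' @param m marker index or id; omit for all markers.
#' @param clip clip constant; default `1 / (2 * nrow(chain$S))`.
#' @return Clipped inclusion probabilities.
#' @export
inclusion_prob <- function(chain, m = NULL, clip = NULL) {
  stopifnot(inherits(chain, "mu_chain"))
  T_ <- nrow(chain$S)
  if (T_ < 1L) stop("chain holds no stored draws")
  if (is.null(clip)) clip <- 1 / (2 * T_)
  p <- if (is.null(m)) colMeans(chain$S) else mean(chain$S[, m])
  pmin(pmax(p, clip), 1 - clip)
}

#' Bayes factor for marker inclusion
#'
#' `BF = [p / (1 - p)] / [(1 - p0) / p0]`: the posterior odds of the
#' inclusion event `S_m = 1` divided by its prior odds `(1 - p0) / p0`.
#'
#' @param p_incl posterior inclusion probability, strictly inside (0, 1)
#'   (clip first, see [inclusion_prob()]).
#' @param p0 prior spike mass of the MU specification.
#' @return The Bayes factor (vectorized over `p_incl`).
#' @export
bayes_factor <- function(p_incl, p0) {
  if (any(p_incl <= 0 | p_incl >= 1))
    stop("p_incl must be strictly inside (0, 1); clip inclusion ",
         "probabilities before forming odds")
  stopifnot(p0 > 0, p0 < 1)
  (p_incl / (1 - p_incl)) / ((1 - p0) / p0)
}

#' Kass-Raftery evidence category of 2 ln(BF)
#'
#' `> 10` very strong, `(6, 10]` strong, `(2, 6]` positive, `(0, 2]` not
#' worth more than a bare mention, `<= 0` none.
#'
#' @param two_ln_bf numeric vector of `2 ln(BF)` values.
#' @return Factor with levels `none < bare mention < positive < strong <
#'   very strong`.
#' @export
evidence_category <- function(two_ln_bf) {
  cut(two_ln_bf, breaks = c(-Inf, 0, 2, 6, 10, Inf),
      labels = c("none", "bare mention", "positive", "strong", "very strong"),
      right = TRUE, ordered_result = TRUE)
}

#' Posterior summary of the QTL count
#'
#' `N_Q = sum_m S_m` per stored draw.
#'
#' @param chain a `mu_chain` with stored indicators.
#' @return List with `mean`, `sd` and the per-draw `draws`.
#' @export
nq_summary <- function(chain) {
  stopifnot(inherits(chain, "mu_chain"))
  nq <- rowSums(chain$S)
  list(mean = mean(nq), sd = stats::sd(nq), draws = nq)
}

#' Posterior summary of the marker heritability
#'
#' `h_M^2 = 1 - (sigma2 + 2 sigma2_u) / var(Y)` per draw; the family
#' variance enters with factor 2 because the additive genetic covariance
#' between full sibs is 1/2. Without the polygenic term `sigma2_u = 0`.
#'
#' @param chain a `mu_chain`.
#' @param var_y sample phenotypic variance of the analysis data.
#' @return List with `mean`, `sd` and the per-draw `draws`.
#' @export
marker_h2 <- function(chain, var_y) {
  stopifnot(inherits(chain, "mu_chain"), var_y > 0)
  s2u <- if (chain$polygenic) chain$sigma2_u else 0
  h <- 1 - (chain$sigma2 + 2 * s2u) / var_y
  list(mean = mean(h), sd = stats::sd(h), draws = h)
}

#' Per-marker percentage of phenotypic variance explained
#'
#' `E_post(%PVE_m) = 2 MAF_m (1 - MAF_m) E_post(beta_m^2) / var(Y) * 100`,
#' using the posterior mean of `beta^2` (not the squared posterior mean).
#' Summing across markers does not recover the total marker heritability
#' because covariances due to LD between markers are missed.
#'
#' @param chain a `mu_chain`.
#' @param maf per-marker minor allele frequencies from the analysis panel.
#' @param var_y sample phenotypic variance.
#' @return Numeric vector of per-marker %PVE.
#' @export
pve <- function(chain, maf, var_y) {
  stopifnot(inherits(chain, "mu_chain"), var_y > 0,
            length(maf) == ncol(chain$beta))
  eb2 <- colMeans(chain$beta^2)
  100 * 2 * maf * (1 - maf) * eb2 / var_y
}

#' Per-marker posterior report for one chain
#'
#' @param chain a `mu_chain`.
#' @param maf optional per-marker MAF (enables the %PVE column).
#' @param var_y phenotypic variance used for %PVE (default 1 for
#'   standardized data).
#' @return A data.frame of class `marker_report` with columns `marker`,
#'   `p_incl`, `bf`, `two_ln_bf`, `category`, `beta_mean`, `beta_sd` and
#'   optionally `pve`.
#' @export
marker_report <- function(chain, maf = NULL, var_y = 1) {
  stopifnot(inherits(chain, "mu_chain"))
  p <- inclusion_prob(chain)
  bf <- bayes_factor(p, chain$spec$p0)
  rep_ <- data.frame(marker = chain$marker_ids, p_incl = p, bf = bf,
                     two_ln_bf = 2 * log(bf),
                     category = evidence_category(2 * log(bf)),
                     beta_mean = colMeans(chain$beta),
                     beta_sd = apply(chain$beta, 2L, stats::sd),
                     row.names = NULL)
  if (!is.null(maf)) rep_$pve <- pve(chain, maf, var_y)
  class(rep_) <- c("marker_report", "data.frame")
  rep_
}

#' Consensus ranking of markers across chains
#'
#' Within each chain markers are ranked by descending `2 ln(BF)` (average
#' ranks on ties); the per-marker mean rank across chains summarizes the
#' evidence while damping the dependence on any single prior specification.
#' The across-chain mean, minimum and maximum of `2 ln(BF)` are reported
#' alongside.
#'
#' @param bf_tables list of per-chain `2 ln(BF)` vectors over a common
#'   marker set (names taken from the first).
#' @return Data.frame with `marker`, `mean_rank`, `two_ln_bf_avg`,
#'   `two_ln_bf_min`, `two_ln_bf_max`, sorted by `mean_rank`.
#' @export
mean_rank_consensus <- function(bf_tables) {
  stopifnot(is.list(bf_tables), length(bf_tables) >= 1L)
  M <- length(bf_tables[[1L]])
  stopifnot(all(vapply(bf_tables, length, 1L) == M))
  B <- do.call(rbind, bf_tables)
  ranks <- t(apply(B, 1L, function(v) rank(-v, ties.method = "average")))
  ids <- names(bf_tables[[1L]])
  if (is.null(ids)) ids <- paste0("snp", seq_len(M))
  out <- data.frame(marker = ids, mean_rank = colMeans(ranks),
                    two_ln_bf_avg = colMeans(B),
                    two_ln_bf_min = apply(B, 2L, min),
                    two_ln_bf_max = apply(B, 2L, max), row.names = NULL)
  out[order(out$mean_rank), , drop = FALSE]
}

#' Pairwise chain comparison on a marker subset
#'
#' For a subset of markers (typically those with the strongest consensus
#' signals), the upper triangle of the returned matrix holds pairwise
#' Spearman rank correlations of `2 ln(BF)` between chains; the lower
#' triangle holds the mean, over the subset, of the ratios
#' `2lnBF(chain row) / 2lnBF(chain column)`, quantifying systematic
#' magnitude differences. Diagonals are `NA`.
#'
#' @param bf_tables list of per-chain `2 ln(BF)` vectors.
#' @param subset indices or marker names of the comparison subset; all
#'   `2 ln(BF)` values on the subset must be positive for the ratios.
#' @return An object of class `chain_comparison`: list with `rank_corr`
#'   and `mean_ratio` merged into one matrix `matrix` plus the two parts.
#' @export
chain_comparison <- function(bf_tables, subset) {
  stopifnot(is.list(bf_tables), length(bf_tables) >= 2L, length(subset) >= 1L)
  B <- do.call(rbind, lapply(bf_tables, function(v) v[subset]))
  if (any(B <= 0))
    stop("all 2 ln(BF) on the comparison subset must be positive; ",
         "choose a subset of markers with signal")
  n <- nrow(B)
  rho <- matrix(NA_real_, n, n)
  ratio <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) rho[i, j] <- stats::cor(B[i, ], B[j, ], method = "spearman")
      if (i > j) ratio[i, j] <- mean(B[i, ] / B[j, ])
    }
  }
  combined <- rho
  combined[lower.tri(combined)] <- ratio[lower.tri(ratio)]
  nm <- names(bf_tables)
  if (is.null(nm)) nm <- paste0("chain", seq_len(n))
  dimnames(combined) <- dimnames(rho) <- dimnames(ratio) <- list(nm, nm)
  structure(list(matrix = combined, rank_corr = rho, mean_ratio = ratio),
            class = "chain_comparison")
}

#' @export
print.chain_comparison <- function(x, ...) {
  cat("chain comparison (upper: Spearman rho; lower: mean 2lnBF ratio",
      "row/column)\n")
  print(round(x$matrix, 2))
  invisible(x)
}

#' Write a marker report as TSV
#'
#' @param report a [marker_report()] data.frame.
#' @param path output path.
#' @param panel optional [genotype_panel()] supplying `chrom`/`pos_cM`
#'   columns.
#' @return `path`, invisibly.
#' @export
write_marker_report <- function(report, path, panel = NULL) {
  out <- report
  if (!is.null(panel)) {
    out$chrom <- panel$chrom[match(out$marker, panel$marker_ids)]
    out$pos_cM <- panel$pos_cM[match(out$marker, panel$marker_ids)]
  }
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
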