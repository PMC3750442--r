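#' Simulation configuration
#'
#' Describes a multi-generation sire x dam breeding design with full-sib
#' families nested in half-sib sire groups, a dense equidistant SNP map and
#' an additive QTL architecture with known true breeding values.
#'
#' @param n_sires,n_dams_per_sire,n_offspring_per_mating pedigree design:
#'   each sire is mated to `n_dams_per_sire` dams, each mating produces one
#'   full-sib family of `n_offspring_per_mating` offspring.
#' @param n_generations_train,n_generations_validate phenotyped training
#'   generations and unphenotyped validation generations (TBV known).
#' @param n_chrom,markers_per_chrom,spacing_cM marker map; markers are
#'   equidistant at `spacing_cM` centiMorgans.
#' @param n_qtl number of additive QTL, placed on randomly chosen markers.
#' @param qtl_effect fixed magnitude of every QTL effect (sign random);
#'   ignored when `qtl_effect_sd` is given.
#' @param qtl_effect_sd if non-`NULL`, effects are drawn
#'   `N(0, qtl_effect_sd^2)` instead of having fixed magnitude.
#' @param qtl_min_maf QTL are restricted to markers whose training-set
#'   allele frequency is at least this far from 0 and 1, so every simulated
#'   QTL is in principle detectable.
#' @param target_h2 narrow-sense heritability targeted in the training set;
#'   the residual variance is solved from the realized TBV variance.
#' @param family_env_var common-environment variance shared by full sibs
#'   (distinct from the analysis model's family effect; default 0).
#' @param founder_maf_range founder allele frequencies are drawn uniformly
#'   from this interval; founders are in linkage equilibrium.
#' @param seed RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sires = 15L, n_dams_per_sire = 6L,
                       n_offspring_per_mating = 6L,
                       n_generations_train = 1L, n_generations_validate = 1L,
                       n_chrom = 2L, markers_per_chrom = 250L,
                       spacing_cM = 1, n_qtl = 10L, qtl_effect = 1,
                       qtl_effect_sd = NULL, qtl_min_maf = 0.2,
                       target_h2 = 0.30, family_env_var = 0,
                       founder_maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(target_h2 > 0, target_h2 < 1, spacing_cM > 0,
            n_qtl <= n_chrom * markers_per_chrom, n_generations_train >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' QTLMAS-style presets
#'
#' Two ready-made [sim_config()]s emulating a multi-generation full-sib /
#' half-sib breeding design with a dense SNP map and a trait of
#' heritability 0.30. The `"full"` preset mirrors the published design
#' scale: 15 sires x 10 dams x 10 offspring (1500 per generation, families
#' of 10), 3 training plus 3 validation generations, 6 chromosomes with
#' 1000 markers each at 0.1 cM, 50 QTL. The `"desk"` preset is a reduced
#' configuration sized for routine testing: 15 sires x 6 dams x 6 offspring
#' (540 training individuals in 90 families), 1 training plus 1 validation
#' generation, 2 chromosomes with 250 markers each at 1 cM, 10 QTL.
#'
#' @param scale `"desk"` or `"full"`.
#' @param seed RNG seed stored in the config.
#' @return A `sim_config`.
#' @export
qtlmas_like_preset <- function(scale = c("desk", "full"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "full") {
    sim_config(n_sires = 15L, n_dams_per_sire = 10L,
               n_offspring_per_mating = 10L, n_generations_train = 3L,
               n_generations_validate = 3L, n_chrom = 6L,
               markers_per_chrom = 1000L, spacing_cM = 0.1, n_qtl = 50L,
               target_h2 = 0.30, seed = seed)
  } else {
    sim_config(seed = seed)
  }
}

# one gamete from a parent's two haplotypes, Haldane (no-interference)
# recombination between adjacent markers; chromosome starts segregate
# independently (switch probability 1/2)
meiosis <- function(h1, h2, switch_prob) {
  phase <- cumsum(stats::runif(length(h1)) < switch_prob) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Simulate a pedigreed SNP population with known breeding values
#'
#' Founder haplotypes are drawn marker-wise from Bernoulli(f_m) with
#' `f_m ~ U(founder_maf_range)` (linkage equilibrium); offspring haplotypes
#' are produced by gene dropping with Haldane recombination
#' (recombination fraction `(1 - exp(-2d)) / 2` at map distance `d` in
#' Morgans), generating
#' realistic within-family LD through the pedigree. Additive QTL effects at
#' marker positions define the true breeding value
#' `TBV_i = sum_q a_q x_iq` (centered coding), and the residual variance is
#' solved so the training-set heritability matches `target_h2`:
#' `sigma_e^2 = var(TBV) (1 - h2) / h2 - family_env_var`. Validation
#' generations carry TBV but no phenotype.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `mu_sim` with training components (`panel`,
#'   `phen`, `fam`, all centered coding), validation components
#'   (`panel_validate`, `fam_validate`) and `truth` (`qtl_idx`,
#'   `qtl_effects`, `tbv_train`, `tbv_validate`, `realized_h2`,
#'   `generation`, `pedigree`).
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  M <- cfg$n_chrom * cfg$markers_per_chrom
  chrom <- rep(seq_len(cfg$n_chrom), each = cfg$markers_per_chrom)
  pos <- rep(seq_len(cfg$markers_per_chrom) - 1L, cfg$n_chrom) * cfg$spacing_cM
  # Haldane recombination fraction between adjacent markers; independent
  # assortment at every chromosome start
  d_morgan <- cfg$spacing_cM / 100
  rec <- rep(0.5 * (1 - exp(-2 * d_morgan)), M)
  rec[c(TRUE, diff(chrom) != 0)[seq_len(M)]] <- 0.5
  rec[1L] <- 0.5
  freqs <- stats::runif(M, cfg$founder_maf_range[1L], cfg$founder_maf_range[2L])

  n_dams <- cfg$n_sires * cfg$n_dams_per_sire
  n_par <- cfg$n_sires + n_dams
  H1 <- matrix(stats::rbinom(n_par * M, 1L, rep(freqs, each = n_par)),
               n_par, M)
  H2 <- matrix(stats::rbinom(n_par * M, 1L, rep(freqs, each = n_par)),
               n_par, M)

  n_gen <- cfg$n_generations_train + cfg$n_generations_validate
  fam_per_gen <- cfg$n_sires * cfg$n_dams_per_sire
  off_per_gen <- fam_per_gen * cfg$n_offspring_per_mating
  G1 <- matrix(0L, n_gen * off_per_gen, M)
  G2 <- matrix(0L, n_gen * off_per_gen, M)
  family <- integer(n_gen * off_per_gen)
  generation <- integer(n_gen * off_per_gen)
  sire_of <- integer(n_gen * off_per_gen)
  dam_of <- integer(n_gen * off_per_gen)

  row <- 0L
  fam_id <- 0L
  for (g in seq_len(n_gen)) {
    if (g > 1L) {
      # parents of generation g are sampled from generation g-1 offspring
      prev <- which(generation == g - 1L)
      picks <- sample(prev, n_par)
      H1 <- G1[picks, , drop = FALSE]
      H2 <- G2[picks, , drop = FALSE]
    }
    sires <- seq_len(cfg$n_sires)
    dams <- cfg$n_sires + seq_len(n_dams)
    di <- 0L
    for (s in sires) {
      for (dd in seq_len(cfg$n_dams_per_sire)) {
        di <- di + 1L
        dam <- dams[di]
        fam_id <- fam_id + 1L
        for (o in seq_len(cfg$n_offspring_per_mating)) {
          row <- row + 1L
          G1[row, ] <- meiosis(H1[s, ], H2[s, ], rec)
          G2[row, ] <- meiosis(H1[dam, ], H2[dam, ], rec)
          family[row] <- fam_id
          generation[row] <- g
          sire_of[row] <- s
          dam_of[row] <- dam
        }
      }
    }
  }

  X <- G1 + G2 - 1L  # centered coding
  storage.mode(X) <- "double"
  is_train <- generation <= cfg$n_generations_train
  train <- which(is_train)
  valid <- which(!is_train)

  # QTL on common markers of the training set
  p_train <- (colMeans(X[train, , drop = FALSE]) + 1) / 2
  candidates <- which(pmin(p_train, 1 - p_train) >= cfg$qtl_min_maf)
  if (length(candidates) < cfg$n_qtl)
    stop("not enough common markers to place the requested QTL")
  qtl_idx <- sort(sample(candidates, cfg$n_qtl))
  effects <- if (!is.null(cfg$qtl_effect_sd)) {
    stats::rnorm(cfg$n_qtl, 0, cfg$qtl_effect_sd)
  } else {
    cfg$qtl_effect * sample(c(-1, 1), cfg$n_qtl, replace = TRUE)
  }
  tbv <- as.vector(X[, qtl_idx, drop = FALSE] %*% effects)

  v_tbv <- stats::var(tbv[train])
  sigma_e2 <- v_tbv * (1 - cfg$target_h2) / cfg$target_h2 - cfg$family_env_var
  if (sigma_e2 <= 0)
    stop("infeasible configuration: family_env_var exceeds the residual ",
         "variance implied by target_h2")
  fam_env <- stats::rnorm(fam_id, 0, sqrt(cfg$family_env_var))
  y <- tbv + fam_env[family] + stats::rnorm(length(tbv), 0, sqrt(sigma_e2))
  realized_h2 <- v_tbv / stats::var(y[train])

  ids <- paste0("snp", seq_len(M))
  mk_panel <- function(rows) {
    genotype_panel(X[rows, , drop = FALSE], ids, chrom, pos,
                   coding = "centered")
  }
  structure(list(
    panel = mk_panel(train),
    phen = phenotype_set(y[train]),
    fam = family_map(family[train]),
    panel_validate = if (length(valid)) mk_panel(valid) else NULL,
    fam_validate = if (length(valid)) family_map(family[valid]) else NULL,
    truth = list(qtl_idx = qtl_idx, qtl_effects = effects,
                 qtl_marker_ids = ids[qtl_idx],
                 tbv_train = tbv[train], tbv_validate = tbv[valid],
                 realized_h2 = realized_h2, sigma_e2 = sigma_e2,
                 generation = generation,
                 pedigree = data.frame(id = seq_along(family),
                                       family = family,
                                       generation = generation,
                                       sire = sire_of, dam = dam_of)),
    config = cfg), class = "mu_sim")
}

#' @export
print.mu_sim <- function(x, ...) {
  cat(sprintf(
    "mu_sim: %d training + %d validation individuals, %d markers, %d QTL (realized h2 = %.3f)\n",
    nrow(x$panel$dosage),
    if (is.null(x$panel_validate)) 0L else nrow(x$panel_validate$dosage),
    ncol(x$panel$dosage), length(x$truth$qtl_idx), x$truth$realized_h2))
  invisible(x)
}

#' Write a simulated data set as delimited text
#'
#' Emits the genotype, phenotype and family TSVs the package readers
#' consume, plus the ground truth (QTL catalogue and TBV).
#'
#' @param sim a `mu_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "mu_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(sim$panel$dosage)
  ids <- paste0("ind", seq_len(n))
  write_genotypes(sim$panel, file.path(dir, "genotypes.tsv"), ids = ids)
  utils::write.table(data.frame(id = ids, value = sim$phen$y),
                     file.path(dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = ids,
                                family = sim$fam$family_of),
                     file.path(dir, "families.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(qtl_index = sim$truth$qtl_idx,
                                marker = sim$truth$qtl_marker_ids,
                                effect = sim$truth$qtl_effects),
                     file.path(dir, "qtl_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = ids, tbv = sim$truth$tbv_train),
                     file.path(dir, "tbv.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
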