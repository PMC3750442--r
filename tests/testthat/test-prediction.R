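test_that("gebv is the linear marker score with correct back-scaling", {
  p <- make_panel(30, 5, coding = "centered", seed = 2)
  expect_equal(gebv(rep(0, 5), p), rep(0, 30))
  b <- c(1, 0, 0, 0, 0)
  expect_equal(gebv(b, p), p$dosage[, 1])
  # standardized fit back-transformed equals the original-scale score up to
  # an additive constant
  y <- phenotype_set(rnorm(30, 10, 3))
  std <- standardize_fit(p, y)
  beta_std <- rnorm(5, 0, 0.1)
  g_std <- gebv(beta_std, p, scaling = std$scaling)
  beta_orig <- beta_std / std$scaling$x_sds * std$scaling$y_sd
  g_orig <- as.vector(p$dosage %*% beta_orig)
  expect_equal(g_std - mean(g_std), g_orig - mean(g_orig), tolerance = 1e-10)
})

test_that("accuracy, rank-correlation and bias metrics are exact", {
  set.seed(8)
  g <- rnorm(50); t_ <- 2 * g + rnorm(50, 0, 0.1)
  expect_equal(accuracy_tbv(g, g), 1)
  expect_equal(accuracy_tbv(g, -g), -1)
  expect_equal(accuracy_tbv(g, t_), cov(g, t_) / sqrt(var(g) * var(t_)),
               tolerance = 1e-12)
  expect_error(accuracy_tbv(rep(1, 5), rnorm(5)), "zero variance")
  # accuracy under positive affine transforms of gebv is invariant
  expect_equal(accuracy_tbv(3 * g + 2, t_), accuracy_tbv(g, t_))
  expect_equal(accuracy_cv(g, t_, 0.62), cor(g, t_) / sqrt(0.62))
  expect_equal(round(0.52 / sqrt(0.62), 3), 0.66)
  expect_equal(accuracy_cv(g, t_, 1), cor(g, t_))
  expect_error(accuracy_cv(g, t_, 0), "h2")
  expect_equal(bias(g, g), 1)
  expect_equal(bias(g, 2 * g), 2)
  expect_equal(bias(g, t_), cov(g, t_) / var(g), tolerance = 1e-14)
})

test_that("top-decile rank correlation selects ceil(N/10) by TBV", {
  set.seed(4)
  tbv <- rnorm(95)
  gv <- tbv + rnorm(95, 0, 0.05)
  expect_equal(top_decile_rank_corr(tbv, tbv), 1)
  top <- order(tbv, decreasing = TRUE)[seq_len(10)]  # ceiling(95/10)
  expect_equal(top_decile_rank_corr(gv, tbv),
               cor(gv[top], tbv[top], method = "spearman"))
})

test_that("cv plans partition individuals according to their scheme", {
  fam <- family_map(rep(1:40, each = 10))
  p1 <- make_cv_plan(fam, "family_blocked", seed = 3)
  expect_equal(sort(unique(p1$fold_of)), 1:10)
  expect_equal(as.vector(table(p1$fold_of)), rep(40, 10))
  # every family intact within one fold
  expect_true(all(tapply(p1$fold_of, fam$family_of,
                         function(v) length(unique(v))) == 1))
  p2 <- make_cv_plan(fam, "within_family", seed = 3)
  # no two sibs share a fold
  expect_true(all(tapply(p2$fold_of, fam$family_of,
                         function(v) !anyDuplicated(v))))
  expect_identical(make_cv_plan(fam, "within_family", seed = 3)$fold_of,
                   p2$fold_of)
  big <- family_map(rep(1:3, each = 12))
  expect_error(make_cv_plan(big, "within_family"), "spread")
  p3 <- make_cv_plan(fam, "random_individual", seed = 1)
  expect_equal(length(p3$fold_of), 400L)
  expect_equal(sort(unique(p3$fold_of)), 1:10)
})

test_that("average_gebv is the elementwise mean", {
  v <- rnorm(20)
  expect_equal(average_gebv(list(v, v, v)), v)
  expect_equal(average_gebv(list(v, -v)), rep(0, 20))
  l <- replicate(5, rnorm(20), simplify = FALSE)
  brute <- Reduce(`+`, l) / 5
  expect_equal(average_gebv(l), brute)
})

test_that("SIS ranks by absolute marginal correlation and is nested", {
  set.seed(44)
  p <- make_panel(100, 30, coding = "centered", seed = 44,
                  freqs = runif(30, 0.25, 0.5))
  y <- p$dosage[, 12] * 1 + rnorm(100, 0, 0.3)
  sel <- sis_select(p, y, k = 5, min_maf = 0.05)
  expect_equal(sel$idx[1], 12L)
  # brute-force ranking agreement
  ac <- abs(cor(p$dosage, y))[, 1]
  maf <- panel_maf(p)
  pool <- which(maf > 0.05)
  brute <- pool[order(ac[pool], decreasing = TRUE)][1:5]
  expect_equal(sel$idx, brute)
  # nested property
  top3 <- sis_select(p, y, k = 3)$idx
  top10 <- sis_select(p, y, k = 10)$idx
  expect_true(all(top3 %in% top10))
  expect_equal(sis_select(p, y, k = length(pool))$idx %in% pool,
               rep(TRUE, length(pool)))
  expect_error(sis_select(p, y, k = 1000), "exceeds")
})

test_that("cross-validation recovers strong signal and nulls out shuffled data", {
  set.seed(50)
  sim <- simulate_population(sim_config(n_sires = 8, n_dams_per_sire = 4,
                                        n_offspring_per_mating = 6,
                                        n_chrom = 1, markers_per_chrom = 60,
                                        n_qtl = 5, target_h2 = 0.6,
                                        seed = 50))
  plan <- make_cv_plan(sim$fam, "family_blocked", seed = 2)
  specs <- list(mu_prior_spec(0.99, 0.01, 1), mu_prior_spec(0.999, 0.01, 1))
  cv <- run_cv(sim$panel, sim$phen, specs, plan, fitter = "gem", h2 = 0.6)
  acc <- cv$metrics$accuracy
  expect_gt(acc[length(acc)], 0.5)              # combined
  expect_true(all(is.finite(cv$combined)))
  expect_equal(cv$combined, rowMeans(cv$gebv))
  # shuffled phenotype: accuracy collapses towards 0
  shuf <- phenotype_set(sample(sim$phen$y))
  cv0 <- run_cv(sim$panel, shuf, specs[1], plan, fitter = "gem", h2 = 0.6)
  expect_lt(abs(cv0$metrics$accuracy[1]), 0.25)
})

test_that("within-training CV accuracy exceeds forward prediction accuracy", {
  sim <- simulate_population(sim_config(n_sires = 10, n_dams_per_sire = 4,
                                        n_offspring_per_mating = 6,
                                        n_chrom = 1, markers_per_chrom = 80,
                                        n_qtl = 6, target_h2 = 0.5,
                                        n_generations_validate = 2L,
                                        seed = 61))
  std <- standardize_fit(sim$panel, sim$phen)
  spec <- mu_prior_spec(0.99, 0.02, 1)
  fit <- gem_fit(std$panel, std$phen, spec)
  # forward accuracy to the *last* (most distant) validation generation
  vgen <- sim$truth$generation[sim$truth$generation > 1]
  last <- vgen == max(vgen)
  g_fwd <- gebv(fit$state$beta,
                subset_individuals(sim$panel_validate, which(last)),
                scaling = std$scaling)
  acc_fwd <- accuracy_tbv(g_fwd, sim$truth$tbv_validate[last])
  plan <- make_cv_plan(sim$fam, "family_blocked", seed = 5)
  cv <- run_cv(sim$panel, sim$phen, spec, plan, fitter = "gem", h2 = 0.5)
  expect_gt(cv$metrics$accuracy[1], acc_fwd - 0.05)
})

test_that("leaky SIS does not underperform clean SIS on average", {
  set.seed(70)
  accs <- sapply(1:3, function(s) {
    sim <- simulate_population(sim_config(n_sires = 8, n_dams_per_sire = 3,
                                          n_offspring_per_mating = 6,
                                          n_chrom = 1, markers_per_chrom = 120,
                                          n_qtl = 4, target_h2 = 0.5,
                                          founder_maf_range = c(0.15, 0.5),
                                          seed = 70 + s))
    plan <- make_cv_plan(sim$fam, "family_blocked", seed = s)
    spec <- mu_prior_spec(0.99, 0.02, 1)
    clean <- run_cv(sim$panel, sim$phen, spec, plan, fitter = "gem", h2 = 0.5,
                    sis_k = 30, sis_maf = 0.05)
    leaky <- run_cv(sim$panel, sim$phen, spec, plan, fitter = "gem", h2 = 0.5,
                    sis_k = 30, sis_maf = 0.05, leaky_sis = TRUE)
    c(clean = clean$metrics$accuracy[1], leaky = leaky$metrics$accuracy[1])
  })
  expect_gte(mean(accs["leaky", ]), mean(accs["clean", ]) - 0.02)
})
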