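# minimal hand-built chain for inference arithmetic
fake_chain <- function(beta, spec, sigma2 = NULL, sigma2_u = NULL,
                       polygenic = FALSE) {
  S <- abs(beta) >= spec$b & abs(beta) <= spec$l
  storage.mode(S) <- "integer"
  if (is.null(sigma2)) sigma2 <- rep(1, nrow(beta))
  structure(list(beta = beta, S = S, sigma2 = sigma2, sigma2_u = sigma2_u,
                 spec = spec, marker_ids = colnames(beta),
                 polygenic = polygenic),
            class = "mu_chain")
}

test_that("inclusion probabilities are clipped at the boundary", {
  spec <- mu_prior_spec(0.99, 0.1, 1)
  beta <- matrix(0, 100, 2, dimnames = list(NULL, c("a", "b")))
  beta[, 2] <- rep(c(0.5, 0), 50)  # alternating in/out
  ch <- fake_chain(beta, spec)
  p <- inclusion_prob(ch)
  expect_equal(unname(p[1]), 1 / 200)   # all-spike draws clip to 1/(2T)
  expect_equal(unname(p[2]), 0.5)
  beta[, 1] <- 0.5                      # always included clips to 1 - 1/(2T)
  expect_equal(unname(inclusion_prob(fake_chain(beta, spec))[1]), 1 - 1 / 200)
})

test_that("Bayes factor arithmetic matches the odds-ratio definition", {
  expect_equal(bayes_factor(0.5, 0.999), 999)
  expect_equal(2 * log(bayes_factor(0.5, 0.999)), 13.81, tolerance = 1e-3)
  expect_equal(bayes_factor(0.9, 0.99), 891)
  # uninformative data: posterior equals prior inclusion mass
  expect_equal(bayes_factor(1 - 0.99, 0.99), 1)
  expect_error(bayes_factor(0, 0.99), "clip")
  expect_error(bayes_factor(1, 0.99), "clip")
  # monotone in p_incl and in p0
  expect_true(all(diff(bayes_factor(seq(0.1, 0.9, 0.1), 0.99)) > 0))
  expect_true(all(diff(sapply(c(0.9, 0.99, 0.999),
                              function(p0) bayes_factor(0.4, p0))) > 0))
})

test_that("evidence categories honor the Kass-Raftery bounds", {
  # right-closed intervals: 2lnBF of exactly 6 is "positive", 10 is "strong"
  expect_equal(as.character(evidence_category(c(11, 10, 6.5, 6, 2.5, 2, 0.5,
                                                0, -1))),
               c("very strong", "strong", "strong", "positive", "positive",
                 "bare mention", "bare mention", "none", "none"))
})

test_that("N_Q summary recounts indicators from raw draws", {
  spec <- mu_prior_spec(0.9, 0.2, 2)
  set.seed(66)
  beta <- matrix(runif(300, -1, 1), 50, 6,
                 dimnames = list(NULL, paste0("m", 1:6)))
  ch <- fake_chain(beta, spec)
  nq <- nq_summary(ch)
  recount <- rowSums(abs(beta) >= 0.2 & abs(beta) <= 2)
  expect_equal(nq$draws, recount, ignore_attr = TRUE)
  expect_equal(nq$mean, mean(recount))
  # degenerate cases
  ch0 <- fake_chain(matrix(0, 20, 3, dimnames = list(NULL, letters[1:3])),
                    spec)
  expect_equal(nq_summary(ch0)$mean, 0)
  ch1 <- fake_chain(matrix(c(rep(0.5, 20), rep(0, 40)), 20, 3,
                           dimnames = list(NULL, letters[1:3])), spec)
  expect_equal(nq_summary(ch1)$mean, 1)
  expect_equal(nq_summary(ch1)$sd, 0)
})

test_that("marker heritability follows 1 - (sigma2 + 2 sigma2_u)/var(Y)", {
  spec <- mu_prior_spec(0.9, 0.1, 1)
  beta <- matrix(0, 10, 1, dimnames = list(NULL, "m"))
  ch <- fake_chain(beta, spec, sigma2 = rep(0.7, 10),
                   sigma2_u = rep(0.05, 10), polygenic = TRUE)
  expect_equal(marker_h2(ch, var_y = 1)$mean, 1 - (0.7 + 0.1))
  ch2 <- fake_chain(beta, spec, sigma2 = rep(1, 10))
  expect_equal(marker_h2(ch2, var_y = 1)$mean, 0)
  ch3 <- fake_chain(beta, spec, sigma2 = rep(0.7, 10))
  expect_equal(marker_h2(ch3, var_y = 1)$mean, 0.3, tolerance = 1e-12)
})

test_that("%PVE uses the posterior mean of beta squared", {
  spec <- mu_prior_spec(0.9, 0.1, 2)
  beta <- matrix(c(rep(1, 10), rep(c(-1, 1), 5)), 10, 2,
                 dimnames = list(NULL, c("m1", "m2")))
  ch <- fake_chain(beta, spec)
  out <- pve(ch, maf = c(0.5, 0.5), var_y = 1)
  expect_equal(unname(out), c(50, 50))  # E[beta^2] = 1 for both
  # squared-mean would give 0 for the sign-flipping marker; E[beta^2] does not
  expect_equal(unname(pve(fake_chain(matrix(0, 10, 1,
                                            dimnames = list(NULL, "z")),
                                     spec),
                          0.3, 1)), 0)
})

test_that("mean-rank consensus is permutation invariant and handles ties", {
  b1 <- c(a = 10, b = 5, c = 1)
  b2 <- c(a = 8, b = 6, c = 2)
  cons <- mean_rank_consensus(list(b1, b2))
  expect_equal(cons$marker, c("a", "b", "c"))
  expect_equal(cons$mean_rank, c(1, 2, 3))
  expect_equal(cons$two_ln_bf_avg, c(9, 5.5, 1.5))
  expect_equal(cons$two_ln_bf_min, c(8, 5, 1))
  expect_equal(cons$two_ln_bf_max, c(10, 6, 2))
  # identical chains reproduce the single-chain ranking
  expect_equal(mean_rank_consensus(list(b1, b1))$mean_rank, c(1, 2, 3))
  # reversed rankings average out
  r1 <- c(x = 10, y = 2); r2 <- c(x = 2, y = 10)
  expect_equal(mean_rank_consensus(list(r1, r2))$mean_rank, c(1.5, 1.5))
  # chain order does not matter
  expect_equal(mean_rank_consensus(list(b2, b1))$mean_rank,
               mean_rank_consensus(list(b1, b2))$mean_rank)
})

test_that("chain comparison produces Spearman upper and ratio lower triangles", {
  b1 <- c(m1 = 4, m2 = 8, m3 = 12, m4 = 2)
  b2 <- 2 * b1
  cc <- chain_comparison(list(A = b1, B = b2), subset = 1:4)
  expect_equal(cc$rank_corr["A", "B"], 1)
  expect_equal(cc$mean_ratio["B", "A"], 2)
  self <- chain_comparison(list(A = b1, B = b1), subset = 1:4)
  expect_equal(self$mean_ratio["B", "A"], 1)
  expect_true(all(is.na(diag(cc$matrix))))
  # agrees with an independent rank-correlation implementation
  set.seed(5)
  r1 <- setNames(runif(15, 0.1, 20), paste0("s", 1:15))
  r2 <- setNames(runif(15, 0.1, 20), paste0("s", 1:15))
  cc2 <- chain_comparison(list(r1, r2), subset = 1:15)
  brute <- cor(rank(r1), rank(r2))
  expect_equal(cc2$rank_corr[1, 2], brute, tolerance = 1e-12)
  expect_error(chain_comparison(list(c(a = 0, b = 1), c(a = 1, b = 1)),
                                subset = 1:2), "positive")
})

test_that("marker_report assembles consistent columns", {
  spec <- mu_prior_spec(0.99, 0.05, 1)
  set.seed(20)
  beta <- matrix(rnorm(400, 0, 0.05), 100, 4,
                 dimnames = list(NULL, paste0("m", 1:4)))
  beta[, 3] <- 0.5
  ch <- fake_chain(beta, spec)
  rep_ <- marker_report(ch, maf = rep(0.3, 4), var_y = 1)
  expect_equal(rep_$bf, bayes_factor(rep_$p_incl, 0.99), ignore_attr = TRUE)
  expect_equal(rep_$two_ln_bf, 2 * log(rep_$bf))
  expect_equal(rep_$beta_mean, colMeans(beta), ignore_attr = TRUE)
  expect_gt(rep_$two_ln_bf[3], 10)
  expect_equal(as.character(rep_$category[3]), "very strong")
  expect_true(all(rep_$pve >= 0))
})
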