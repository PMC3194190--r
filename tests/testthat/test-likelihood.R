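test_that("allele frequency is the mean per-pool minor fraction", {
  cnt <- pool_counts(y_major = c(80, 60), y_minor = c(20, 40))
  expect_equal(estimate_allele_freq(cnt), 0.3)
  expect_equal(estimate_allele_freq(cnt, weighted = TRUE), 60 / 200)
  expect_equal(estimate_allele_freq(pool_counts(y_major = c(5, 9), y_minor = c(0, 0))), 0)
  expect_error(estimate_allele_freq(pool_counts(y_major = c(0, 0), y_minor = c(0, 0))),
               "zero reads")
})

test_that("allele frequency estimate is consistent on simulated cohorts", {
  d <- generate_random_design(60, 8, seed = 1)
  np <- noise_params(sigma_p = 0, epsilon = 0, coverage_lambda = 150)
  ph <- vapply(1:80, function(s) {
    g <- simulate_genotypes_hwe(0.3, 60, seed = s)
    estimate_allele_freq(simulate_genotype_pools(g, d, np, seed = s + 1000))
  }, numeric(1))
  expect_lt(abs(mean(ph) - 0.3), 3.5 * sd(ph) / sqrt(80))
})

test_that("Hardy-Weinberg log-likelihood matches the genotype-count formula", {
  expect_equal(hwe_loglik(rep(1L, 10), 0.5), 10 * log(0.5))
  g <- c(rep(0L, 81), rep(1L, 18), rep(2L, 1))
  expect_equal(hwe_loglik(g, 0.1),
               81 * log(0.81) + 18 * log(0.18) + log(0.01))
  # zero-probability genotypes yield -Inf, not an error
  expect_identical(hwe_loglik(c(0L, 1L), 0), -Inf)
  expect_identical(hwe_loglik(rep(0L, 5), 0), 0)
})

test_that("the Hardy-Weinberg prior normalizes over all genotype vectors", {
  for (n in c(3, 5)) {
    G <- all_genotype_vectors(n)
    for (p in c(0.2, 0.5)) {
      total <- sum(exp(apply(G, 2, hwe_loglik, p_hat = p)))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("the imputation likelihood normalizes and matches direct evaluation", {
  pr <- imputation_prior(matrix(1 / 3, 4, 3))
  expect_equal(imputation_loglik(c(0L, 1L, 2L, 1L), pr), -4 * log(3))
  pr2 <- imputation_prior(matrix(rep(c(0.7, 0.2, 0.1), each = 5), 5))
  expect_equal(imputation_loglik(rep(0L, 5), pr2), 5 * log(0.7))
  # normalization by enumeration at N = 4
  G <- all_genotype_vectors(4)
  pr3 <- imputation_prior(rbind(c(0.5, 0.3, 0.2), c(0.1, 0.8, 0.1),
                                c(0.25, 0.5, 0.25), c(0.9, 0.05, 0.05)))
  total <- sum(exp(apply(G, 2, imputation_loglik, prior = pr3)))
  expect_equal(total, 1, tolerance = 1e-10)
  # point mass on the truth scores log(1) = 0
  prt <- imputation_prior(diag(3)[c(1, 2, 3), ])
  expect_equal(imputation_loglik(c(0L, 1L, 2L), prt), 0)
  expect_identical(imputation_loglik(c(1L, 1L, 2L), prt), -Inf)
})

test_that("noise log-likelihood peaks at the true means and guards zero means", {
  d <- small_design()
  g <- c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 0L)
  cnt <- exact_counts(g, d, 100)
  ll_true <- noise_loglik(g, d, 100, cnt, epsilon = 0, error_adjust = FALSE)
  G <- all_genotype_vectors(8)
  lls <- apply(G, 2, function(z)
    noise_loglik(as.integer(z), d, 100, cnt, epsilon = 0, error_adjust = FALSE))
  expect_equal(max(lls), ll_true)
  # epsilon = 0 with all-reference truth: positive minor count is impossible
  cnt2 <- pool_counts(y_major = cnt$y_major, y_minor = rep(1, 8))
  expect_identical(noise_loglik(rep(0L, 8), d, 100, cnt2, epsilon = 0,
                                error_adjust = TRUE), -Inf)
})

test_that("the true configuration usually outscores a single flipped genotype", {
  d <- generate_random_design(20, 10, seed = 2)
  np <- noise_params(sigma_p = 0, epsilon = 0.005, coverage_lambda = 150)
  wins <- 0L
  reps <- 60
  for (s in 1:reps) {
    g <- simulate_genotypes_hwe(0.3, 20, seed = s)
    cnt <- simulate_genotype_pools(g, d, np, seed = s + 500, per_pool = TRUE)
    flip <- ((s - 1) %% 20) + 1
    g2 <- g; g2[flip] <- (g[flip] + 1L) %% 3L
    a <- noise_loglik(g, d, 150, cnt, epsilon = 0.005)
    b <- noise_loglik(g2, d, 150, cnt, epsilon = 0.005)
    wins <- wins + (a > b)
  }
  expect_gte(wins / reps, 0.95)
})

test_that("composite likelihood is the weighted sum of its components", {
  d <- small_design()
  g <- simulate_genotypes_hwe(0.3, 8, seed = 3)
  np <- noise_params(sigma_p = 0, epsilon = 0.01, coverage_lambda = 60)
  cnt <- simulate_genotype_pools(g, d, np, seed = 4)
  pr <- simulate_imputation_priors(g, 0.9, 0.9, seed = 5)
  sc <- composite_loglik(g, d, 60, cnt, 0.01, prior = pr)
  expect_equal(sc$total, sc$hwe_loglik + sc$noise_loglik + sc$imputation_loglik)
  sc2 <- composite_loglik(g, d, 60, cnt, 0.01, prior = pr, weights = c(0, 1, 0))
  expect_equal(sc2$total, sc2$noise_loglik)
  # without a prior the imputation term is absent
  sc3 <- composite_loglik(g, d, 60, cnt, 0.01)
  expect_true(is.na(sc3$imputation_loglik))
  expect_equal(sc3$total, sc3$hwe_loglik + sc3$noise_loglik)
})

test_that("composite argmax agrees with independent brute-force enumeration", {
  A <- rbind(c(1, 0, 1), c(0, 1, 1))
  d <- pool_design(A)
  np <- noise_params(sigma_p = 0, epsilon = 0.01, coverage_lambda = 40)
  for (s in 1:5) {
    g <- simulate_genotypes_hwe(0.4, 3, seed = s)
    cnt <- simulate_genotype_pools(g, d, np, seed = s + 50)
    pr <- simulate_imputation_priors(g, 0.9, 0.8, seed = s + 100)
    G <- all_genotype_vectors(3)
    via_pkg <- apply(G, 2, function(z)
      composite_loglik(as.integer(z), d, 40, cnt, 0.01, prior = pr)$total)
    via_naive <- apply(G, 2, function(z)
      naive_composite(as.integer(z), A, 40, cnt, 0.01, prior = pr))
    expect_equal(which.max(via_pkg), which.max(via_naive))
    expect_equal(via_pkg, via_naive, tolerance = 1e-9)
  }
})

test_that("composite likelihood is invariant under consistent permutation", {
  d <- generate_random_design(10, 6, seed = 6)
  np <- noise_params(sigma_p = 0.05, epsilon = 0.01, coverage_lambda = 80)
  g <- simulate_genotypes_hwe(0.3, 10, seed = 7)
  nd <- perturb_design(d, 0.05, seed = 8)
  cnt <- simulate_genotype_pools(g, nd, np, seed = 9)
  pr <- simulate_imputation_priors(g, 0.9, 0.9, seed = 10)
  perm <- sample(10)
  nd_p <- noisy_design(nd$matrix[, perm],
                       pool_design(d$matrix[, perm], d$pool_ids, d$sample_ids[perm]))
  pr_p <- imputation_prior(pr$probs[perm, ])
  s1 <- composite_loglik(g, nd, 80, cnt, 0.01, prior = pr)
  s2 <- composite_loglik(g[perm], nd_p, 80, cnt, 0.01, prior = pr_p)
  expect_equal(s1$total, s2$total)
})

test_that("vectorized scorers agree with scalar composite evaluation", {
  d <- small_design()
  np <- noise_params(sigma_p = 0, epsilon = 0.01, coverage_lambda = 60)
  g <- simulate_genotypes_hwe(0.3, 8, seed = 11)
  cnt <- simulate_genotype_pools(g, d, np, seed = 12)
  pr <- simulate_imputation_priors(g, 0.9, 0.9, seed = 13)
  G <- all_genotype_vectors(8)[, sample(3^8, 40)]
  exact <- pooldecode:::composite_scores_matrix(G, d$matrix, 60, cnt, 0.01,
                                                prior = pr)
  scalar <- apply(G, 2, function(z)
    composite_loglik(as.integer(z), d, 60, cnt, 0.01, prior = pr)$total)
  expect_equal(exact, scalar, tolerance = 1e-9)
  # the fast scorer matches up to a common constant
  fast <- pooldecode:::composite_scores_fast(G, d$matrix, 60, cnt, 0.01,
                                             prior = pr)
  expect_equal(diff(range((exact - fast))), 0, tolerance = 1e-8)
})
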