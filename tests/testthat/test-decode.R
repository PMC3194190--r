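test_that("noiseless counts on a full-rank design are recovered exactly", {
  d <- small_design()
  g <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L)
  cnt <- exact_counts(g, d, 150)
  pr <- simulate_imputation_priors(g, 0.9, 0.9, seed = 1)
  # beta = 0: pure count fitting; the full-rank system pins x = g exactly
  res <- decode_lp(cnt, d, 150, pr, beta = 0, epsilon = 0)
  expect_equal(res$fractional_solution, as.numeric(g), tolerance = 1e-4)
  expect_identical(res$genotypes, g)
  expect_lt(res$lp_objective, 1e-2)
  # with the imputation anchor the objective also counts |x - I|, but the
  # genotypes are still recovered
  res1 <- decode_lp(cnt, d, 150, pr, beta = 1, epsilon = 0)
  expect_identical(res1$genotypes, g)
})

test_that("a dominant prior weight pins the solution to the rounded dosage", {
  d <- small_design()
  g <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L)
  cnt <- exact_counts(g, d, 150)
  dosage <- c(2, 0, 1, 0, 2, 0, 1, 2)  # deliberately contradicts the counts
  res <- decode_lp(cnt, d, 150, prior = dosage, beta = 1e7, epsilon = 0,
                   refine = FALSE)
  expect_identical(res$genotypes, as.integer(round(dosage)))
})

test_that("decode_rare equals decode_lp with a zero anchor", {
  d <- small_design()
  g <- c(0L, 0L, 1L, 0L, 0L, 0L, 1L, 0L)
  np <- noise_params(sigma_p = 0.05, epsilon = 0.005, coverage_lambda = 150)
  nd <- perturb_design(d, 0.05, seed = 2)
  cnt <- simulate_genotype_pools(g, nd, np, seed = 3)
  r1 <- decode_rare(cnt, nd, 150, beta = 1, epsilon = 0.005)
  r2 <- decode_lp(cnt, nd, 150, prior = rep(0, 8), beta = 1, epsilon = 0.005)
  expect_identical(r1$genotypes, r2$genotypes)
  expect_equal(r1$lp_objective, r2$lp_objective)
})

test_that("no carriers and no error decode to the zero vector with zero objective", {
  d <- small_design()
  cnt <- exact_counts(rep(0L, 8), d, 150)
  res <- decode_rare(cnt, d, 150, epsilon = 0)
  expect_identical(res$genotypes, rep(0L, 8))
  expect_lt(res$lp_objective, 1e-2)
})

test_that("a single heterozygous carrier is identified from noiseless counts", {
  d <- local_search_optimize(generate_random_design(10, 6, seed = 3), 200, seed = 3)
  for (carrier in c(2, 7, 10)) {
    g <- integer(10); g[carrier] <- 1L
    cnt <- exact_counts(g, d, 150)
    res <- decode_rare(cnt, d, 150, epsilon = 0)
    expect_identical(res$genotypes, g)
  }
})

test_that("the LP optimum lower-bounds the objective of integer vectors", {
  d <- generate_random_design(12, 8, seed = 4)
  np <- noise_params(sigma_p = 0.05, epsilon = 0.01, coverage_lambda = 100)
  nd <- perturb_design(d, 0.05, seed = 5)
  g <- simulate_genotypes_hwe(0.3, 12, seed = 6)
  cnt <- simulate_genotype_pools(g, nd, np, seed = 7)
  pr <- simulate_imputation_priors(g, 0.9, 0.9, seed = 8)
  res <- decode_lp(cnt, nd, 100, pr, beta = 1, epsilon = 0.01, refine = FALSE)
  w <- res$effective_prior_weight
  A <- nd$matrix
  objective <- function(z)
    sum(abs(100 * as.vector(A %*% z) - cnt$y_minor)) + w * sum(abs(z - pr$dosage))
  set.seed(9)
  for (r in 1:25) {
    z <- sample(0:2, 12, replace = TRUE)
    expect_gte(objective(z), res$lp_objective - 1e-6 * max(1, res$lp_objective))
  }
  expect_gte(objective(g), res$lp_objective - 1e-6)
})

test_that("the interior-point LP matches a simplex oracle on a small instance", {
  skip_if_not_installed("boot")
  # min |2x1 + x2 - 3| + |x1 - x2| + 0.5|x1 - 1| + 0.5|x2 - 1|, 0 <= x <= 2
  X <- rbind(c(2, 1), c(1, -1), diag(0.5, 2))
  yv <- c(3, 0, 0.5, 0.5)
  x <- pooldecode:::solve_l1_box(X, yv, c(0, 0), c(2, 2))
  obj <- sum(abs(yv - X %*% x))
  a <- c(0, 0, 1, 1, 0.5, 0.5)
  A1 <- rbind(c(2, 1, -1, 0, 0, 0), c(-2, -1, -1, 0, 0, 0),
              c(1, -1, 0, -1, 0, 0), c(-1, 1, 0, -1, 0, 0),
              c(1, 0, 0, 0, -1, 0), c(-1, 0, 0, 0, -1, 0),
              c(0, 1, 0, 0, 0, -1), c(0, -1, 0, 0, 0, -1),
              c(1, 0, 0, 0, 0, 0), c(0, 1, 0, 0, 0, 0))
  b1 <- c(3, -3, 0, 0, 1, -1, 1, -1, 2, 2)
  s <- boot::simplex(a, A1 = A1, b1 = b1)
  expect_equal(obj, unname(s$value), tolerance = 1e-8)
})

test_that("round_and_refine rounds unambiguous coordinates directly", {
  d <- pool_design(rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 0)))
  cnt <- exact_counts(c(0L, 1L, 2L), d, 50)
  expect_identical(round_and_refine(c(0, 1, 2), cnt, d, 50, 0, restarts = 0),
                   c(0L, 1L, 2L))
  d2 <- pool_design(rbind(c(1, 0), c(0, 1), c(1, 1)))
  cnt2 <- exact_counts(c(1L, 1L), d2, 50)
  expect_identical(round_and_refine(c(0.95, 1.05), cnt2, d2, 50, 0, restarts = 0),
                   c(1L, 1L))
})

test_that("ambiguous-coordinate resolution equals exhaustive floor/ceil enumeration", {
  d <- small_design()
  np <- noise_params(sigma_p = 0, epsilon = 0.005, coverage_lambda = 120)
  for (s in 1:6) {
    g <- simulate_genotypes_hwe(0.35, 8, seed = s)
    cnt <- simulate_genotype_pools(g, d, np, seed = s + 20, per_pool = TRUE)
    pr <- simulate_imputation_priors(g, 0.9, 0.9, seed = s + 40)
    set.seed(s + 60)
    frac <- pmin(2, pmax(0, g + sample(c(-1, 1), 8, TRUE) * runif(8, 0.25, 0.45)))
    got <- round_and_refine(frac, cnt, d, 120, 0.005, prior = pr,
                            polish = FALSE, restarts = 0)
    # independent oracle: enumerate every floor/ceil combination directly
    lo <- floor(frac); hi <- ceiling(frac)
    combos <- as.matrix(expand.grid(lapply(1:8, function(i) unique(c(lo[i], hi[i])))))
    p_hat <- estimate_allele_freq(cnt)
    scores <- apply(combos, 1, function(z)
      naive_composite(as.integer(z), d$matrix, 120, cnt, 0.005, prior = pr,
                      p_hat = p_hat))
    expect_equal(naive_composite(got, d$matrix, 120, cnt, 0.005, prior = pr,
                                 p_hat = p_hat),
                 max(scores), tolerance = 1e-9)
    if (sum(abs(scores - max(scores)) < 1e-9) == 1L)
      expect_identical(got, as.integer(combos[which.max(scores), ]))
  }
})

test_that("concentration calibration recovers the noisy design", {
  d <- generate_random_design(6, 4, seed = 10)
  set.seed(11)
  G <- matrix(rbinom(15 * 6, 2, 0.4), 15, 6)
  nd <- perturb_design(d, 0.05, seed = 12)
  Y <- 100 * G %*% t(nd$matrix)   # noiseless counts at the true concentrations
  est <- estimate_concentrations(d, G, Y, 100)
  expect_equal(est$matrix, nd$matrix, tolerance = 1e-8)
  # scalar case: single-sample pools, one site with g = 2
  d1 <- pool_design(rbind(c(1, 0), c(0, 1)), sample_ids = c("a", "b"))
  Y1 <- matrix(c(2 * 50 * 0.9, 2 * 50 * 1.1), 1)
  G1 <- matrix(c(2, 2), 1)
  est1 <- suppressWarnings(estimate_concentrations(d1, G1, Y1, 50))
  expect_equal(est1$matrix[1, 1], 0.9, tolerance = 1e-8)
  expect_equal(est1$matrix[2, 2], 1.1, tolerance = 1e-8)
})

test_that("calibration error decreases with more calibration sites", {
  d <- generate_random_design(8, 5, seed = 13)
  nd <- perturb_design(d, 0.05, seed = 14)
  mae <- function(S) {
    errs <- vapply(1:10, function(r) {
      set.seed(1000 * S + r)
      G <- matrix(rbinom(S * 8, 2, 0.4), S, 8)
      Y <- 150 * G %*% t(nd$matrix) + matrix(rnorm(S * 5, 0, 10), S, 5)
      Y[Y < 0] <- 0
      est <- estimate_concentrations(d, G, Y, 150)
      mean(abs(est$matrix - nd$matrix)[d$matrix == 1])
    }, numeric(1))
    mean(errs)
  }
  e1 <- mae(8); e2 <- mae(16); e3 <- mae(32)
  expect_gt(e1, e2)
  expect_gt(e2, e3)
})

test_that("calibration reports rank-deficient pools", {
  d <- pool_design(rbind(c(1, 1, 0), c(0, 1, 1)))
  G <- matrix(c(1, 1, 1, 1, 1, 1), 2, 3)  # identical genotype rows
  Y <- matrix(10, 2, 2)
  expect_error(suppressWarnings(estimate_concentrations(d, G, Y, 10)),
               "rank deficient")
})

test_that("brute force decoding maximizes the composite and bounds the LP result", {
  d <- local_search_optimize(generate_random_design(6, 6, seed = 15), 100, seed = 15)
  np <- noise_params(sigma_p = 0, epsilon = 0.005, coverage_lambda = 150)
  for (s in 1:8) {
    g <- simulate_genotypes_hwe(0.3, 6, seed = s)
    cnt <- simulate_genotype_pools(g, d, np, seed = s + 30, per_pool = TRUE)
    pr <- simulate_imputation_priors(g, 0.9, 0.9, seed = s + 60)
    bf <- brute_force_decode(cnt, d, 150, 0.005, prior = pr)
    lp <- decode_lp(cnt, d, 150, pr, epsilon = 0.005)
    sc <- function(z) composite_loglik(z, d, 150, cnt, 0.005, prior = pr)$total
    expect_gte(sc(bf), sc(lp$genotypes) - 1e-9)
  }
  expect_error(brute_force_decode(
    pool_counts(y_major = 1, y_minor = 1),
    pool_design(matrix(1, 1, 13), sample_ids = paste0("s", 1:13)), 10, 0), "N <= 12")
})

test_that("brute force on one noiseless heterozygote returns (1)", {
  d <- pool_design(matrix(1, 1, 1))
  cnt <- pool_counts(y_major = 50, y_minor = 50)
  expect_identical(brute_force_decode(cnt, d, 50, 0), 1L)
})

test_that("decoding is equivariant under sample permutation", {
  d <- generate_random_design(10, 8, seed = 16)
  np <- noise_params(sigma_p = 0.05, epsilon = 0.005, coverage_lambda = 150)
  g <- simulate_genotypes_hwe(0.3, 10, seed = 17)
  nd <- perturb_design(d, 0.05, seed = 18)
  cnt <- simulate_genotype_pools(g, nd, np, seed = 19)
  pr <- simulate_imputation_priors(g, 0.9, 0.9, seed = 20)
  res <- decode_lp(cnt, nd, 150, pr, epsilon = 0.005)
  set.seed(21)
  perm <- sample(10)
  nd_p <- noisy_design(nd$matrix[, perm],
                       pool_design(d$matrix[, perm], d$pool_ids, d$sample_ids[perm]))
  pr_p <- imputation_prior(pr$probs[perm, ])
  res_p <- decode_lp(cnt, nd_p, 150, pr_p, epsilon = 0.005)
  expect_identical(res_p$genotypes, res$genotypes[perm])
})

test_that("decoding accuracy does not improve as sequencing error grows", {
  d <- local_search_optimize(generate_random_design(12, 8, seed = 22), 200, seed = 22)
  acc <- vapply(c(0, 0.05), function(eps) {
    ok <- 0L
    for (s in 1:15) {
      g <- simulate_genotypes_hwe(0.25, 12, seed = s)
      np <- noise_params(sigma_p = 0, epsilon = eps, coverage_lambda = 60)
      cnt <- simulate_genotype_pools(g, d, np, seed = s + 70, per_pool = TRUE)
      pr <- simulate_imputation_priors(g, 0.9, 0.9, seed = s + 140)
      ok <- ok + all(decode_lp(cnt, d, 60, pr, epsilon = eps)$genotypes == g)
    }
    ok / 15
  }, numeric(1))
  expect_gte(acc[1], acc[2] - 0.15)
})
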