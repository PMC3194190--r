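test_that("carrier-set enumeration is complete and ordered", {
  sets <- enumerate_carrier_sets(3, 1)
  expect_identical(sets, list(1L, 2L, 3L))
  expect_identical(enumerate_carrier_sets(5, 0), list())
  sets2 <- enumerate_carrier_sets(5, 2)
  expect_length(sets2, 5 + 10)
  sizes <- lengths(sets2)
  expect_true(all(diff(sizes) >= 0))           # size-then-lex order
  expect_identical(sets2[[6]], c(1L, 2L))
  expect_error(enumerate_carrier_sets(4, 5), "exceeds")
  # binomial-coefficient total for the study-scale case
  expect_equal(choose(100, 1) + choose(100, 2) + choose(100, 3), 166750)
})

test_that("least-squares expression fit solves a consistent system exactly", {
  d <- small_design()
  A <- d$matrix
  carrier <- which(colSums(A) >= 3)[1]
  y <- 16 * 5 * A[, carrier]
  cand <- fit_expression_ls(carrier, d, pool_counts(y_fusion = y), 16)
  expect_equal(cand$expression_estimate, 5, tolerance = 1e-8)
  expect_equal(cand$per_pool_error, 0, tolerance = 1e-8)
  expect_lt(cand$ls_residual, 1e-8)
  expect_false(cand$degenerate)
})

test_that("the true carrier has strictly smaller residual than wrong singletons", {
  d <- local_search_optimize(generate_random_design(20, 8, seed = 1), 200, seed = 1)
  A <- d$matrix
  carrier <- 7
  y <- 16 * 2 * A[, carrier]
  cnt <- pool_counts(y_fusion = y)
  res_true <- fit_expression_ls(carrier, d, cnt, 16)$ls_residual
  for (j in setdiff(1:20, carrier)) {
    if (any(A[, j] != A[, carrier]))
      expect_gt(fit_expression_ls(j, d, cnt, 16)$ls_residual, res_true)
  }
})

test_that("rank_candidates sorts by residual with size-then-lex tie-breaks", {
  mk <- function(carriers, res, degenerate = FALSE)
    fusion_candidate(carriers, rep(1, length(carriers)), 0, res,
                     degenerate = degenerate)
  cands <- list(mk(c(2, 3), 5), mk(1, 5), mk(4, 2), mk(9, Inf, TRUE), mk(c(1, 2), 1))
  ranked <- rank_candidates(cands, top = 10)
  expect_identical(lapply(ranked, `[[`, "carriers"),
                   list(c(1L, 2L), 4L, 1L, c(2L, 3L)))
  top1 <- rank_candidates(cands, top = 1)
  expect_identical(top1[[1]]$carriers, c(1L, 2L))
  res <- vapply(ranked, `[[`, numeric(1), "ls_residual")
  expect_true(all(diff(res) >= 0))
})

test_that("grid refinement never scores below its starting point and recovers e", {
  d <- local_search_optimize(generate_random_design(15, 6, seed = 2), 150, seed = 2)
  A <- d$matrix
  carrier <- 4
  ok <- 0L
  reps <- 100
  for (s in 1:reps) {
    sim <- simulate_fusion_pools(carrier, 15, d, expression_fold_range = 1,
                                 coverage_lambda = 16, epsilon = 0.01, seed = s)
    cand <- fit_expression_ls(carrier, d, sim$counts, 16)
    ref <- grid_search_refine(cand, d, sim$counts, 16, epsilon = 0.01)
    start_e <- pmin(10, pmax(cand$expression_estimate, 1))
    ll_start <- pooldecode:::fusion_loglik(start_e, carrier, A,
                                           sim$counts$y_fusion, 16, 0.01)
    expect_gte(ref$refined_loglik, ll_start - 1e-9)
    ok <- ok + (abs(ref$expression_estimate - 1) <= 0.2)
  }
  expect_gte(ok / reps, 0.8)
})

test_that("grid refinement rejects bad grids and degenerate candidates", {
  d <- small_design()
  cnt <- pool_counts(y_fusion = rep(1, 8))
  cand <- fit_expression_ls(1, d, cnt, 16)
  expect_error(grid_search_refine(cand, d, cnt, 16, grid_spec = list(span = 0.5)),
               "span")
  bad <- fusion_candidate(1, NA_real_, NA_real_, Inf, degenerate = TRUE)
  expect_error(grid_search_refine(bad, d, cnt, 16), "degenerate")
})

test_that("compiled and pure-R screening agree", {
  d <- local_search_optimize(generate_random_design(15, 6, seed = 3), 150, seed = 3)
  sim <- simulate_fusion_pools(c(3, 11), 15, d, coverage_lambda = 16,
                               epsilon = 0.01, seed = 4)
  a <- detect_fusion(sim$counts, d, 16, 0.01, k = 2, use_compiled = TRUE)
  b <- detect_fusion(sim$counts, d, 16, 0.01, k = 2, use_compiled = FALSE)
  expect_identical(a$carriers, b$carriers)
  expect_equal(a$refined_loglik, b$refined_loglik, tolerance = 1e-9)
  # and the screening residuals themselves match fit_expression_ls
  scr <- pooldecode:::screen_carrier_sets_cpp(d$matrix, sim$counts$y_fusion,
                                              16, 2L, 10L, TRUE)
  for (i in seq_along(scr$sets)) {
    ref <- fit_expression_ls(scr$sets[[i]], d, sim$counts, 16)
    expect_equal(scr$residual[i], ref$ls_residual, tolerance = 1e-7)
  }
})

test_that("detect_fusion finds planted carriers and honours the no-call contract", {
  d <- local_search_optimize(generate_random_design(20, 8, seed = 5), 300, seed = 5)
  sim <- simulate_fusion_pools(7, 20, d, coverage_lambda = 16, epsilon = 0.01,
                               seed = 6)
  call <- detect_fusion(sim$counts, d, 16, 0.01, k = 3)
  expect_identical(call$carriers, 7L)
  # all-zero counts: explicit no-call
  zero <- pool_counts(y_fusion = rep(0, 8))
  nc <- detect_fusion(zero, d, 16, 0, k = 3)
  expect_length(nc$carriers, 0)
  expect_length(detect_fusion(sim$counts, d, 16, 0.01, k = 0)$carriers, 0)
})

test_that("detect_fusion with all candidates equals exhaustive refined maximization", {
  d <- local_search_optimize(generate_random_design(12, 6, seed = 7), 150, seed = 7)
  for (s in 1:3) {
    sim <- simulate_fusion_pools(c(2, 9), 12, d, coverage_lambda = 20,
                                 epsilon = 0.01, seed = s + 10)
    call <- detect_fusion(sim$counts, d, 20, 0.01, k = 2, top = 10^4)
    # oracle: refine every candidate set independently and apply the same
    # AIC-penalized selection
    sets <- enumerate_carrier_sets(12, 2)
    best <- NULL; best_pen <- -Inf
    for (S in sets) {
      cand <- fit_expression_ls(S, d, sim$counts, 20)
      if (cand$degenerate) next
      ref <- grid_search_refine(cand, d, sim$counts, 20, epsilon = 0.01)
      pen <- ref$refined_loglik - length(S)
      if (pen > best_pen + 1e-12) { best_pen <- pen; best <- ref }
    }
    expect_identical(call$carriers, best$carriers)
  }
})

test_that("fusion detection is equivariant under sample relabeling", {
  d <- local_search_optimize(generate_random_design(15, 7, seed = 8), 150, seed = 8)
  sim <- simulate_fusion_pools(c(4, 12), 15, d, coverage_lambda = 24,
                               epsilon = 0.01, seed = 9)
  call <- detect_fusion(sim$counts, d, 24, 0.01, k = 2)
  set.seed(10)
  perm <- sample(15)  # perm maps new index -> old index
  d_p <- pool_design(d$matrix[, perm], d$pool_ids, d$sample_ids[perm])
  call_p <- detect_fusion(sim$counts, d_p, 24, 0.01, k = 2)
  expect_setequal(match(call$carriers, perm), call_p$carriers)
})

test_that("true-carrier residual shrinks as coverage grows (noiseless error)", {
  d <- local_search_optimize(generate_random_design(15, 6, seed = 11), 150, seed = 11)
  med <- vapply(c(16, 64, 256), function(lam) {
    r <- vapply(1:30, function(s) {
      sim <- simulate_fusion_pools(5, 15, d, coverage_lambda = lam,
                                   epsilon = 0, mixing = "per_pool", seed = s)
      # residual relative to the signal scale
      fit_expression_ls(5, d, sim$counts, lam)$ls_residual / lam
    }, numeric(1))
    median(r)
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})
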