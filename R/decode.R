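#' @title LP-based genotype decoding
#' @name decode_lp
#' @description
#' Recovers per-individual genotypes from pool-level minor-allele counts
#' by linear programming.  With expected per-copy coverage `lambda` the
#' pools should roughly satisfy `lambda * A_hat %*% G = Y`, and the
#' decoder solves
#'
#'   minimize  sum_t | lambda (A_hat x)_t - y_t |  +  w sum_i | x_i - I_i |
#'   subject to 0 <= x_i <= 2,
#'
#' where `I` is the imputation dosage vector and
#' `w = beta * lambda` (with the default `scale_beta = TRUE`, which makes
#' the count and dosage terms commensurate; `w = beta` otherwise).  The
#' l1 terms are linearized with slack variables and the LP is solved
#' exactly by the Frisch-Newton interior-point method of
#' \code{quantreg::rq.fit.fnc} (a box-constrained l1 regression is the
#' same LP).  The optimum is a lower bound on the objective attainable by
#' any integer genotype vector; the fractional solution is then converted
#' to genotypes by [round_and_refine()].
#'
#' @param counts A [pool_counts()] of kind `"genotype"`.
#' @param noisy_design A [noisy_design()] (calibrated concentrations) or
#'   a [pool_design()].
#' @param coverage_lambda Expected reads per chromosomal copy.
#' @param prior An [imputation_prior()] (its dosage anchors the LP and
#'   its probabilities enter the refinement scoring), or a bare numeric
#'   dosage vector in `[0, 2]`.
#' @param beta Non-negative trade-off between fitting the pool counts
#'   and staying close to the imputation dosage; default 1.
#' @param epsilon Substitution error rate used in the refinement
#'   likelihood (not in the LP itself).
#' @param scale_beta Multiply `beta` by `lambda` inside the objective
#'   (default `TRUE`).
#' @param refine Use likelihood-guided rounding ([round_and_refine()]);
#'   `FALSE` rounds each coordinate to the nearest integer.
#' @param both_classes Also fit the major-allele counts in the LP
#'   (default `FALSE`: major counts are complementary given total
#'   coverage).
#' @param multi_start Also refine the fractional solutions of two LP
#'   variants (major counts included; anchor weight quadrupled) and
#'   return the candidate with the best composite score (default
#'   `TRUE`).  Different anchor strengths land the rounding search in
#'   different basins; the composite likelihood arbitrates.  The
#'   reported `fractional_solution` and `lp_objective` always come from
#'   the primary LP.
#' @param weights Component weights passed to the refinement scoring.
#' @param restarts Basin-hopping rounds per refinement, see
#'   [round_and_refine()].
#' @return An object of class `decode_result`: list with `genotypes`,
#'   `fractional_solution` (length-N reals in `[0,2]`), `lp_objective`
#'   (the attained l1 bound, using the effective prior weight `w`), and
#'   `score` (the [composite_loglik()] of the returned genotypes).
#' @examples
#' d <- generate_random_design(8, 8, seed = 1)
#' g <- simulate_genotypes_hwe(0.3, 8, seed = 2)
#' cnt <- simulate_genotype_pools(g, d, noise_params(coverage_lambda = 150,
#'                                                   epsilon = 0.005, sigma_p = 0),
#'                                seed = 3)
#' pr <- simulate_imputation_priors(g, seed = 4)
#' res <- decode_lp(cnt, d, 150, pr, epsilon = 0.005)
#' rbind(truth = g, decoded = res$genotypes)
NULL

# exact l1 LP: min |X b - y|_1 over box lo <= b <= up, via quantreg's
# Frisch-Newton interior point.  The problem is scaled to unit magnitude
# first; rare numerically singular instances are retried with a small
# column jitter, which perturbs the optimum by O(jitter).
solve_l1_box <- function(X, y, lo, up) {
  N <- ncol(X)
  R <- rbind(diag(N), -diag(N))
  r <- c(lo, -up)
  s <- max(abs(X), 1)
  run <- function(Xs) quantreg::rq.fit.fnc(Xs / s, y / s, R = R, r = r, tau = 0.5)
  fit <- tryCatch(run(X), error = function(e) e)
  if (inherits(fit, "error")) {
    for (jit in c(1e-6, 1e-4)) {
      Xj <- with_seed(271828,
        X * (1 + matrix(rnorm(length(X), 0, jit), nrow(X))))
      fit <- tryCatch(run(Xj), error = function(e) e)
      if (!inherits(fit, "error")) break
    }
  }
  if (inherits(fit, "error"))
    stopf("l1 LP solver failed: %s", conditionMessage(fit))
  pmin(up, pmax(lo, as.vector(fit$coefficients)))
}

#' @rdname decode_lp
#' @export
decode_lp <- function(counts, noisy_design, coverage_lambda, prior,
                      beta = 1, epsilon = 0.005, scale_beta = TRUE,
                      refine = TRUE, both_classes = FALSE,
                      multi_start = TRUE, weights = c(1, 1, 1),
                      restarts = 4) {
  nd <- as_noisy_design(noisy_design)
  A <- nd$matrix
  Tn <- nrow(A); N <- ncol(A)
  if (!inherits(counts, "pool_counts") || counts$kind != "genotype")
    stopf("`counts` must be genotype pool_counts")
  if (n_pools_of(counts) != Tn) stopf("counts and design disagree on the number of pools")
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) stopf("`beta` must be non-negative")
  if (!is.numeric(coverage_lambda) || coverage_lambda <= 0)
    stopf("`coverage_lambda` must be positive")

  if (inherits(prior, "imputation_prior")) {
    dosage <- prior$dosage
    prior_probs <- prior
  } else {
    dosage <- as.numeric(prior)
    prior_probs <- NULL
  }
  if (length(dosage) != N) stopf("prior dosage must have one entry per sample")
  if (any(dosage < 0 | dosage > 2)) stopf("dosage entries must lie in [0, 2]")

  lam <- coverage_lambda
  w <- if (scale_beta) beta * lam else beta
  # degenerate beta = 0: keep a vanishing anchor so the LP stays full rank;
  # the reported objective still uses w = 0
  w_solve <- if (w > 0) w else 1e-8 * lam

  solve_variant <- function(w_v, both_v) {
    Xc <- lam * A
    yc <- counts$y_minor
    if (both_v) {
      # |lam A (2 - x) - y_major| = |lam A x - (2 lam A 1 - y_major)|
      Xc <- rbind(Xc, lam * A)
      yc <- c(yc, 2 * lam * rowSums(A) - counts$y_major)
    }
    wv_solve <- if (w_v > 0) w_v else 1e-8 * lam
    X <- rbind(Xc, wv_solve * diag(N))
    yy <- c(yc, wv_solve * dosage)
    x <- solve_l1_box(X, yy, rep(0, N), rep(2, N))
    list(x = x,
         obj = sum(abs(as.vector(Xc %*% x) - yc)) + w_v * sum(abs(x - dosage)))
  }

  primary <- solve_variant(w, both_classes)
  x <- primary$x
  lp_obj <- primary$obj

  p_hat <- estimate_allele_freq(counts)
  genotypes <- if (refine) {
    starts <- list(x)
    if (multi_start) {
      if (!both_classes) starts <- c(starts, list(solve_variant(w, TRUE)$x))
      starts <- c(starts, list(solve_variant(4 * w, TRUE)$x))
    }
    cands <- lapply(starts, function(xs)
      round_and_refine(xs, counts, nd, lam, epsilon, prior = prior_probs,
                       p_hat = p_hat, weights = weights, restarts = restarts))
    if (length(cands) == 1L) cands[[1]]
    else {
      scores <- vapply(cands, function(gc)
        composite_loglik(gc, nd, lam, counts, epsilon, prior = prior_probs,
                         weights = weights, p_hat = p_hat)$total, numeric(1))
      cands[[which.max(scores)]]
    }
  } else {
    as.integer(pmin(2, pmax(0, floor(x + 0.5))))
  }
  score <- composite_loglik(genotypes, nd, lam, counts, epsilon,
                            prior = prior_probs, weights = weights, p_hat = p_hat)
  structure(list(genotypes = genotypes, fractional_solution = x,
                 lp_objective = lp_obj, score = score,
                 beta = beta, effective_prior_weight = w),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result: %d samples, lp_objective %.4f\n",
              length(x$genotypes), x$lp_objective))
  cat("  genotype counts:", paste(sprintf("%d:%d", 0:2, tabulate(x$genotypes + 1L, 3L)),
                                  collapse = " "), "\n")
  invisible(x)
}

#' Decode a rare variant without an imputation anchor
#'
#' [decode_lp()] with the imputation dosage replaced by the zero vector:
#' most individuals are expected not to carry a rare variant, so the
#' anchor pulls the solution toward sparsity.  Refinement scoring uses no
#' imputation term (a uniform prior contributes only a constant).
#'
#' @inheritParams decode_lp
#' @return A `decode_result` (see [decode_lp()]).
#' @export
decode_rare <- function(counts, noisy_design, coverage_lambda, beta = 1,
                        epsilon = 0.005, scale_beta = TRUE, refine = TRUE,
                        both_classes = FALSE) {
  nd <- as_noisy_design(noisy_design)
  decode_lp(counts, nd, coverage_lambda, prior = rep(0, ncol(nd$matrix)),
            beta = beta, epsilon = epsilon, scale_beta = scale_beta,
            refine = refine, both_classes = both_classes)
}

#' Round a fractional LP solution to integer genotypes
#'
#' Coordinates whose fractional part is below `lower` or above `upper`
#' are rounded to the nearest integer.  The remaining ambiguous
#' coordinates are resolved by likelihood: if there are at most
#' `max_enum` of them, all floor/ceiling combinations are enumerated and
#' scored by the composite likelihood and the argmax is returned (ties
#' broken toward the lexicographically smallest vector); otherwise a
#' greedy coordinate-wise maximization is run from the nearest-integer
#' start until no single-coordinate change improves the score.
#'
#' @param fractional Numeric vector in `[0, 2]`.
#' @param counts,noisy_design,coverage_lambda,epsilon,prior,weights As in
#'   [decode_lp()] (`prior` may be `NULL`).
#' @param p_hat Allele frequency for the Hardy-Weinberg term (estimated
#'   from the counts when `NULL`).
#' @param lower,upper Fractional-part thresholds delimiting the
#'   ambiguous band (defaults 0.2 and 0.8).
#' @param max_enum Maximal number of ambiguous coordinates enumerated
#'   exhaustively (default 20).
#' @param polish Run a final steepest-ascent pass over *all* coordinates
#'   (each step applies the single genotype change — or joint change of a
#'   suspect pair — that most improves the composite score, until none
#'   does); catches errors outside the ambiguous band (default `TRUE`).
#' @param restarts Number of basin-hopping rounds: the polished solution
#'   is perturbed at a few random suspect coordinates and re-polished,
#'   keeping the best scoring result (default 8; 0 disables).  The
#'   perturbations use an internal fixed random stream, so the result is
#'   deterministic given the inputs.  Compensating error patterns along
#'   near-null integer directions of the design form deep local optima
#'   that single- and pair-moves cannot escape; shaking is what gets the
#'   search across.
#' @return Integer genotype vector.
#' @export
round_and_refine <- function(fractional, counts, noisy_design, coverage_lambda,
                             epsilon = 0.005, prior = NULL, p_hat = NULL,
                             lower = 0.2, upper = 0.8, max_enum = 20,
                             weights = c(1, 1, 1), polish = TRUE,
                             restarts = 8) {
  nd <- as_noisy_design(noisy_design)
  A <- nd$matrix
  x <- pmin(2, pmax(0, as.numeric(fractional)))
  if (length(x) != ncol(A)) stopf("`fractional` must have one entry per sample")
  if (!(lower <= upper) || lower < 0 || upper > 1) stopf("need 0 <= lower <= upper <= 1")
  frac <- x - floor(x)
  base <- as.integer(pmin(2, floor(x + 0.5)))
  amb <- which(frac > 0 & frac >= lower & frac <= upper)
  if (is.null(p_hat)) p_hat <- estimate_allele_freq(counts)
  lam <- coverage_lambda

  # relative scores (exact up to a site-constant) are all the search needs
  score_mat <- function(Gmat) {
    composite_scores_fast(Gmat, A, lam, counts, epsilon, prior = prior,
                          p_hat = p_hat, weights = weights)
  }

  # steepest-ascent polish: repeatedly apply the best single-coordinate
  # genotype change, or the best joint change of a *pair* of suspect
  # coordinates, while it improves the composite score.  Pair moves are
  # essential: two individuals with similar pool-membership columns can
  # carry compensating errors that no single change improves (the pool
  # sums are nearly preserved), a valley one-coordinate search cannot
  # cross.  Suspects are the coordinates whose LP solution was not
  # essentially integral (capped at 30, nearest to half-integer first).
  suspects <- {
    fr <- pmin(frac, 1 - frac)
    cand <- which(fr > 0.02)
    cand[order(-fr[cand])][seq_len(min(30L, length(cand)))]
  }
  polish_fn <- function(g) {
    if (!polish) return(g)
    N <- length(g)
    susp <- sort(unique(suspects))
    for (step in seq_len(5L * N)) {
      cur <- score_mat(matrix(g))[1]
      # all single-coordinate changes
      si <- rep(seq_len(N), each = 2L)
      sv <- as.integer(unlist(lapply(g, function(v) setdiff(0:2, v))))
      # pair changes among the suspect coordinates
      if (length(susp) >= 2L) {
        pr_ <- utils::combn(susp, 2L)
        pi_ <- pr_[1, ]; pj <- pr_[2, ]
        # 4 value combinations per pair
        pi4 <- rep(pi_, each = 4L); pj4 <- rep(pj, each = 4L)
        ai <- as.integer(t(vapply(pi_, function(i) rep(setdiff(0:2, g[i]), each = 2L),
                                  integer(4))))
        bj <- as.integer(t(vapply(pj, function(j) rep(setdiff(0:2, g[j]), times = 2L),
                                  integer(4))))
      } else {
        pi4 <- pj4 <- ai <- bj <- integer(0)
      }
      K <- length(si) + length(pi4)
      Gmat <- matrix(g, N, K)
      cols_s <- seq_along(si)
      Gmat[cbind(si, cols_s)] <- sv
      if (length(pi4)) {
        cols_p <- length(si) + seq_along(pi4)
        Gmat[cbind(pi4, cols_p)] <- ai
        Gmat[cbind(pj4, cols_p)] <- bj
      }
      s <- score_mat(Gmat)
      j <- which.max(s)
      if (s[j] <= cur + 1e-9) break
      changed <- which(Gmat[, j] != g)
      g <- as.integer(Gmat[, j])
      susp <- sort(unique(c(susp, changed)))
    }
    g
  }

  if (length(amb) == 0L) return(polish_fn(base))

  # more ambiguous coordinates than the enumeration cap: enumerate the
  # max_enum closest to half-integer; the remainder is handled by greedy
  # coordinate-wise maximization (and by the polish pass)
  leftover <- integer(0)
  if (length(amb) > max_enum) {
    closeness <- abs(frac[amb] - 0.5)
    ord <- order(closeness)
    leftover <- amb[ord][-seq_len(max_enum)]
    amb <- amb[ord][seq_len(max_enum)]
  }

  m <- length(amb)
  lo <- as.integer(floor(x[amb]))
  g0 <- base
  g0[amb] <- lo
  # incremental enumeration: setting bit b raises coordinate amb[b] from
  # its floor by one, so the Poisson means, genotype counts and prior
  # terms are all affine in the bit vector; only the y*log(mu) terms need
  # recomputation per pattern
  eps_adj <- epsilon
  rsA <- rowSums(A)
  mu1_0 <- lam * (1 - 2 * eps_adj) * as.vector(A %*% g0) + 2 * eps_adj * lam * rsA
  Dmu <- lam * (1 - 2 * eps_adj) * A[, amb, drop = FALSE]
  Ctot <- 2 * lam * rsA
  y1 <- round(counts$y_minor); y0 <- round(counts$y_major)
  i1 <- which(y1 > 0); i0 <- which(y0 > 0)
  pr <- c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  use_fast <- all(pr > 0)
  lpr <- log(pmax(pr, 1e-300))
  # per-bit additive contributions: HWE category change and prior mass
  dlin <- vapply(seq_len(m), function(b) {
    i <- amb[b]
    d <- weights[1] * (lpr[lo[b] + 2L] - lpr[lo[b] + 1L])
    if (!is.null(prior))
      d <- d + weights[3] * (log(prior$probs[i, lo[b] + 2L]) -
                             log(prior$probs[i, lo[b] + 1L]))
    d
  }, numeric(1))
  base_lin <- 0  # common to all patterns; argmax unaffected
  use_fast <- use_fast && all(is.finite(dlin))  # zero prior mass: slow path

  best_g <- NULL; best_s <- -Inf
  total <- 2^m
  chunk <- 8192L
  done <- 0
  while (done < total) {
    k <- min(chunk, total - done)
    # bit patterns done .. done+k-1, earliest ambiguous coordinate most
    # significant so enumeration order is lexicographic in the vector
    idx <- done + seq_len(k) - 1
    bits <- matrix(0L, m, k)
    for (b in seq_len(m)) bits[b, ] <- as.integer((idx %/% 2^(m - b)) %% 2)
    if (use_fast && length(amb) > 0) {
      MU1 <- mu1_0 + Dmu %*% bits
      MU0 <- Ctot - MU1
      s <- as.vector(crossprod(bits, dlin)) + base_lin
      if (length(i1)) s <- s + weights[2] * colSums(y1[i1] * log(MU1[i1, , drop = FALSE]))
      if (length(i0)) s <- s + weights[2] * colSums(y0[i0] * log(MU0[i0, , drop = FALSE]))
    } else {
      Gmat <- matrix(rep.int(base, k), length(base), k)
      Gmat[amb, ] <- lo + bits
      s <- score_mat(Gmat)
    }
    j <- which.max(s)
    if (s[j] > best_s) {
      best_s <- s[j]
      best_g <- base
      best_g[amb] <- lo + bits[, j]
    }
    done <- done + k
  }
  g <- as.integer(best_g)
  if (length(leftover)) {
    cur <- score_mat(matrix(g))[1]
    for (pass in 1:10) {
      changed <- FALSE
      for (i in leftover) {
        alt <- g
        alt[i] <- if (g[i] == floor(x[i])) as.integer(ceiling(x[i])) else as.integer(floor(x[i]))
        s <- score_mat(matrix(alt))[1]
        if (s > cur) { g <- alt; cur <- s; changed <- TRUE }
      }
      if (!changed) break
    }
  }
  g <- polish_fn(g)
  if (!polish || restarts <= 0) return(g)

  # basin hopping: perturb a few suspect coordinates, re-polish, keep the
  # best; also try the imputation modal vector as an alternative start
  starts <- list()
  if (!is.null(prior)) starts$mode <- as.integer(max.col(prior$probs) - 1L)
  best_g <- g
  best_s <- score_mat(matrix(best_g))[1]
  for (st in starts) {
    cand <- polish_fn(st)
    s <- score_mat(matrix(cand))[1]
    if (s > best_s) { best_s <- s; best_g <- cand }
  }
  pool <- unique(c(suspects, amb, leftover))
  if (length(pool) >= 2L) {
    with_seed(20111217, {
      for (r in seq_len(restarts)) {
        gp <- best_g
        flip <- pool[sample.int(length(pool), min(4L, length(pool)))]
        for (i in flip) gp[i] <- sample(setdiff(0:2, gp[i]), 1L)
        cand <- polish_fn(as.integer(gp))
        s <- score_mat(matrix(cand))[1]
        if (s > best_s) { best_s <- s; best_g <- cand }
      }
    })
  }
  best_g
}

#' Estimate pool concentrations from calibration SNPs
#'
#' The realized concentrations `A_hat[t, j]` can be recovered by
#' genotyping a panel of S calibration SNPs in all individuals: each SNP
#' contributes, per pool, one linear equation
#' `lambda_s * sum_j g[s, j] * A_hat[t, j] = y_minor[s, t]`.  For each
#' pool independently, the non-negative least-squares problem restricted
#' to the pool's member samples is solved; non-member entries are fixed
#' at zero.
#'
#' @param design The intended [pool_design()].
#' @param known_genotypes S x N matrix of known genotypes in `{0,1,2}`.
#' @param calibration_counts S x T matrix of per-site, per-pool
#'   minor-allele counts, or a list of S [pool_counts()] objects.
#' @param coverage_lambdas Per-site expected per-copy coverage (length S,
#'   or a single value recycled).
#' @return A [noisy_design()] holding the estimated concentrations.
#' @examples
#' d <- generate_random_design(6, 4, seed = 1)
#' G <- matrix(rbinom(12 * 6, 2, 0.4), 12, 6)
#' Y <- 100 * G %*% t(d$matrix)   # noiseless counts at lambda = 100
#' ahat <- estimate_concentrations(d, G, Y, 100)
#' max(abs(ahat$matrix - d$matrix))  # ~0
#' @export
estimate_concentrations <- function(design, known_genotypes, calibration_counts,
                                    coverage_lambdas) {
  if (!inherits(design, "pool_design")) stopf("`design` must be a pool_design")
  A <- design$matrix
  Tn <- nrow(A); N <- ncol(A)
  G <- as.matrix(known_genotypes)
  if (ncol(G) != N) stopf("known genotypes must have one column per sample")
  S <- nrow(G)
  if (is.list(calibration_counts) && !is.matrix(calibration_counts)) {
    Y <- t(vapply(calibration_counts, function(cc) {
      if (!inherits(cc, "pool_counts")) stopf("calibration counts list must hold pool_counts")
      cc$y_minor
    }, numeric(Tn)))
  } else {
    Y <- as.matrix(calibration_counts)
  }
  if (!identical(dim(Y), c(S, Tn)))
    stopf("calibration counts must be %d sites x %d pools", S, Tn)
  lam <- rep_len(as.numeric(coverage_lambdas), S)
  if (any(lam <= 0)) stopf("coverage must be positive")
  if (S < N) warnf("only %d calibration sites for %d samples; estimates may be poor", S, N)

  Ahat <- matrix(0, Tn, N)
  for (t in seq_len(Tn)) {
    sup <- which(A[t, ] == 1)
    X <- G[, sup, drop = FALSE] * lam
    rk <- qr(X)$rank
    if (rk < length(sup))
      stopf("pool %s: calibration genotypes are rank deficient by %d on its %d member samples",
            design$pool_ids[t], length(sup) - rk, length(sup))
    Ahat[t, sup] <- pracma::lsqnonneg(X, Y[, t])$x
  }
  noisy_design(Ahat, design)
}

#' Exhaustive maximum-composite-likelihood decoding (testing oracle)
#'
#' Enumerates all `3^N` genotype vectors and returns the one maximizing
#' the composite likelihood, ties broken lexicographically.  Intended as
#' an independent oracle for small instances; refuses `N > 12`.
#'
#' @inheritParams decode_lp
#' @param prior An [imputation_prior()] or `NULL`.
#' @param weights Component weights for the composite likelihood.
#' @return Integer genotype vector of length N.
#' @export
brute_force_decode <- function(counts, noisy_design, coverage_lambda,
                               epsilon = 0, prior = NULL, weights = c(1, 1, 1)) {
  nd <- as_noisy_design(noisy_design)
  A <- nd$matrix
  N <- ncol(A)
  if (N > 12) stopf("brute force enumeration is limited to N <= 12 (3^N vectors)")
  p_hat <- estimate_allele_freq(counts)
  combos <- as.matrix(expand.grid(rep(list(0:2), N)))[, N:1, drop = FALSE]
  Gmat <- t(combos)  # N x 3^N, columns in lexicographic order of the vector
  storage.mode(Gmat) <- "integer"
  best <- -Inf; best_j <- 1L
  K <- ncol(Gmat); chunk <- 8192L; done <- 0L
  while (done < K) {
    k <- min(chunk, K - done)
    cols <- done + seq_len(k)
    s <- composite_scores_matrix(Gmat[, cols, drop = FALSE], A, coverage_lambda,
                                 counts, epsilon, prior = prior, p_hat = p_hat,
                                 weights = weights)
    j <- which.max(s)
    if (s[j] > best) { best <- s[j]; best_j <- cols[j] }
    done <- done + k
  }
  as.integer(Gmat[, best_j])
}
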