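#' Estimate the allele frequency from pool counts
#'
#' The overall minor allele frequency of the site is estimated as the
#' unweighted mean, across pools with at least one read, of the per-pool
#' minor-read fraction `y_minor / (y_minor + y_major)`.  Setting
#' `weighted = TRUE` instead returns the read-count-weighted mean
#' (total minor reads over total reads).
#'
#' @param counts A [pool_counts()] of kind `"genotype"`.
#' @param weighted Use the read-weighted mean (default `FALSE`).
#' @return Estimated allele frequency in `[0, 1]`.
#' @examples
#' cnt <- pool_counts(y_major = c(80, 60), y_minor = c(20, 40))
#' estimate_allele_freq(cnt)  # (0.2 + 0.4) / 2
#' @export
estimate_allele_freq <- function(counts, weighted = FALSE) {
  if (!inherits(counts, "pool_counts") || counts$kind != "genotype")
    stopf("`counts` must be genotype pool_counts")
  tot <- counts$y_major + counts$y_minor
  if (all(tot == 0)) stopf("all pools have zero reads; allele frequency is undefined")
  if (weighted) sum(counts$y_minor) / sum(tot)
  else mean((counts$y_minor / tot)[tot > 0])
}

#' Hardy-Weinberg log-likelihood of a genotype vector
#'
#' Log-probability of the observed genotypes under Hardy-Weinberg
#' equilibrium at allele frequency `p_hat`:
#' `n0 log((1-p)^2) + n1 log(2p(1-p)) + n2 log(p^2)` where `n_k` counts
#' individuals with genotype `k`.  Genotypes whose Hardy-Weinberg
#' probability is zero (e.g. a heterozygote at `p_hat = 0`) yield a
#' `-Inf` sentinel rather than an error.
#'
#' @param genotypes Integer vector in `{0,1,2}`.
#' @param p_hat Allele frequency in `[0, 1]`.
#' @return Log-likelihood (possibly `-Inf`).
#' @examples
#' hwe_loglik(rep(1, 10), 0.5)  # 10 * log(0.5)
#' @export
hwe_loglik <- function(genotypes, p_hat) {
  g <- check_genotypes(genotypes)
  if (!is.numeric(p_hat) || length(p_hat) != 1L || p_hat < 0 || p_hat > 1)
    stopf("`p_hat` must lie in [0, 1]")
  n <- tabulate(g + 1L, 3L)
  pr <- c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  sum(ifelse(n > 0, n * log(pr), 0))
}

# Poisson means for minor/major counts given genotypes; epsilon-adjusted
# means mix the two allele classes by the substitution error rate
pool_count_means <- function(g, A, lambda, epsilon, error_adjust = TRUE) {
  if (!error_adjust) epsilon <- 0
  e1 <- lambda * ((1 - epsilon) * g + epsilon * (2 - g))
  e0 <- lambda * ((1 - epsilon) * (2 - g) + epsilon * g)
  list(mu_minor = as.vector(A %*% e1), mu_major = as.vector(A %*% e0))
}

# Poisson log-pmf for possibly non-integer counts: either round the count
# (default) or use the gamma-function continuous extension
poisson_term <- function(y, mu, continuous = FALSE) {
  if (continuous) {
    out <- ifelse(mu > 0, y * log(mu) - mu - lgamma(y + 1),
                  ifelse(y > 0, -Inf, 0))
    sum(out)
  } else {
    sum(dpois(round(y), mu, log = TRUE))
  }
}

#' Poisson read-count log-likelihood of a genotype vector
#'
#' Likelihood of the observed pool counts given genotypes `G`: the
#' minor-allele count of pool `t` is Poisson with mean
#' `sum_j A_hat[t,j] * lambda * ((1-eps) g_j + eps (2-g_j))` and the
#' major-allele count symmetrically (both allele classes are scored).
#' The `eps` terms account for reads misassigned by sequencing error;
#' `error_adjust = FALSE` drops them and uses the raw means
#' `lambda * A_hat %*% g`.  Mixed counts are generally non-integer;
#' by default they are rounded before evaluating the Poisson pmf, or a
#' gamma-function continuous extension is used with
#' `continuous = TRUE`.  A zero mean facing a positive count yields
#' `-Inf`.
#'
#' @param genotypes Integer vector in `{0,1,2}`.
#' @param noisy_design A [noisy_design()] or [pool_design()].
#' @param coverage_lambda Expected reads per chromosomal copy.
#' @param counts A [pool_counts()] of kind `"genotype"`.
#' @param epsilon Substitution error rate.
#' @param error_adjust Include the error mixing in the means (default
#'   `TRUE`).
#' @param continuous Evaluate the Poisson log-pmf continuously instead of
#'   rounding counts (default `FALSE`).
#' @return Log-likelihood (possibly `-Inf`).
#' @export
noise_loglik <- function(genotypes, noisy_design, coverage_lambda, counts,
                         epsilon = 0, error_adjust = TRUE, continuous = FALSE) {
  nd <- as_noisy_design(noisy_design)
  A <- nd$matrix
  g <- check_genotypes(genotypes, ncol(A))
  if (!inherits(counts, "pool_counts") || counts$kind != "genotype")
    stopf("`counts` must be genotype pool_counts")
  if (n_pools_of(counts) != nrow(A)) stopf("counts and design disagree on the number of pools")
  if (!is.numeric(coverage_lambda) || coverage_lambda <= 0) stopf("`coverage_lambda` must be positive")
  mu <- pool_count_means(g, A, coverage_lambda, epsilon, error_adjust)
  poisson_term(counts$y_minor, mu$mu_minor, continuous) +
    poisson_term(counts$y_major, mu$mu_major, continuous)
}

#' Imputation log-likelihood of a genotype vector
#'
#' `sum_i log h_i(g_i)` where `h_i` is individual `i`'s imputation
#' genotype distribution; `-Inf` when any assigned genotype has zero
#' prior mass.
#'
#' @param genotypes Integer vector in `{0,1,2}`.
#' @param prior An [imputation_prior()].
#' @return Log-likelihood (possibly `-Inf`).
#' @examples
#' pr <- imputation_prior(matrix(1/3, 4, 3))
#' imputation_loglik(c(0, 1, 2, 1), pr)  # -4 log 3
#' @export
imputation_loglik <- function(genotypes, prior) {
  g <- check_genotypes(genotypes)
  if (!inherits(prior, "imputation_prior")) stopf("`prior` must be an imputation_prior")
  if (nrow(prior$probs) != length(g)) stopf("prior rows and genotypes differ in length")
  sum(log(prior$probs[cbind(seq_along(g), g + 1L)]))
}

#' Composite log-likelihood of a genotype assignment
#'
#' Product (sum in log space) of three independently specified
#' components: the Hardy-Weinberg prior at the pool-estimated allele
#' frequency, the Poisson read-count likelihood, and (when a prior is
#' supplied) the imputation likelihood.  Component weights default to 1.
#'
#' @inheritParams noise_loglik
#' @param prior An [imputation_prior()], or `NULL` to omit the
#'   imputation term.
#' @param weights Length-3 numeric weights for the (HWE, noise,
#'   imputation) components.
#' @param p_hat Allele frequency for the Hardy-Weinberg term; estimated
#'   from `counts` via [estimate_allele_freq()] when `NULL`.
#' @return An object of class `composite_score`: a list with
#'   `hwe_loglik`, `noise_loglik`, `imputation_loglik` (`NA` when no
#'   prior), and `total` (the weighted sum).
#' @export
composite_loglik <- function(genotypes, noisy_design, coverage_lambda, counts,
                             epsilon = 0, prior = NULL,
                             weights = c(1, 1, 1), p_hat = NULL,
                             error_adjust = TRUE, continuous = FALSE) {
  if (length(weights) != 3L || !is.numeric(weights)) stopf("`weights` must be 3 numbers")
  if (is.null(p_hat)) p_hat <- estimate_allele_freq(counts)
  hwe <- hwe_loglik(genotypes, p_hat)
  noi <- noise_loglik(genotypes, noisy_design, coverage_lambda, counts,
                      epsilon, error_adjust, continuous)
  imp <- if (is.null(prior)) NA_real_ else imputation_loglik(genotypes, prior)
  total <- weights[1] * hwe + weights[2] * noi +
    (if (is.null(prior)) 0 else weights[3] * imp)
  structure(list(hwe_loglik = hwe, noise_loglik = noi,
                 imputation_loglik = imp, total = total),
            class = "composite_score")
}

#' @export
print.composite_score <- function(x, ...) {
  cat(sprintf("composite score: total %.4f (HWE %.4f, noise %.4f, imputation %s)\n",
              x$total, x$hwe_loglik, x$noise_loglik,
              if (is.na(x$imputation_loglik)) "-" else sprintf("%.4f", x$imputation_loglik)))
  invisible(x)
}

# Vectorized composite scorer over candidate genotype vectors (N x K),
# exact up to a site-constant: the Poisson normalization lgamma(y+1) and
# the -mu terms (mu_minor + mu_major is the same for every genotype
# vector) are dropped, leaving y * log(mu) summed over pools with y > 0.
# Used by the refinement search, where only relative scores matter.
composite_scores_fast <- function(Gmat, A, lambda, counts, epsilon,
                                  prior = NULL, p_hat = NULL,
                                  weights = c(1, 1, 1),
                                  error_adjust = TRUE) {
  N <- nrow(Gmat); K <- ncol(Gmat)
  if (is.null(p_hat)) p_hat <- estimate_allele_freq(counts)
  eps <- if (error_adjust) epsilon else 0
  pr <- c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  if (any(pr == 0))  # -Inf bookkeeping needs the exact scorer
    return(composite_scores_matrix(Gmat, A, lambda, counts, epsilon,
                                   prior, p_hat, weights, error_adjust))
  lpr <- log(pr)
  n1 <- colSums(Gmat == 1L); n2 <- colSums(Gmat == 2L); n0 <- N - n1 - n2
  hwe <- n0 * lpr[1] + n1 * lpr[2] + n2 * lpr[3]

  rsA <- rowSums(A)
  mu_raw <- A %*% Gmat                       # T x K
  mu1 <- lambda * (1 - 2 * eps) * mu_raw + 2 * eps * lambda * rsA
  mu0 <- 2 * lambda * rsA - mu1
  y1 <- round(counts$y_minor); y0 <- round(counts$y_major)
  i1 <- which(y1 > 0); i0 <- which(y0 > 0)
  noi <- numeric(K)
  if (length(i1))
    noi <- noi + colSums(y1[i1] * log(mu1[i1, , drop = FALSE]))
  if (length(i0))
    noi <- noi + colSums(y0[i0] * log(mu0[i0, , drop = FALSE]))

  tot <- weights[1] * hwe + weights[2] * noi
  if (!is.null(prior)) {
    logH <- log(prior$probs)
    imp <- colSums(matrix(logH[cbind(rep.int(seq_len(N), K),
                                     as.vector(Gmat) + 1L)], N, K))
    tot <- tot + weights[3] * imp
  }
  tot
}

# Vectorized composite scorer over a matrix of candidate genotype vectors
# (N x K).  Shared by the brute-force decoder and the rounding refinement.
composite_scores_matrix <- function(Gmat, A, lambda, counts, epsilon,
                                    prior = NULL, p_hat = NULL,
                                    weights = c(1, 1, 1),
                                    error_adjust = TRUE) {
  N <- nrow(Gmat); K <- ncol(Gmat)
  Tn <- nrow(A)
  if (is.null(p_hat)) p_hat <- estimate_allele_freq(counts)
  eps <- if (error_adjust) epsilon else 0

  pr <- c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  lpr <- log(pr)
  n1 <- colSums(Gmat == 1L); n2 <- colSums(Gmat == 2L); n0 <- N - n1 - n2
  term <- function(n, lp) ifelse(n > 0, n * lp, 0)
  hwe <- term(n0, lpr[1]) + term(n1, lpr[2]) + term(n2, lpr[3])

  E1 <- lambda * ((1 - eps) * Gmat + eps * (2 - Gmat))
  mu1 <- A %*% E1
  # mu0 = lambda * A ((1-eps)(2-g) + eps g) = 2 lambda (A 1) - mu1
  mu0 <- matrix(2 * lambda * rowSums(A), Tn, K) - mu1
  y1 <- round(counts$y_minor); y0 <- round(counts$y_major)
  ll1 <- colSums(matrix(dpois(y1, mu1, log = TRUE), Tn, K))
  ll0 <- colSums(matrix(dpois(y0, mu0, log = TRUE), Tn, K))
  noi <- ll1 + ll0

  tot <- weights[1] * hwe + weights[2] * noi
  if (!is.null(prior)) {
    logH <- log(prior$probs)
    imp <- colSums(matrix(logH[cbind(rep.int(seq_len(N), K), as.vector(Gmat) + 1L)], N, K))
    tot <- tot + weights[3] * imp
  }
  tot
}
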