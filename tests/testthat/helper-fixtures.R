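# Shared fixtures: everything is generated in code at test time.

# small, well-conditioned design: 8 pools x 8 samples, distinct columns;
# the seed is chosen so the matrix has full column rank
small_design <- function(seed = 40) {
  d <- local_search_optimize(generate_random_design(8, 8, seed = seed),
                             n_iters = 100, seed = seed)
  stopifnot(qr(d$matrix)$rank == 8)
  d
}

# a noiseless genotype-count object: counts exactly at their expectations
exact_counts <- function(g, design, lambda) {
  A <- if (inherits(design, "noisy_design")) design$matrix else design$matrix
  pool_counts(y_major = as.vector(A %*% (lambda * (2 - g))),
              y_minor = as.vector(A %*% (lambda * g)))
}

# independent scalar composite evaluation (no shared code with the
# vectorized scorer): plain sums of dpois/log terms
naive_composite <- function(g, A, lambda, counts, epsilon, prior = NULL,
                            p_hat = NULL) {
  if (is.null(p_hat)) {
    tot <- counts$y_major + counts$y_minor
    p_hat <- mean((counts$y_minor / tot)[tot > 0])
  }
  pr <- c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  hwe <- 0
  for (gi in g) hwe <- hwe + log(pr[gi + 1])
  mu1 <- as.vector(A %*% (lambda * ((1 - epsilon) * g + epsilon * (2 - g))))
  mu0 <- as.vector(A %*% (lambda * ((1 - epsilon) * (2 - g) + epsilon * g)))
  noi <- sum(dpois(round(counts$y_minor), mu1, log = TRUE)) +
    sum(dpois(round(counts$y_major), mu0, log = TRUE))
  imp <- if (is.null(prior)) 0 else {
    s <- 0
    for (i in seq_along(g)) s <- s + log(prior$probs[i, g[i] + 1])
    s
  }
  hwe + noi + imp
}

# all genotype vectors of length n, lexicographic order, as an n x 3^n matrix
all_genotype_vectors <- function(n) {
  combos <- as.matrix(expand.grid(rep(list(0:2), n)))[, n:1, drop = FALSE]
  t(combos)
}
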