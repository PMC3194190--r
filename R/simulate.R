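#' Noise model parameters for pooled sequencing
#'
#' Bundles the three noise sources of the read-count model: concentration
#' jitter on the pooling matrix, per-base substitution error, and
#' per-individual coverage drawn from a Gamma distribution.
#'
#' @param sigma_p Standard deviation of the Normal concentration noise
#'   added to each non-zero design entry (dimensionless; entries are
#'   order 1).  Default 0.05, i.e. 5% jitter.
#' @param epsilon Probability that a sequenced base is substituted, so a
#'   read is assigned to the wrong allele class.  Must lie in `[0, 0.5)`.
#' @param coverage_lambda Expected number of reads per chromosomal copy
#'   per individual (a diploid individual contributes `2*lambda` reads on
#'   average).
#' @param gamma_shape Shape of the Gamma distribution of per-individual
#'   coverage `m_i` (scale is `coverage_lambda / gamma_shape`, so the
#'   mean is `coverage_lambda`).  The default 6.3 matches empirical
#'   coverage dispersion of Illumina sequencers.
#' @return An object of class `noise_params`.
#' @examples
#' noise_params(coverage_lambda = 150, epsilon = 0.005)
#' @export
noise_params <- function(sigma_p = 0.05, epsilon = 0.01,
                         coverage_lambda = 150, gamma_shape = 6.3) {
  if (!is.numeric(sigma_p) || length(sigma_p) != 1L || sigma_p < 0)
    stopf("`sigma_p` must be a single non-negative number")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 || epsilon >= 0.5)
    stopf("`epsilon` must lie in [0, 0.5)")
  if (!is.numeric(coverage_lambda) || length(coverage_lambda) != 1L || coverage_lambda <= 0)
    stopf("`coverage_lambda` must be positive")
  if (!is.numeric(gamma_shape) || length(gamma_shape) != 1L || gamma_shape <= 0)
    stopf("`gamma_shape` must be positive")
  structure(list(sigma_p = sigma_p, epsilon = epsilon,
                 coverage_lambda = coverage_lambda, gamma_shape = gamma_shape),
            class = "noise_params")
}

#' Noisy pooling matrix
#'
#' Wraps the realized concentration matrix `A_hat`: the design `A` with
#' per-entry concentration noise.  Entries are zero exactly where the
#' parent design is zero, and non-negative everywhere.
#'
#' @param matrix Non-negative T x N matrix.
#' @param source The parent [pool_design()].
#' @return An object of class `noisy_design`.
#' @export
noisy_design <- function(matrix, source) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (!inherits(source, "pool_design")) stopf("`source` must be a pool_design")
  if (!identical(dim(m), dim(source$matrix))) stopf("dimensions differ from the source design")
  if (any(m < 0)) stopf("concentrations must be non-negative")
  if (any(m[source$matrix == 0] != 0)) stopf("entries must be zero wherever the design is zero")
  structure(list(matrix = m, source = source), class = "noisy_design")
}

# accept a pool_design or noisy_design wherever concentrations are needed
as_noisy_design <- function(x) {
  if (inherits(x, "noisy_design")) return(x)
  if (inherits(x, "pool_design")) return(noisy_design(x$matrix, x))
  stopf("expected a pool_design or noisy_design")
}

#' Add concentration noise to a pooling design
#'
#' Models unequal sample amounts in each pool: every non-zero design
#' entry receives independent Normal(0, `sigma_p`) noise and is clamped
#' at zero (concentrations are physical); zero entries stay exactly zero.
#'
#' @param design A [pool_design()].
#' @param sigma_p Noise standard deviation (>= 0).
#' @param seed Seed for reproducibility.
#' @return A [noisy_design()].
#' @examples
#' d <- generate_random_design(10, 4, seed = 1)
#' ahat <- perturb_design(d, sigma_p = 0.05, seed = 2)
#' @export
perturb_design <- function(design, sigma_p = 0.05, seed = NULL) {
  if (!inherits(design, "pool_design")) stopf("`design` must be a pool_design")
  if (!is.numeric(sigma_p) || length(sigma_p) != 1L || sigma_p < 0)
    stopf("`sigma_p` must be non-negative")
  m <- design$matrix
  with_seed(seed, {
    on_idx <- which(m == 1)
    m[on_idx] <- pmax(0, 1 + rnorm(length(on_idx), 0, sigma_p))
    noisy_design(m, design)
  })
}

#' Per-pool read counts
#'
#' Container for observed pool-level counts.  Genotyping experiments
#' carry major- and minor-allele counts (`y_major`, `y_minor`); fusion
#' experiments carry a single fusion-read count per pool (`y_fusion`).
#' Counts may be non-integer because pooling mixes per-individual reads
#' with real-valued concentrations.
#'
#' @param y_major,y_minor Non-negative length-T vectors of major/minor
#'   allele read counts (genotyping mode).
#' @param y_fusion Non-negative length-T vector of fusion-supporting read
#'   counts (fusion mode); mutually exclusive with `y_major`/`y_minor`.
#' @param site_coverage Optional realized per-individual coverage draws
#'   `m_i`, kept for diagnostics.
#' @param pool_ids Optional pool labels.
#' @return An object of class `pool_counts` with a `kind` field of
#'   `"genotype"` or `"fusion"`.
#' @export
pool_counts <- function(y_major = NULL, y_minor = NULL, y_fusion = NULL,
                        site_coverage = NULL, pool_ids = NULL) {
  if (!is.null(y_fusion)) {
    if (!is.null(y_major) || !is.null(y_minor))
      stopf("supply either genotype counts or fusion counts, not both")
    y_fusion <- as.numeric(y_fusion)
    if (any(!is.finite(y_fusion)) || any(y_fusion < 0)) stopf("counts must be finite and non-negative")
    kind <- "fusion"
    n <- length(y_fusion)
  } else {
    if (is.null(y_major) || is.null(y_minor)) stopf("genotype counts need `y_major` and `y_minor`")
    y_major <- as.numeric(y_major); y_minor <- as.numeric(y_minor)
    if (length(y_major) != length(y_minor)) stopf("`y_major` and `y_minor` must have equal length")
    if (any(!is.finite(c(y_major, y_minor))) || any(c(y_major, y_minor) < 0))
      stopf("counts must be finite and non-negative")
    kind <- "genotype"
    n <- length(y_major)
  }
  if (is.null(pool_ids)) pool_ids <- paste0("P", seq_len(n))
  if (length(pool_ids) != n) stopf("`pool_ids` must have one entry per pool")
  structure(list(kind = kind, y_major = y_major, y_minor = y_minor,
                 y_fusion = y_fusion, site_coverage = site_coverage,
                 pool_ids = as.character(pool_ids)),
            class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  n <- if (x$kind == "fusion") length(x$y_fusion) else length(x$y_major)
  cat(sprintf("pool_counts (%s): %d pools\n", x$kind, n))
  if (x$kind == "fusion") cat("  y_fusion:", format(utils::head(x$y_fusion), digits = 4), "...\n")
  else cat("  y_minor:", format(utils::head(x$y_minor), digits = 4), "...\n")
  invisible(x)
}

n_pools_of <- function(counts) {
  if (counts$kind == "fusion") length(counts$y_fusion) else length(counts$y_major)
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Draws `n_samples` independent genotypes at a biallelic site with minor
#' allele frequency `allele_freq`: counts of the minor allele are
#' Binomial(2, p), i.e. P(0) = (1-p)^2, P(1) = 2p(1-p), P(2) = p^2.
#'
#' @param allele_freq Minor allele frequency in `[0, 1]`.
#' @param n_samples Number of individuals.
#' @param seed Seed for reproducibility.
#' @return Integer vector of genotypes in `{0, 1, 2}`.
#' @examples
#' table(simulate_genotypes_hwe(0.3, 1000, seed = 1))
#' @export
simulate_genotypes_hwe <- function(allele_freq, n_samples, seed = NULL) {
  if (!is.numeric(allele_freq) || length(allele_freq) != 1L ||
      allele_freq < 0 || allele_freq > 1)
    stopf("`allele_freq` must lie in [0, 1]")
  if (!is_count(n_samples) || n_samples < 1) stopf("`n_samples` must be a positive integer")
  with_seed(seed, rbinom(n_samples, 2L, allele_freq))
}

check_genotypes <- function(g, n = NULL) {
  if (!is.numeric(g) || any(!is.finite(g)) || any(g != floor(g)) || any(g < 0 | g > 2))
    stopf("genotypes must be integers in {0, 1, 2}")
  if (!is.null(n) && length(g) != n)
    stopf("genotype vector has length %d but the design has %d samples", length(g), n)
  as.integer(g)
}

#' Simulate pooled read counts for one biallelic site
#'
#' Generative model: each individual's coverage `m_i` is drawn from a
#' Gamma distribution with shape `gamma_shape` and mean `coverage_lambda`;
#' minor-allele reads are Poisson with mean `m_i * g_i` and major-allele
#' reads Poisson with mean `m_i * (2 - g_i)`; sequencing error then moves
#' each read to the other allele class independently with probability
#' `epsilon` (binomial thinning both ways).  The pool counts are
#' `Y^k = A_hat %*% R^k`: per-individual reads are drawn once and mixed
#' into every pool containing the individual.  Setting
#' `per_pool = TRUE` instead draws independent Poisson reads for every
#' (pool, individual) cell, matching the decoder's independence
#' assumption exactly.
#'
#' @param genotypes Integer vector in `{0,1,2}`, one entry per sample.
#' @param noisy_design A [noisy_design()] (or [pool_design()] for exact
#'   concentrations).
#' @param noise A [noise_params()].
#' @param seed Seed for reproducibility.
#' @param per_pool Draw reads independently per pool (default `FALSE`).
#' @return A [pool_counts()] of kind `"genotype"`; `site_coverage` holds
#'   the realized `m_i` (for `per_pool = FALSE`).
#' @examples
#' d <- generate_random_design(10, 4, seed = 1)
#' g <- simulate_genotypes_hwe(0.3, 10, seed = 2)
#' simulate_genotype_pools(g, d, noise_params(coverage_lambda = 50), seed = 3)
#' @export
simulate_genotype_pools <- function(genotypes, noisy_design, noise, seed = NULL,
                                    per_pool = FALSE) {
  nd <- as_noisy_design(noisy_design)
  if (!inherits(noise, "noise_params")) stopf("`noise` must be a noise_params object")
  A <- nd$matrix
  g <- check_genotypes(genotypes, ncol(A))
  N <- length(g)
  lam <- noise$coverage_lambda
  eps <- noise$epsilon
  with_seed(seed, {
    if (per_pool) {
      # independent reads in every (pool, individual) cell
      mu1 <- sweep(A, 2L, g, "*") * lam
      mu0 <- sweep(A, 2L, 2 - g, "*") * lam
      r1 <- matrix(rpois(length(mu1), mu1), nrow(A))
      r0 <- matrix(rpois(length(mu0), mu0), nrow(A))
      flip1 <- matrix(rbinom(length(r1), r1, eps), nrow(A))
      flip0 <- matrix(rbinom(length(r0), r0, eps), nrow(A))
      y1 <- rowSums(r1 - flip1 + flip0)
      y0 <- rowSums(r0 - flip0 + flip1)
      m <- NULL
    } else {
      m <- rgamma(N, shape = noise$gamma_shape, scale = lam / noise$gamma_shape)
      r1 <- rpois(N, m * g)
      r0 <- rpois(N, m * (2 - g))
      flip1 <- rbinom(N, r1, eps)   # true-minor reads read as major
      flip0 <- rbinom(N, r0, eps)   # true-major reads read as minor
      obs1 <- r1 - flip1 + flip0
      obs0 <- r0 - flip0 + flip1
      y1 <- as.vector(A %*% obs1)
      y0 <- as.vector(A %*% obs0)
    }
    pool_counts(y_major = y0, y_minor = y1, site_coverage = m,
                pool_ids = nd$source$pool_ids)
  })
}

#' Imputation prior
#'
#' Per-individual genotype probability distributions, as produced by an
#' imputation engine run against a reference panel: row `i` holds
#' `(h_i(0), h_i(1), h_i(2))`, the probabilities that individual `i`
#' carries 0, 1, or 2 copies of the minor allele.  The dosage
#' `I_i = h_i(1) + 2 h_i(2)` is the expected genotype and anchors the LP
#' decoder.
#'
#' @param probs N x 3 matrix of genotype probabilities; rows must sum to
#'   1 (tolerance 1e-9) and entries lie in `[0, 1]`.
#' @param sample_ids Optional sample labels.
#' @return An object of class `imputation_prior` with elements `probs`
#'   and `dosage`.
#' @export
imputation_prior <- function(probs, sample_ids = NULL) {
  p <- as.matrix(probs)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) stopf("`probs` must have 3 columns")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) stopf("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(p) - 1) > 1e-9)) stopf("each prior row must sum to 1")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(p)))
  if (length(sample_ids) != nrow(p)) stopf("`sample_ids` must have one entry per row")
  dimnames(p) <- NULL
  structure(list(probs = p, dosage = as.vector(p[, 2] + 2 * p[, 3]),
                 sample_ids = as.character(sample_ids)),
            class = "imputation_prior")
}

#' Simulate calibrated synthetic imputation priors
#'
#' Stand-in for the output of a real imputation engine.  For each
#' individual, with probability `concordance` the prior's modal genotype
#' equals the true genotype; otherwise the mode is one of the other two
#' genotypes, chosen with probability proportional to their
#' Hardy-Weinberg frequencies.  Probability mass `confidence` is placed
#' on the mode and the remainder is split over the other genotypes in
#' proportion to their Hardy-Weinberg frequencies.  With `concordance`
#' 0.955 the chance that all of 100 individuals have a correct modal
#' genotype is about 0.955^100 = 0.01, the regime where raw imputation
#' almost never gets a whole site right.
#'
#' @param genotypes True genotype vector in `{0,1,2}`.
#' @param concordance Per-individual probability that the modal genotype
#'   is correct, in `(0, 1]`.
#' @param confidence Probability mass on the modal genotype, in
#'   `(1/3, 1]`.
#' @param allele_freq Allele frequency used for the Hardy-Weinberg
#'   weights; estimated from `genotypes` when omitted.
#' @param seed Seed for reproducibility.
#' @return An [imputation_prior()].
#' @examples
#' g <- simulate_genotypes_hwe(0.3, 50, seed = 1)
#' pr <- simulate_imputation_priors(g, concordance = 0.955, seed = 2)
#' mean((max.col(pr$probs) - 1L) == g)  # ~0.955
#' @export
simulate_imputation_priors <- function(genotypes, concordance = 0.955,
                                       confidence = 0.95, allele_freq = NULL,
                                       seed = NULL) {
  g <- check_genotypes(genotypes)
  if (!is.numeric(concordance) || length(concordance) != 1L ||
      concordance <= 0 || concordance > 1)
    stopf("`concordance` must lie in (0, 1]")
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence <= 1 / 3 || confidence > 1)
    stopf("`confidence` must lie in (1/3, 1]")
  if (is.null(allele_freq)) allele_freq <- mean(g) / 2
  p <- allele_freq
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  N <- length(g)
  with_seed(seed, {
    mode <- g
    wrong <- runif(N) >= concordance
    for (i in which(wrong)) {
      others <- setdiff(0:2, g[i])
      w <- hw[others + 1L]
      if (sum(w) <= 0) w <- c(1, 1)
      mode[i] <- others[sample.int(2L, 1L, prob = w)]
    }
    probs <- matrix(0, N, 3L)
    for (i in seq_len(N)) {
      others <- setdiff(0:2, mode[i])
      w <- hw[others + 1L]
      if (sum(w) <= 0) w <- c(1, 1)
      probs[i, mode[i] + 1L] <- confidence
      probs[i, others + 1L] <- (1 - confidence) * w / sum(w)
    }
    imputation_prior(probs)
  })
}

#' Fusion-gene carrier scenario
#'
#' Ground truth for a fusion experiment: which samples carry the fusion
#' and the (unknown to the decoder) relative expression level of the
#' fusion transcript in each carrier, constant across pools.
#'
#' @param carriers Integer vector of carrier sample indices (1-based).
#' @param expression Positive expression level for each carrier, same
#'   length and order as `carriers`.
#' @param n_samples Total number of samples.
#' @return An object of class `fusion_scenario`.
#' @export
fusion_scenario <- function(carriers, expression, n_samples) {
  carriers <- as.integer(carriers)
  if (anyDuplicated(carriers)) stopf("`carriers` must be distinct")
  if (length(carriers) && (min(carriers) < 1L || max(carriers) > n_samples))
    stopf("carrier indices must lie in 1..n_samples")
  expression <- as.numeric(expression)
  if (length(expression) != length(carriers)) stopf("one expression level per carrier")
  if (any(expression <= 0)) stopf("expression levels must be positive")
  structure(list(carriers = carriers, expression = expression,
                 n_samples = as.integer(n_samples)),
            class = "fusion_scenario")
}

#' Simulate pooled fusion read counts
#'
#' Each carrier `j` receives a relative expression level `e_j` drawn
#' log-uniformly on `[1, range]`, so the concentration of the fusion
#' transcript differs by up to a factor of `expression_fold_range`
#' between carriers; the unit baseline is the nominal expression at
#' which one pool membership yields `coverage_lambda` expected reads.  With the default
#' `mixing = "per_individual"`, carrier `j`'s fusion reads are drawn
#' once, `r_j ~ Poisson(lambda * e_j)`, and mixed into every pool
#' containing the carrier (the pooled library is sequenced from the
#' same material, so `Y = A H`); `mixing = "per_pool"` instead draws
#' independent Poisson reads with mean `A[t, j] * lambda * e_j` in
#' every (pool, carrier) cell.  Spurious background reads (sequencing
#' error producing apparent chimeric reads) are added per pool: with
#' the default `error_model = "per_pool"` each pool accrues background
#' Poisson reads with mean `epsilon * lambda`; with `"per_sample"`
#' every non-carrier contributes background with mean
#' `A[t, j] * lambda * epsilon`, so background grows with pool size.
#'
#' @param carriers Integer vector of carrier indices (possibly empty).
#' @param n_samples Total number of samples N.
#' @param design A [pool_design()] with N columns.
#' @param expression_fold_range Maximal fold difference between carrier
#'   expression levels (>= 1); default 10.
#' @param coverage_lambda Expected fusion reads per unit expression per
#'   pool membership.
#' @param epsilon Background (error) read rate multiplier.
#' @param error_model `"per_pool"` (default) or `"per_sample"`, see
#'   above.
#' @param mixing `"per_individual"` (default: one read count per
#'   carrier, shared across its pools) or `"per_pool"` (independent
#'   Poisson per pool).
#' @param seed Seed for reproducibility.
#' @return A list with `counts` (a [pool_counts()] of kind `"fusion"`)
#'   and `scenario` (a [fusion_scenario()] with the realized expression
#'   levels, for parameter-recovery tests).
#' @examples
#' d <- generate_random_design(20, 6, seed = 1)
#' sim <- simulate_fusion_pools(c(3, 11), 20, d, coverage_lambda = 16, seed = 2)
#' sim$counts$y_fusion
#' @export
simulate_fusion_pools <- function(carriers, n_samples, design,
                                  expression_fold_range = 10,
                                  coverage_lambda = 16, epsilon = 0.01,
                                  error_model = c("per_pool", "per_sample"),
                                  mixing = c("per_individual", "per_pool"),
                                  seed = NULL) {
  error_model <- match.arg(error_model)
  mixing <- match.arg(mixing)
  if (!inherits(design, "pool_design")) stopf("`design` must be a pool_design")
  if (ncol(design$matrix) != n_samples)
    stopf("design has %d samples but `n_samples` = %d", ncol(design$matrix), n_samples)
  carriers <- as.integer(carriers)
  if (length(carriers) && max(carriers) > n_samples)
    stopf("carrier index %d exceeds n_samples = %d", max(carriers), n_samples)
  if (length(carriers) && min(carriers) < 1L) stopf("carrier indices must be >= 1")
  if (!is.numeric(expression_fold_range) || expression_fold_range < 1)
    stopf("`expression_fold_range` must be >= 1")
  if (!is.numeric(coverage_lambda) || coverage_lambda <= 0) stopf("`coverage_lambda` must be positive")
  if (!is.numeric(epsilon) || epsilon < 0) stopf("`epsilon` must be non-negative")
  A <- design$matrix
  Tn <- nrow(A)
  with_seed(seed, {
    k <- length(carriers)
    e <- exp(runif(k, 0, log(expression_fold_range)))
    signal <- if (k == 0) {
      rep(0, Tn)
    } else if (mixing == "per_individual") {
      r <- rpois(k, coverage_lambda * e)
      as.vector(A[, carriers, drop = FALSE] %*% r)
    } else {
      mu <- A[, carriers, drop = FALSE] * coverage_lambda *
        matrix(e, Tn, k, byrow = TRUE)
      rowSums(matrix(rpois(length(mu), mu), Tn))
    }
    bg_mu <- if (error_model == "per_pool") {
      rep(epsilon * coverage_lambda, Tn)
    } else {
      noncar <- setdiff(seq_len(n_samples), carriers)
      epsilon * coverage_lambda *
        (if (length(noncar)) rowSums(A[, noncar, drop = FALSE]) else rep(0, Tn))
    }
    y <- signal + rpois(Tn, bg_mu)
    list(counts = pool_counts(y_fusion = y, pool_ids = design$pool_ids),
         scenario = fusion_scenario(carriers, e, n_samples))
  })
}
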