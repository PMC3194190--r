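#' Run a simulate-and-decode benchmark
#'
#' Runs `n_trials` (fusion) or `n_sites` (genotyping) independent
#' simulate-decode cycles under an [experiment_config()] and reports the
#' accuracy with an exact binomial 95% confidence interval.  A site or
#' trial is counted correct only if *every* individual genotype is
#' recovered (genotyping) or the exact carrier set is called (fusion).
#' Trial `i` is seeded with [derive_seed()]`(seed, i)` so it can be
#' reproduced in isolation; the design is generated and local-search
#' optimized once per run from `derive_seed(seed, 0)`.
#'
#' @param config An [experiment_config()].
#' @param design Optional pre-built [pool_design()]; by default one is
#'   generated and optimized per the config.
#' @param fixed_noisy_design If `TRUE`, draw the concentration noise once
#'   and reuse the same realized matrix for every site (default `FALSE`:
#'   redrawn per site).
#' @param progress Print a dot every 10 trials.
#' @return A one-row `data.frame`: scenario, the key parameters,
#'   `n_trials`, `n_correct`, `accuracy`, `ci_lower`, `ci_upper`, and
#'   for the imputed scenario `baseline_accuracy` (fraction of sites
#'   where the rounded prior alone is correct for every individual).
#' @examples
#' \donttest{
#' cfg <- experiment_config("fusion", n_pools = 10, coverage_lambda = 16,
#'                          epsilon = 0.01, n_carriers = 1, n_trials = 5, seed = 1)
#' run_benchmark(cfg)
#' }
#' @export
run_benchmark <- function(config, design = NULL, fixed_noisy_design = FALSE,
                          progress = FALSE) {
  if (!inherits(config, "experiment_config")) stopf("`config` must be an experiment_config")
  cfg <- config
  if (is.null(design)) {
    design <- generate_random_design(cfg$n_samples, cfg$n_pools,
                                     seed = derive_seed(cfg$seed, 0))
    if (cfg$optimize_iters > 0)
      design <- local_search_optimize(design, n_iters = cfg$optimize_iters,
                                      seed = derive_seed(cfg$seed, 0))
  }
  n_rep <- if (cfg$scenario == "fusion") cfg$n_trials else cfg$n_sites
  correct <- logical(n_rep)
  baseline <- rep(NA, n_rep)
  failures <- 0L

  fixed_nd <- if (fixed_noisy_design)
    perturb_design(design, cfg$sigma_p, seed = derive_seed(cfg$seed, 0)) else NULL

  for (i in seq_len(n_rep)) {
    s <- derive_seed(cfg$seed, i)
    res <- tryCatch(switch(cfg$scenario,
      genotyping_imputed = {
        maf <- with_seed(s, runif(1, 0.05, 0.5))
        g <- simulate_genotypes_hwe(maf, cfg$n_samples, seed = derive_seed(s, 1))
        prior <- simulate_imputation_priors(g, cfg$concordance, cfg$confidence,
                                            allele_freq = maf, seed = derive_seed(s, 2))
        nd <- if (fixed_noisy_design) fixed_nd
              else perturb_design(design, cfg$sigma_p, seed = derive_seed(s, 3))
        np <- noise_params(sigma_p = cfg$sigma_p, epsilon = cfg$epsilon,
                           coverage_lambda = cfg$coverage_lambda)
        cnt <- simulate_genotype_pools(g, nd, np, seed = derive_seed(s, 4),
                                       per_pool = cfg$read_model == "per_pool")
        dec <- decode_lp(cnt, nd, cfg$coverage_lambda, prior, beta = cfg$beta,
                         epsilon = cfg$epsilon)
        list(correct = all(dec$genotypes == g),
             baseline = all((max.col(prior$probs) - 1L) == g))
      },
      genotyping_rare = {
        n_car <- with_seed(s, sample.int(max(1L, cfg$n_carriers), 1L))
        g <- integer(cfg$n_samples)
        g[with_seed(derive_seed(s, 1), sample.int(cfg$n_samples, n_car))] <- 1L
        nd <- if (fixed_noisy_design) fixed_nd
              else perturb_design(design, cfg$sigma_p, seed = derive_seed(s, 3))
        np <- noise_params(sigma_p = cfg$sigma_p, epsilon = cfg$epsilon,
                           coverage_lambda = cfg$coverage_lambda)
        cnt <- simulate_genotype_pools(g, nd, np, seed = derive_seed(s, 4),
                                       per_pool = cfg$read_model == "per_pool")
        dec <- decode_rare(cnt, nd, cfg$coverage_lambda, beta = cfg$beta,
                           epsilon = cfg$epsilon)
        list(correct = all(dec$genotypes == g), baseline = NA)
      },
      fusion = {
        carriers <- with_seed(s, sort(sample.int(cfg$n_samples, cfg$n_carriers)))
        sim <- simulate_fusion_pools(carriers, cfg$n_samples, design,
                                     expression_fold_range = cfg$expression_fold_range,
                                     coverage_lambda = cfg$coverage_lambda,
                                     epsilon = cfg$epsilon, seed = derive_seed(s, 1))
        call <- detect_fusion(sim$counts, design, cfg$coverage_lambda,
                              epsilon = cfg$epsilon, k = cfg$k)
        list(correct = setequal(call$carriers, carriers), baseline = NA)
      }),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      warnf("trial %d failed: %s", i, conditionMessage(res))
      correct[i] <- FALSE
    } else {
      correct[i] <- isTRUE(res$correct)
      baseline[i] <- res$baseline
    }
    if (progress && i %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")

  n_ok <- sum(correct)
  ci <- binom.test(n_ok, n_rep)$conf.int
  out <- data.frame(scenario = cfg$scenario, n_samples = cfg$n_samples,
                    n_pools = cfg$n_pools, coverage_lambda = cfg$coverage_lambda,
                    epsilon = cfg$epsilon,
                    n_carriers = if (cfg$scenario == "fusion") cfg$n_carriers else NA,
                    n_trials = n_rep, n_correct = n_ok,
                    accuracy = n_ok / n_rep,
                    ci_lower = ci[1], ci_upper = ci[2],
                    baseline_accuracy = if (all(is.na(baseline))) NA
                                        else mean(baseline, na.rm = TRUE),
                    n_failed = failures,
                    stringsAsFactors = FALSE)
  out
}

#' Standard benchmark grids
#'
#' `benchmark_genotyping_grid()` runs the common-variant decoding
#' experiment (100 individuals, MAF >= 5%, coverage 150, error 0.005,
#' imputation priors calibrated to a ~1% whole-site baseline) for a set
#' of pool counts.  `benchmark_fusion_grid()` runs the fusion-detection
#' experiment (100 tumor samples, 10-fold expression variability, error
#' 0.01) over a grid of (pools, coverage) settings and 1-3 true
#' carriers.
#'
#' @param seed Master seed.
#' @param pool_counts Pool counts to sweep (genotyping).
#' @param n_sites,n_trials Number of sites / trials per configuration.
#' @param grid Data frame with columns `n_pools` and `coverage_lambda`
#'   (fusion).
#' @param carrier_counts True carrier counts to sweep (fusion).
#' @param progress Print progress dots.
#' @return Data frame with one row per configuration, as
#'   [run_benchmark()].
#' @export
benchmark_genotyping_grid <- function(seed = 1, pool_counts = c(36, 30),
                                      n_sites = 100, progress = FALSE) {
  do.call(rbind, lapply(pool_counts, function(tp) {
    cfg <- experiment_config("genotyping_imputed", n_pools = tp,
                             n_sites = n_sites, seed = derive_seed(seed, tp))
    run_benchmark(cfg, progress = progress)
  }))
}

#' @rdname benchmark_genotyping_grid
#' @export
benchmark_fusion_grid <- function(seed = 1,
                                  grid = data.frame(
                                    n_pools = c(10, 10, 10, 10, 10, 10, 4, 6, 8),
                                    coverage_lambda = c(4, 12, 16, 20, 24, 28, 28, 28, 28)),
                                  carrier_counts = 1:3, n_trials = 100,
                                  progress = FALSE) {
  rows <- list()
  for (r in seq_len(nrow(grid))) {
    for (nc in carrier_counts) {
      cfg <- experiment_config("fusion", n_pools = grid$n_pools[r],
                               coverage_lambda = grid$coverage_lambda[r],
                               epsilon = 0.01, n_carriers = nc,
                               n_trials = n_trials,
                               seed = derive_seed(seed, 100 * r + nc))
      rows[[length(rows) + 1L]] <- run_benchmark(cfg, progress = progress)
    }
  }
  do.call(rbind, rows)
}
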