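#' Read and write pooling experiment files
#'
#' All matrix-shaped files are headered, UTF-8, tab-separated.
#' * Design: first column `pool_id`, one 0/1 column per sample, header
#'   row carrying the sample IDs.
#' * Genotype counts: columns `pool_id`, `y_major`, `y_minor`.
#' * Fusion counts: columns `pool_id`, `y_fusion`.
#' * Imputation prior: columns `sample_id`, `p0`, `p1`, `p2`.
#' Malformed rows are reported with their line number (counting the
#' header as line 1).
#'
#' @param design A [pool_design()].
#' @param path File path.
#' @return The read functions return the corresponding object; the write
#'   functions return `path` invisibly.
#' @name pool_io
NULL

io_err <- function(path, line, msg) {
  stopf("%s, line %d: %s", path, line, msg)
}

#' @rdname pool_io
#' @export
write_design <- function(design, path) {
  if (!inherits(design, "pool_design")) stopf("`design` must be a pool_design")
  df <- data.frame(pool_id = design$pool_ids, design$matrix, check.names = FALSE)
  names(df) <- c("pool_id", design$sample_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pool_io
#' @export
read_design <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = NA)
  if (ncol(df) < 2L || names(df)[1] != "pool_id")
    stopf("%s: expected a header starting with 'pool_id'", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | (m != 0 & m != 1), arr.ind = TRUE)
  if (nrow(bad)) io_err(path, bad[1, 1] + 1L, sprintf(
    "design entry '%s' is not 0/1", as.character(m[bad[1, 1], bad[1, 2]])))
  pool_design(m, pool_ids = df$pool_id, sample_ids = names(df)[-1])
}

#' @rdname pool_io
#' @param counts A [pool_counts()].
#' @export
write_counts <- function(counts, path) {
  if (!inherits(counts, "pool_counts")) stopf("`counts` must be pool_counts")
  df <- if (counts$kind == "fusion") {
    data.frame(pool_id = counts$pool_ids, y_fusion = counts$y_fusion)
  } else {
    data.frame(pool_id = counts$pool_ids, y_major = counts$y_major,
               y_minor = counts$y_minor)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pool_io
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  fusion <- "y_fusion" %in% names(df)
  need <- if (fusion) "y_fusion" else c("y_major", "y_minor")
  if (!"pool_id" %in% names(df) || !all(need %in% names(df)))
    stopf("%s: expected columns pool_id plus %s", path, paste(need, collapse = "/"))
  for (col in need) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) io_err(path, bad[1] + 1L, sprintf(
      "%s value '%s' is negative or not a number", col, as.character(v[bad[1]])))
  }
  if (fusion) pool_counts(y_fusion = df$y_fusion, pool_ids = df$pool_id)
  else pool_counts(y_major = df$y_major, y_minor = df$y_minor, pool_ids = df$pool_id)
}

#' @rdname pool_io
#' @param prior An [imputation_prior()].
#' @export
write_prior <- function(prior, path) {
  if (!inherits(prior, "imputation_prior")) stopf("`prior` must be an imputation_prior")
  df <- data.frame(sample_id = prior$sample_ids,
                   p0 = prior$probs[, 1], p1 = prior$probs[, 2], p2 = prior$probs[, 3])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pool_io
#' @export
read_prior <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("sample_id", "p0", "p1", "p2")
  if (!all(need %in% names(df)))
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  p <- as.matrix(df[, c("p0", "p1", "p2")])
  bad <- which(!is.finite(p) | p < 0 | p > 1, arr.ind = TRUE)
  if (nrow(bad)) io_err(path, bad[1, 1] + 1L, "probability outside [0, 1]")
  badrow <- which(abs(rowSums(p) - 1) > 1e-6)
  if (length(badrow)) io_err(path, badrow[1] + 1L, "probabilities do not sum to 1")
  # renormalize away file-precision rounding before the strict constructor
  p <- p / rowSums(p)
  imputation_prior(p, sample_ids = df$sample_id)
}

#' Write decoded genotypes as VCF
#'
#' Emits a minimal VCF 4.2 file with one record per site and one sample
#' column per individual.  `FORMAT` carries `GT` (diploid genotype,
#' `0/0`, `0/1` or `1/1`) and `FX`, the fractional LP solution for the
#' sample at that site.
#'
#' @param genotypes S x N integer matrix (sites x samples) in `{0,1,2}`,
#'   or a single genotype vector.
#' @param path Output path.
#' @param sample_ids Sample names (default `S1..SN`).
#' @param site_ids Site names (default `site1..siteS`).
#' @param fractional Optional S x N matrix of fractional LP solutions.
#' @return `path`, invisibly.
#' @export
write_vcf_calls <- function(genotypes, path, sample_ids = NULL, site_ids = NULL,
                            fractional = NULL) {
  G <- if (is.matrix(genotypes)) genotypes else matrix(genotypes, nrow = 1L)
  S <- nrow(G); N <- ncol(G)
  if (any(!(G %in% 0:2))) stopf("genotypes must be integers in {0, 1, 2}")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(N))
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(S))
  if (!is.null(fractional)) {
    fractional <- if (is.matrix(fractional)) fractional else matrix(fractional, nrow = 1L)
    if (!identical(dim(fractional), dim(G))) stopf("`fractional` must match `genotypes` in shape")
  }
  gt_code <- c("0/0", "0/1", "1/1")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=pooldecode",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=FX,Number=1,Type=Float,Description=\"Fractional LP solution\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", sample_ids), collapse = "\t"))
  rows <- vapply(seq_len(S), function(s) {
    cells <- vapply(seq_len(N), function(j) {
      fx <- if (is.null(fractional)) sprintf("%.4f", G[s, j])
            else sprintf("%.4f", fractional[s, j])
      paste0(gt_code[G[s, j] + 1L], ":", fx)
    }, character(1))
    paste(c("1", s, site_ids[s], "A", "C", ".", "PASS", ".", "GT:FX", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Experiment configuration
#'
#' Parameter bundle describing one simulate-and-decode experiment, used
#' by [run_benchmark()] and serializable to YAML with an exact
#' round-trip.
#'
#' @param scenario One of `"genotyping_imputed"`, `"genotyping_rare"`,
#'   `"fusion"`.
#' @param n_samples,n_pools Cohort and design size.
#' @param coverage_lambda Expected reads per chromosomal copy (genotyping)
#'   or per unit expression (fusion).
#' @param epsilon Sequencing error rate.
#' @param sigma_p Concentration noise (genotyping scenarios).
#' @param beta LP anchor trade-off.
#' @param k Maximal carrier-set size for fusion decoding.
#' @param n_carriers True number of fusion carriers per trial, or the
#'   maximum number of rare-variant carriers per site (1 to `n_carriers`
#'   drawn uniformly).
#' @param n_trials Number of fusion trials.
#' @param n_sites Number of genotyping sites.
#' @param seed Master seed; trial `i` uses [derive_seed()]`(seed, i)`.
#' @param concordance,confidence Synthetic imputation prior calibration
#'   (see [simulate_imputation_priors()]).
#' @param read_model Genotype read simulation variant: `"per_pool"`
#'   (independent Poisson reads in every pool-individual cell, matching
#'   the decoder's likelihood) or `"mixed"` (per-individual Gamma-Poisson
#'   reads mixed through the concentration matrix).
#' @param expression_fold_range Fusion expression variability.
#' @param optimize_iters Local-search iterations applied to the design.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scenario = c("genotyping_imputed", "genotyping_rare", "fusion"),
                              n_samples = 100, n_pools = 36,
                              coverage_lambda = 150, epsilon = 0.005,
                              sigma_p = 0.05, beta = 1, k = 3, n_carriers = 1,
                              n_trials = 100, n_sites = 100, seed = 1,
                              concordance = 0.955, confidence = 0.95,
                              expression_fold_range = 10, optimize_iters = 1000,
                              read_model = c("per_pool", "mixed")) {
  scenario <- match.arg(scenario)
  read_model <- match.arg(read_model)
  cfg <- list(scenario = scenario, n_samples = n_samples, n_pools = n_pools,
              coverage_lambda = coverage_lambda, epsilon = epsilon,
              sigma_p = sigma_p, beta = beta, k = k, n_carriers = n_carriers,
              n_trials = n_trials, n_sites = n_sites, seed = seed,
              concordance = concordance, confidence = confidence,
              expression_fold_range = expression_fold_range,
              optimize_iters = optimize_iters, read_model = read_model)
  for (f in c("n_samples", "n_pools", "n_trials", "n_sites", "k", "n_carriers",
              "optimize_iters"))
    if (!is_count(cfg[[f]])) stopf("`%s` must be a non-negative integer", f)
  if (cfg$n_samples < 2 || cfg$n_pools < 1) stopf("need n_samples >= 2 and n_pools >= 1")
  if (cfg$epsilon < 0 || cfg$epsilon >= 0.5) stopf("`epsilon` must lie in [0, 0.5)")
  if (cfg$sigma_p < 0) stopf("`sigma_p` must be non-negative")
  if (cfg$coverage_lambda <= 0) stopf("`coverage_lambda` must be positive")
  if (cfg$concordance <= 0 || cfg$concordance > 1) stopf("`concordance` must lie in (0, 1]")
  if (cfg$confidence <= 1/3 || cfg$confidence > 1) stopf("`confidence` must lie in (1/3, 1]")
  structure(cfg, class = "experiment_config")
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @param path File path (YAML).
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "experiment_config")) stopf("`config` must be an experiment_config")
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(experiment_config, lst)
}
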