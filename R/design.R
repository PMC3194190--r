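#' Pooling design matrices
#'
#' A pooling design is a binary T x N matrix `A`: row `t` describes pool
#' `t`, and `A[t, j] = 1` iff sample `j` is mixed into that pool.  Designs
#' constructed by [generate_random_design()] have exactly `floor(N/2)`
#' ones per row; user-supplied designs are only required to have at least
#' one `1` in every row and column, no duplicated rows, and 0/1 entries.
#'
#' @param matrix Binary matrix, pools in rows, samples in columns.
#' @param pool_ids Optional character vector of row labels (default
#'   `"P1"..."PT"`).
#' @param sample_ids Optional character vector of column labels (default
#'   `"S1"..."SN"`).
#' @return An object of class `pool_design` with elements `matrix`,
#'   `pool_ids`, `sample_ids`.
#' @examples
#' d <- pool_design(rbind(c(1, 0, 1), c(0, 1, 1)))
#' d$matrix
#' @export
pool_design <- function(matrix, pool_ids = NULL, sample_ids = NULL) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m != 0 & m != 1))
    stopf("design entries must all be 0 or 1")
  if (nrow(m) < 1L || ncol(m) < 1L) stopf("design must have at least one pool and one sample")
  if (any(rowSums(m) == 0)) stopf("every pool (row) must contain at least one sample")
  if (any(colSums(m) == 0))
    warnf("%d sample(s) appear in no pool and cannot be decoded",
          sum(colSums(m) == 0))
  if (anyDuplicated(apply(m, 1L, paste, collapse = "")))
    stopf("design rows must be distinct (duplicated pools carry no information)")
  if (is.null(pool_ids)) pool_ids <- paste0("P", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(m)))
  if (length(pool_ids) != nrow(m)) stopf("`pool_ids` must have one entry per row")
  if (length(sample_ids) != ncol(m)) stopf("`sample_ids` must have one entry per column")
  dimnames(m) <- NULL
  structure(list(matrix = m,
                 pool_ids = as.character(pool_ids),
                 sample_ids = as.character(sample_ids)),
            class = "pool_design")
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("pool_design: %d pools x %d samples\n", nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  row sums: %s\n", paste(range(rowSums(x$matrix)), collapse = "-")))
  cat(sprintf("  min pairwise row / column Hamming distance: %d / %d\n",
              design_min_distance(x, "rows")$min,
              design_min_distance(x, "columns")$min))
  invisible(x)
}

#' @export
dim.pool_design <- function(x) dim(x$matrix)

#' Generate a random half-ones pooling design
#'
#' Each row assigns exactly `floor(n_samples/2)` samples, placed uniformly
#' at random, to the pool.  Rows are redrawn until all are distinct.
#'
#' @param n_samples Number of samples N (>= 2).
#' @param n_pools Number of pools T (>= 1).
#' @param seed Seed for reproducibility.
#' @return A [pool_design()].
#' @examples
#' d <- generate_random_design(10, 5, seed = 1)
#' rowSums(d$matrix)  # all 5
#' @seealso [local_search_optimize()] to spread the rows and columns apart.
#' @export
generate_random_design <- function(n_samples, n_pools, seed = NULL) {
  if (!is_count(n_samples) || n_samples < 2) stopf("`n_samples` must be an integer >= 2")
  if (!is_count(n_pools) || n_pools < 1) stopf("`n_pools` must be an integer >= 1")
  if (n_pools > 2^min(n_samples, 62)) stopf("n_pools > 2^n_samples: duplicate pools are unavoidable")
  half <- floor(n_samples / 2)
  if (n_pools > choose(n_samples, half))
    stopf("n_pools exceeds the number of distinct rows with %d ones", half)
  with_seed(seed, {
    for (attempt in 1:1000) {
      m <- matrix(0, n_pools, n_samples)
      for (t in seq_len(n_pools)) m[t, sample.int(n_samples, half)] <- 1
      # redraw clashing rows until all pools are distinct
      for (redraw in 1:100) {
        dup <- which(duplicated(apply(m, 1L, paste, collapse = "")))
        if (length(dup) == 0L) break
        for (t in dup) {
          m[t, ] <- 0
          m[t, sample.int(n_samples, half)] <- 1
        }
      }
      # a sample left out of every pool is undecodable; give each one a slot
      # by swapping in a 1 from a column with spare coverage (row sums kept)
      for (fix in 1:(10 * n_samples)) {
        empty <- which(colSums(m) == 0)
        if (length(empty) == 0L) break
        t <- sample.int(n_pools, 1L)
        donors <- which(m[t, ] == 1 & colSums(m) >= 2)
        if (length(donors) == 0L) next
        m[t, donors[sample.int(length(donors), 1L)]] <- 0
        m[t, empty[1]] <- 1
      }
      covered <- all(colSums(m) >= 1) || n_pools * half < n_samples
      d <- tryCatch(if (covered) suppressWarnings(pool_design(m)),
                    error = function(e) NULL)
      if (!is.null(d)) {
        if (any(colSums(d$matrix) == 0))
          warnf("%d pools cannot cover all %d samples; some samples are unpooled",
                n_pools, n_samples)
        return(d)
      }
    }
    stopf("could not generate a valid %d x %d design", n_pools, n_samples)
  })
}

# min pairwise Hamming distance between rows or columns, plus the number of
# pairs attaining it (used as a lexicographic tie-break by the local search)
# and, optionally, which rows/columns sit in a minimum-distance pair
design_min_distance <- function(design, what = c("rows", "columns"),
                                members = FALSE) {
  what <- match.arg(what)
  m <- if (inherits(design, "pool_design")) design$matrix else as.matrix(design)
  if (what == "columns") m <- t(m)
  k <- nrow(m)
  if (k < 2L) return(list(min = NA_integer_, n_at_min = 0L, at_min = integer(0)))
  cp <- tcrossprod(m)               # inner products between rows
  s <- rowSums(m)
  h <- outer(s, s, "+") - 2 * cp    # Hamming distance for 0/1 rows
  diag(h) <- NA
  mn <- min(h, na.rm = TRUE)
  out <- list(min = as.integer(mn), n_at_min = sum(h == mn, na.rm = TRUE) / 2L)
  if (members) out$at_min <- which(apply(h == mn, 1L, any, na.rm = TRUE))
  out
}

#' Local-search optimization of a pooling design
#'
#' Spreads the rows and the columns of the design apart by hill climbing on
#' the minimum pairwise Hamming distance.  Each iteration makes two
#' sub-moves, both realized as a swap of a 0 and a 1 inside one row (which
#' preserves every row sum): a *row move* swaps two entries of a random
#' row and is accepted on the row-distance objective; a *column move*
#' picks a random column and exchanges one of its entries with a
#' differing entry of a second column in the same row, and is accepted on
#' the column-distance objective.  The objective is evaluated
#' lexicographically as (minimum pairwise distance, minus the number of
#' pairs attaining it), so plateau moves that reduce the number of
#' closest pairs are accepted; rejected moves are reverted.
#'
#' @param design A [pool_design()].
#' @param n_iters Number of iterations (row move + column move each).
#' @param seed Seed for reproducibility.
#' @param strict If `TRUE`, only accept sub-moves that strictly increase
#'   the minimum distance (no plateau exploration).
#' @return A [pool_design()] whose minimum pairwise row and column
#'   Hamming distances are each at least those of the input.
#' @examples
#' d <- generate_random_design(20, 8, seed = 1)
#' d2 <- local_search_optimize(d, n_iters = 200, seed = 2)
#' @export
local_search_optimize <- function(design, n_iters = 1000, seed = NULL, strict = FALSE) {
  if (!inherits(design, "pool_design")) stopf("`design` must be a pool_design")
  if (!is_count(n_iters)) stopf("`n_iters` must be a non-negative integer")
  m <- design$matrix
  if (nrow(m) < 2L || n_iters == 0L) return(design)

  obj <- function(mat, what) {
    d <- design_min_distance(mat, what)
    c(d$min, -d$n_at_min)
  }
  lex_ok <- function(new, old) {
    if (strict) return(new[1] > old[1])
    new[1] > old[1] || (new[1] == old[1] && new[2] >= old[2])
  }

  with_seed(seed, {
    row_obj <- obj(m, "rows")
    col_obj <- obj(m, "columns")
    row_min0 <- row_obj[1]; col_min0 <- col_obj[1]
    Tn <- nrow(m); N <- ncol(m)
    # a sub-move is accepted when its own objective does not decrease
    # (lexicographically) and the other view's minimum distance stays at
    # or above its value on entry; the output therefore dominates the
    # input in both minima, while neither view can lock the other out of
    # its plateau.  Columns must also stay covered and rows distinct.
    try_swap <- function(r, j1, j0, primary) {
      m[r, j1] <<- 0; m[r, j0] <<- 1
      if (sum(m[, j1]) == 0) {               # emptied a column
        m[r, j1] <<- 1; m[r, j0] <<- 0
        return(invisible(FALSE))
      }
      new_row <- obj(m, "rows"); new_col <- obj(m, "columns")
      ok <- if (primary == "rows")
        lex_ok(new_row, row_obj) && new_col[1] >= col_min0
      else
        lex_ok(new_col, col_obj) && new_row[1] >= row_min0
      if (ok && new_row[1] > 0) {
        row_obj <<- new_row; col_obj <<- new_col
      } else {
        m[r, j1] <<- 1; m[r, j0] <<- 0
      }
      invisible(ok)
    }
    for (iter in seq_len(n_iters)) {
      # row move: swap a random 1 and a random 0 inside a random row
      r <- sample.int(Tn, 1L)
      ones <- which(m[r, ] == 1); zeros <- which(m[r, ] == 0)
      if (length(ones) && length(zeros)) {
        try_swap(r, ones[sample.int(length(ones), 1L)],
                 zeros[sample.int(length(zeros), 1L)], "rows")
      }
      # column move: exchange an entry of a random column drawn from the
      # closest column pairs with a differing entry of another column in
      # the same row (row sums unchanged); targeting the minimum-distance
      # pairs is what lets the search separate duplicated columns within
      # the iteration budget
      close_cols <- design_min_distance(m, "columns", members = TRUE)$at_min
      c1 <- if (length(close_cols)) close_cols[sample.int(length(close_cols), 1L)]
            else sample.int(N, 1L)
      r2 <- sample.int(Tn, 1L)
      diffs <- which(m[r2, ] != m[r2, c1])
      if (length(diffs)) {
        c2 <- diffs[sample.int(length(diffs), 1L)]
        if (m[r2, c1] == 1) try_swap(r2, c1, c2, "columns")
        else try_swap(r2, c2, c1, "columns")
      }
    }
    pool_design(m, design$pool_ids, design$sample_ids)
  })
}

#' Information-theoretic lower bounds on the number of pools
#'
#' Counting bounds on the number of pools T needed to decode all N
#' individual genotypes from pool-level measurements.  With rounded
#' (presence/absence) pool results there are `2^T` observable outcomes
#' against `3^N` genotype vectors, giving `T > N log2(3)`
#' (`"rounded_binary"`).  Using full counts each pool can take about `2N`
#' values, giving `T > N log(3) / log(2N)` (`"full_counts"`).  For a rare
#' variant of allele frequency `alpha` the number of plausible genotype
#' vectors shrinks to roughly `(1/alpha)^(N alpha)`, giving
#' `T >= -N alpha log(alpha)` for rounded results (`"rare_rounded"`) and
#' `T >= -N alpha log(alpha) / log(2N)` with full counts
#' (`"rare_counts"`).
#'
#' @param n_samples Number of samples N (>= 1).
#' @param allele_freq Allele frequency `alpha` in (0, 1]; required for the
#'   `rare_*` modes.
#' @param mode One of `"rounded_binary"`, `"full_counts"`,
#'   `"rare_rounded"`, `"rare_counts"`.
#' @param base Logarithm base for the `rounded_binary` and `rare_rounded`
#'   entropy terms (default 2, i.e. bits, matching the binary counting
#'   argument).  The `*_counts` modes are ratios of logarithms and do not
#'   depend on the base.
#' @return The real-valued lower bound on T (callers should take the
#'   ceiling).
#' @examples
#' min_pools_lower_bound(100, mode = "rounded_binary")      # ~158.5
#' min_pools_lower_bound(100, 0.05, mode = "rare_rounded")  # ~21.6
#' @export
min_pools_lower_bound <- function(n_samples, allele_freq = NULL,
                                  mode = c("rounded_binary", "full_counts",
                                           "rare_rounded", "rare_counts"),
                                  base = 2) {
  mode <- match.arg(mode)
  if (!is_count(n_samples) || n_samples < 1) stopf("`n_samples` must be an integer >= 1")
  if (!is.numeric(base) || length(base) != 1L || base <= 1) stopf("`base` must be > 1")
  rare <- mode %in% c("rare_rounded", "rare_counts")
  if (rare) {
    if (is.null(allele_freq)) stopf("`allele_freq` is required for mode \"%s\"", mode)
    if (!is.numeric(allele_freq) || length(allele_freq) != 1L ||
        allele_freq <= 0 || allele_freq > 1)
      stopf("`allele_freq` must be in (0, 1]")
  }
  N <- n_samples
  switch(mode,
    rounded_binary = N * log(3, base = base),
    full_counts    = N * log(3) / log(2 * N),
    rare_rounded   = -N * allele_freq * log(allele_freq, base = base),
    rare_counts    = -N * allele_freq * log(allele_freq) / log(2 * N))
}
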