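#' Shuffle sample labels across two compared conditions
#'
#' Pools the samples assigned to the two compared conditions and reassigns
#' them uniformly at random, preserving the per-condition sample counts.
#' Samples outside the two conditions are untouched. This is the unit step
#' of the permutation null: under the shuffle, any systematic difference in
#' correlation between the two groups is destroyed.
#'
#' @param design Design tibble/matrix of 0/1 indicators.
#' @param compare The two condition names.
#' @param seed Optional integer seed (calls `set.seed()`), making the
#'   permutation deterministic.
#' @return A design tibble with permuted assignments in the two compared
#'   columns.
#' @export
permute_design <- function(design, compare, seed = NULL) {
  check_compare(design, compare)
  if (!is.null(seed)) set.seed(seed)
  m <- as_design_matrix(design)
  in1 <- m[, compare[1]] == 1
  in2 <- m[, compare[2]] == 1
  pooled <- which(in1 | in2)
  new1 <- sample(pooled, sum(in1))
  m[pooled, compare[1]] <- 0
  m[pooled, compare[2]] <- 0
  m[new1, compare[1]] <- 1
  m[setdiff(pooled, new1), compare[2]] <- 1
  tibble::as_tibble(m, rownames = "sample")
}

#' Pooled permutation null of |dz| values
#'
#' Reruns the full differential-correlation pipeline (same correlation
#' method and sign restriction) on `n_perm` label-shuffled datasets and
#' pools every finite |dz| across permutations and pairs into one flat
#' reference distribution. Undefined pairs are omitted.
#'
#' @param expr Expression tibble or matrix.
#' @param design Design tibble/matrix.
#' @param compare The two condition names.
#' @param method,sign_type As in [ddcor()].
#' @param n_perm Number of permutations (>= 1); default 10, adequate for a
#'   pooled null shared across many pairs.
#' @param split_gene Optional gene id restricting pairs, as in [ddcor()].
#' @param seed Optional integer seed.
#' @return Numeric vector of pooled |dz| values with attributes `n_perm`
#'   and `n_pairs`.
#' @export
build_null_pool <- function(expr, design, compare,
                            method = c("pearson", "spearman"),
                            sign_type = c("all", "positive", "negative"),
                            n_perm = 10, split_gene = NULL, seed = NULL) {
  method <- match.arg(method)
  sign_type <- match.arg(sign_type)
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- as_expr_matrix(expr)
  check_compare(design, compare)
  pairs <- pair_index(rownames(m), split_gene)
  vals <- purrr::map(seq_len(n_perm), function(b) {
    pd <- permute_design(design, compare)
    cc <- condition_correlations(m, pd, compare, method = method)
    dz <- pair_dz_vec(extract_pairs(cc, pairs), method, sign_type)$dz
    abs(dz[is.finite(dz)])
  })
  structure(unlist(vals), n_perm = n_perm, n_pairs = nrow(pairs))
}

#' Empirical p-values against a pooled permutation null
#'
#' Ranks each observed statistic within the pooled null with an add-one
#' pseudocount: p = (1 + #\{pool >= observed\}) / (1 + pool size). The
#' pseudocount keeps p strictly positive, making the resolution limit of
#' the permutation scheme (1 / (pool size + 1)) explicit.
#'
#' @param observed Non-negative observed statistics (|dz|).
#' @param pool Pooled null values from [build_null_pool()].
#' @return Empirical p-values, monotone non-increasing in `observed`.
#' @examples
#' empirical_pvalues(3.5, c(1, 2, 3, 4, 5)) # (1 + 2) / 6
#' @export
empirical_pvalues <- function(observed, pool) {
  if (length(pool) == 0) abort("empty permutation pool")
  sp <- sort(pool)
  n_ge <- length(sp) - findInterval(observed, sp, left.open = TRUE)
  (1 + n_ge) / (1 + length(sp))
}

#' Estimate the proportion of true null hypotheses (pi0)
#'
#' Computes raw estimates pi0(lambda) = #\{p > lambda\} / (m * (1 - lambda))
#' over a grid of the tuning parameter lambda, smooths them with a cubic
#' smoothing spline, and takes the spline value at the largest lambda --
#' extrapolating the trend of the raw estimates towards lambda -> 1, where
#' only true nulls remain. The result is clamped to (0, 1] (lower bound
#' 1/m). With fewer p-values than grid points the estimate falls back to 1
#' with a warning.
#'
#' @param pvals Empirical p-values in `[0, 1]` (at least ~100 recommended).
#' @param lambda_grid Strictly increasing grid in `[0, 1)`; default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @param df Effective degrees of freedom of the smoothing spline
#'   (default 3).
#' @return A list with `lambda_grid`, `pi0_at_lambda` (raw estimates) and
#'   `pi0` (final, in (0, 1]).
#' @export
estimate_pi0 <- function(pvals, lambda_grid = seq(0.05, 0.95, by = 0.05), df = 3) {
  pvals <- pvals[!is.na(pvals)]
  m <- length(pvals)
  stopifnot(all(pvals >= 0 & pvals <= 1), all(diff(lambda_grid) > 0),
            all(lambda_grid >= 0 & lambda_grid < 1))
  raw <- vapply(lambda_grid, function(l) sum(pvals > l) / (m * (1 - l)), numeric(1))
  if (m < length(lambda_grid)) {
    warn("fewer p-values than lambda grid points; falling back to pi0 = 1")
    return(list(lambda_grid = lambda_grid, pi0_at_lambda = raw, pi0 = 1))
  }
  fit <- smooth.spline(lambda_grid, raw, df = df)
  pi0 <- predict(fit, x = max(lambda_grid))$y
  pi0 <- min(max(pi0, 1 / m), 1)
  list(lambda_grid = lambda_grid, pi0_at_lambda = raw, pi0 = pi0)
}

#' q-values from empirical p-values and pi0
#'
#' Step-up q-values: q_i = pi0 * min over \{j : p_j >= p_i\} of
#' (m * p_j / rank_j), capped at 1. Monotone in p; scaling pi0 rescales
#' every q.
#'
#' @param p_emp P-values in `[0, 1]`.
#' @param pi0 Proportion of true nulls in (0, 1]; default 1 (conservative).
#' @return q-values in `[0, 1]`, same order as `p_emp`.
#' @export
qvalues <- function(p_emp, pi0 = 1) {
  stopifnot(all(p_emp >= 0 & p_emp <= 1, na.rm = TRUE), pi0 > 0, pi0 <= 1)
  m <- length(p_emp)
  o <- order(p_emp, decreasing = TRUE)
  ro <- order(o)
  rk <- rank(p_emp, ties.method = "max")
  q <- pi0 * pmin(1, cummin(p_emp[o] * m / rk[o]))[ro]
  pmin(q, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as a named
#' surface so every adjustment in the package routes through one place.
#'
#' @param pvals P-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
bh_adjust <- function(pvals) {
  p.adjust(pvals, method = "BH")
}
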