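#' Pairwise correlation and complete-observation counts
#'
#' Computes the gene-by-gene correlation matrix on pairwise-complete
#' samples, together with the per-pair number of complete observations.
#' Pairs with fewer than 4 complete observations, or with zero variance in
#' either gene over the shared samples, are undefined (`NA`). Spearman uses
#' average ranks for ties.
#'
#' @param expr Expression tibble (gene column first) or matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with symmetric matrices `r` (coefficients), `nobs`
#'   (complete-observation counts) and `pval` (two-sided per-pair
#'   correlation p-values from [corr_pvalue()]).
#' @export
pairwise_correlations <- function(expr, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as_expr_matrix(expr)
  if (nrow(m) < 2) abort("need at least 2 genes")
  if (ncol(m) < 4) {
    warn("fewer than 4 samples: all pairwise correlations undefined")
  }
  obs <- !is.na(m)
  nobs <- obs %*% t(obs)
  r <- suppressWarnings(
    cor(t(m), use = "pairwise.complete.obs", method = method)
  )
  r[nobs < 4] <- NA_real_
  pval <- corr_pvalue(r, nobs)
  list(r = r, nobs = nobs, pval = pval)
}

#' Two-sided p-value for a correlation coefficient
#'
#' Tests the null of zero correlation using the approximation that
#' t = r * sqrt((n - 2) / (1 - r^2)) follows a t-distribution with n - 2
#' degrees of freedom. |r| = 1 is handled as the limit p = 0. Entries with
#' fewer than 4 complete observations are undefined.
#'
#' @param r Correlation coefficient(s); vector or matrix.
#' @param n Complete-observation count(s), recycled against `r`.
#' @return Two-sided p-value(s), same shape as `r`.
#' @examples
#' corr_pvalue(0.5, 22)
#' @export
corr_pvalue <- function(r, n) {
  p <- r # keep shape/dimnames
  ok <- !is.na(r) & !is.na(n) & n >= 4
  p[!ok] <- NA_real_
  rr <- r[ok]
  nn <- n[ok]
  tstat <- ifelse(abs(rr) >= 1, Inf, abs(rr) * sqrt((nn - 2) / (1 - rr^2)))
  p[ok] <- 2 * pt(tstat, df = nn - 2, lower.tail = FALSE)
  p
}

#' Per-condition pairwise correlations
#'
#' Splits samples by the two compared conditions and computes the
#' correlation, complete-observation count and per-condition significance
#' matrices within each.
#'
#' @param expr Expression tibble (gene column first) or matrix.
#' @param design Design tibble/matrix of 0/1 condition indicators.
#' @param compare Character vector of the two condition names, in order;
#'   results are returned in this order.
#' @param method `"pearson"` or `"spearman"`.
#' @return A named list (one element per compared condition, in `compare`
#'   order) of `pairwise_correlations()` results.
#' @export
condition_correlations <- function(expr, design, compare,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as_expr_matrix(expr)
  check_compare(design, compare)
  out <- purrr::map(compare, function(cond) {
    ids <- condition_samples(design, cond)
    missing <- setdiff(ids, colnames(m))
    if (length(missing) > 0) {
      abort(paste0("design sample(s) absent from expression matrix: ",
                   paste(missing, collapse = ", ")))
    }
    pairwise_correlations(m[, ids, drop = FALSE], method = method)
  })
  setNames(out, compare)
}
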