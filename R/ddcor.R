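# Pair index (i, j) rows over a gene vector: all unordered pairs, or all
# pairs involving split_gene.
pair_index <- function(genes, split_gene = NULL) {
  n <- length(genes)
  if (is.null(split_gene)) {
    idx <- which(upper.tri(matrix(0, n, n)))
    cbind(row = ((idx - 1) %% n) + 1, col = ((idx - 1) %/% n) + 1)
  } else {
    k <- match(split_gene, genes)
    if (is.na(k)) abort(paste0("split_gene '", split_gene, "' not found in expression matrix"))
    cbind(row = rep(k, n - 1), col = setdiff(seq_len(n), k))
  }
}

# Per-pair stats for one condition split; cc is a condition_correlations()
# result, pairs a 2-column index matrix.
extract_pairs <- function(cc, pairs) {
  list(
    r1 = cc[[1]]$r[pairs], n1 = cc[[1]]$nobs[pairs], p1 = cc[[1]]$pval[pairs],
    r2 = cc[[2]]$r[pairs], n2 = cc[[2]]$nobs[pairs], p2 = cc[[2]]$pval[pairs]
  )
}

# dz + p for extracted pair stats; undefined where either condition has
# nobs < 4 or an undefined coefficient.
pair_dz_vec <- function(st, method, sign_type) {
  ok <- !is.na(st$r1) & !is.na(st$r2) & st$n1 >= 4 & st$n2 >= 4
  dz <- rep(NA_real_, length(st$r1))
  p <- rep(NA_real_, length(st$r1))
  if (any(ok)) {
    res <- suppressWarnings(pair_diff_z(
      st$r1[ok], st$n1[ok], st$r2[ok], st$n2[ok],
      method = method, sign_type = sign_type
    ))
    dz[ok] <- res$dz
    p[ok] <- res$p
  }
  list(dz = dz, p = p)
}

#' Differential correlation analysis of all gene pairs between two conditions
#'
#' The core pipeline: per-condition pairwise correlations (with
#' pairwise-complete observation counts), Fisher z-transformation, the
#' standardized difference-in-z statistic per pair, 9-class categorization,
#' and multiple-testing adjustment. Positive `dz` means a gain of
#' correlation in the second condition of `compare` relative to the first.
#'
#' With `adjust = "perm"` (the default), sample labels are shuffled across
#' the two compared conditions `n_perm` times, the whole pipeline is rerun
#' on each shuffle, and all permuted |dz| values are pooled into one
#' empirical null against which every observed pair is ranked
#' ([empirical_pvalues()]); q-values then combine the empirical p-values
#' with a spline-based estimate of the proportion of true nulls
#' ([estimate_pi0()], [qvalues()]). Because the null is pooled across
#' pairs, a handful of permutations suffices when many pairs are tested.
#'
#' @param expr Expression tibble (gene id column first, one numeric column
#'   per sample) or matrix with gene rownames.
#' @param design Design tibble/matrix of 0/1 condition indicators (see
#'   [design_from_labels()]).
#' @param compare Character vector of the two condition names to compare,
#'   in order; each needs at least 4 samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha Per-condition significance level used for the class labels
#'   (default 0.05). Per-condition p-values are not multiplicity-adjusted.
#' @param sign_type `"all"`, `"positive"` or `"negative"`; see
#'   [pair_diff_z()]. Class labels always use the unclamped coefficients.
#' @param adjust `"perm"` (permutation q-values, default), `"bh"`
#'   (Benjamini-Hochberg on the normal p-values) or `"none"`.
#' @param n_perm Number of label permutations when `adjust = "perm"`
#'   (default 10, suitable for the pooled null).
#' @param split_gene Optional gene id: evaluate only pairs containing this
#'   gene (one-vs-all analysis).
#' @param sig_threshold Reporting threshold applied to the q-value (or to
#'   the p-value when `adjust = "none"`); non-significant pairs keep their
#'   class in the `class` column but are flagged `sig = FALSE` and written
#'   out as `"NonSig"` by [write_ddcor()]. Default 0.05.
#' @param seed Optional integer seed making the permutation null
#'   reproducible.
#' @return A tibble of class `"tbl_ddcor"`, one row per gene pair, sorted
#'   by |dz| descending (ties broken lexicographically by gene ids):
#'   columns `gene_a`, `gene_b`, `r1`, `p1`, `r2`, `p2`, `z1`, `z2`, `dz`,
#'   `p_diff`, `p_emp` and `q` (when computed), `class`, `sig`. Attributes
#'   record `compare`, `method`, `sign_type`, `alpha`, `adjust`, `n_perm`
#'   and the estimated `pi0`.
#' @seealso [write_ddcor()], [glance.tbl_ddcor()], [autoplot.tbl_ddcor()],
#'   [median_dz_test()]
#' @examples
#' sim <- simulate_pair_benchmark(n_samples = 20, seed = 1, n_genes = c(30, 10, 20))
#' res <- ddcor(sim$expression, sim$design, c("A", "B"), n_perm = 3, seed = 1)
#' head(res)
#' @export
ddcor <- function(expr, design, compare,
                  method = c("pearson", "spearman"),
                  alpha = 0.05,
                  sign_type = c("all", "positive", "negative"),
                  adjust = c("perm", "bh", "none"),
                  n_perm = 10,
                  split_gene = NULL,
                  sig_threshold = 0.05,
                  seed = NULL) {
  method <- match.arg(method)
  sign_type <- match.arg(sign_type)
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1)
  m <- as_expr_matrix(expr)
  check_compare(design, compare)
  pairs <- pair_index(rownames(m), split_gene)

  cc <- condition_correlations(m, design, compare, method = method)
  st <- extract_pairs(cc, pairs)
  dzp <- pair_dz_vec(st, method, sign_type)

  out <- tibble::tibble(
    gene_a = rownames(m)[pairs[, 1]],
    gene_b = rownames(m)[pairs[, 2]],
    r1 = st$r1, p1 = st$p1, r2 = st$r2, p2 = st$p2,
    z1 = suppressWarnings(fisher_z(st$r1)),
    z2 = suppressWarnings(fisher_z(st$r2)),
    dz = dzp$dz, p_diff = dzp$p,
    class = classify_pair(st$r1, st$p1, st$r2, st$p2, alpha)
  )

  pi0 <- NA_real_
  if (adjust == "bh") {
    out$q <- bh_adjust(out$p_diff)
  } else if (adjust == "perm") {
    if (!is.null(seed)) set.seed(seed)
    pool <- build_null_pool(m, design, compare,
      method = method, sign_type = sign_type,
      n_perm = n_perm, split_gene = split_gene
    )
    out$p_emp <- rep(NA_real_, nrow(out))
    ok <- !is.na(out$dz)
    out$p_emp[ok] <- empirical_pvalues(abs(out$dz[ok]), pool)
    pi0 <- estimate_pi0(out$p_emp[ok])$pi0
    out$q <- rep(NA_real_, nrow(out))
    out$q[ok] <- qvalues(out$p_emp[ok], pi0)
  }

  crit <- if (adjust == "none") out$p_diff else out$q
  out$sig <- !is.na(crit) & crit < sig_threshold
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$dz)), .data$gene_a, .data$gene_b)

  structure(out,
    class = c("tbl_ddcor", class(out)),
    compare = compare, method = method, sign_type = sign_type,
    alpha = alpha, adjust = adjust,
    n_perm = if (adjust == "perm") n_perm else NA_integer_,
    pi0 = pi0, sig_threshold = sig_threshold
  )
}

#' Write a differential correlation table to TSV
#'
#' Columns, in order: GeneA, GeneB, Cor1, pVal1, Cor2, pVal2, zScoreDiff,
#' pValDiff, then empPVal and qValue when present, then Classes. Pairs
#' below the reporting threshold carry their class label; the rest are
#' written as `"NonSig"`.
#'
#' @param x A `tbl_ddcor` from [ddcor()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ddcor <- function(x, path) {
  stopifnot(inherits(x, "tbl_ddcor"))
  out <- tibble::tibble(
    GeneA = x$gene_a, GeneB = x$gene_b,
    Cor1 = x$r1, pVal1 = x$p1, Cor2 = x$r2, pVal2 = x$p2,
    zScoreDiff = x$dz, pValDiff = x$p_diff
  )
  if (!is.null(x$p_emp)) out$empPVal <- x$p_emp
  if (!is.null(x$q)) out$qValue <- x$q
  out$Classes <- ifelse(x$sig, x$class, "NonSig")
  readr::write_tsv(out, path)
  invisible(path)
}
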