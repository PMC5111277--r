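#' Matrix of difference-in-z statistics for all gene pairs
#'
#' Convenience engine behind the aggregate tests: computes the symmetric
#' matrix of dz statistics (second condition minus first, see
#' [pair_diff_z()]) for every gene pair. The diagonal is `NA`.
#'
#' @inheritParams ddcor
#' @return Symmetric numeric matrix of dz values with gene dimnames.
#' @export
dz_matrix <- function(expr, design, compare,
                      method = c("pearson", "spearman"),
                      sign_type = c("all", "positive", "negative")) {
  method <- match.arg(method)
  sign_type <- match.arg(sign_type)
  m <- as_expr_matrix(expr)
  cc <- condition_correlations(m, design, compare, method = method)
  pairs <- pair_index(rownames(m))
  dz <- pair_dz_vec(extract_pairs(cc, pairs), method, sign_type)$dz
  out <- matrix(NA_real_, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  out[pairs] <- dz
  out[pairs[, 2:1, drop = FALSE]] <- dz
  out
}

#' Median difference-in-z of one gene against the others
#'
#' The median of the finite dz values between `gene` and every other gene
#' in the matrix. A median above 0 indicates a tendency towards a gain of
#' correlation between the gene and the set in the second compared
#' condition; below 0, a loss.
#'
#' @param dz Symmetric dz matrix (see [dz_matrix()]).
#' @param gene Gene id (must be a row of `dz`).
#' @return Median dz (NA if all pair values are undefined).
#' @export
median_dz_by_gene <- function(dz, gene) {
  stopifnot(nrow(dz) >= 2)
  if (!gene %in% rownames(dz)) abort(paste0("gene '", gene, "' not in dz matrix"))
  vals <- dz[gene, setdiff(colnames(dz), gene)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(NA_real_)
  median(vals)
}

#' Median difference-in-z over all gene pairs
#'
#' @param dz Symmetric dz matrix (see [dz_matrix()]).
#' @return Median of the finite dz values over all unordered pairs.
#' @export
global_median_dz <- function(dz) {
  stopifnot(nrow(dz) >= 2)
  vals <- dz[upper.tri(dz)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(NA_real_)
  median(vals)
}

#' Two-sided empirical p-value for an aggregate median statistic
#'
#' Counts how often the magnitude of a permutation median meets or exceeds
#' the observed magnitude: p = #\{|median_perm| >= |median_obs|\} / n.
#' Unlike the pooled pair-level null, this is a non-pooled test -- each
#' statistic is compared only against its own permutation replicates -- so
#' the number of permutations sets a hard floor of 1/n on resolvable
#' p-values, and a reported 0 means p < 1/n.
#'
#' @param observed_median Observed median dz.
#' @param permuted_medians One median per permutation (length >= 1).
#' @return Empirical two-sided p-value in `[0, 1]`.
#' @examples
#' aggregate_empirical_p(0.5, c(0.1, 0.2, 0.3, 0.4)) # 0
#' @export
aggregate_empirical_p <- function(observed_median, permuted_medians) {
  if (length(permuted_medians) == 0) abort("empty permutation set")
  mean(abs(permuted_medians) >= abs(observed_median))
}

#' Aggregate median difference-in-z test
#'
#' Tests whether each gene's median change in z-transformed correlation
#' with all other genes in the set -- and the global median over all pairs
#' -- is more extreme than expected under label permutation. Per-gene
#' empirical p-values are BH-adjusted across genes. This is the non-pooled
#' counterpart to the pair-level permutation FDR: with the dimensionality
#' reduced to one statistic per gene, each statistic gets its own
#' permutation distribution, so on the order of 1,000 permutations are
#' needed (default) rather than the ~10 of the pooled scheme.
#'
#' @inheritParams ddcor
#' @param genes Optional character vector restricting the analysis to a
#'   gene set (default: all genes in `expr`).
#' @param n_perm Number of label permutations (default 1000).
#' @return An object of class `"dgc_median_dz"`: a list with `by_gene`
#'   (tibble: `gene`, `median_dz`, `p_emp`, `p_adj`), `global` (one-row
#'   tibble: `median_dz`, `p_emp`), `n_perm`, `compare`, `method`. A
#'   `p_emp` of 0 means below the 1/`n_perm` resolution. [tidy()] returns
#'   the per-gene table, [glance()] the global row.
#' @examples
#' sim <- simulate_pair_benchmark(n_samples = 20, seed = 1, n_genes = c(30, 10, 20))
#' agg <- median_dz_test(sim$expression, sim$design, c("A", "B"),
#'   genes = paste0("g", sprintf("%03d", 1:10)), n_perm = 50, seed = 1
#' )
#' glance(agg)
#' @export
median_dz_test <- function(expr, design, compare,
                           method = c("pearson", "spearman"),
                           sign_type = c("all", "positive", "negative"),
                           genes = NULL, n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  sign_type <- match.arg(sign_type)
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- as_expr_matrix(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing) > 0) {
      abort(paste0("gene(s) not in expression matrix: ", paste(missing, collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("need at least 2 genes")

  gene_medians <- function(dz) {
    diag(dz) <- NA_real_
    apply(dz, 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v) == 0) NA_real_ else median(v)
    })
  }

  dz_obs <- dz_matrix(m, design, compare, method = method, sign_type = sign_type)
  obs_gene <- gene_medians(dz_obs)
  obs_global <- global_median_dz(dz_obs)

  perm_gene <- matrix(NA_real_, n_perm, nrow(m))
  perm_global <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pd <- permute_design(design, compare)
    dz_b <- dz_matrix(m, pd, compare, method = method, sign_type = sign_type)
    perm_gene[b, ] <- gene_medians(dz_b)
    perm_global[b] <- global_median_dz(dz_b)
  }

  p_gene <- vapply(seq_len(nrow(m)), function(i) {
    aggregate_empirical_p(obs_gene[i], perm_gene[, i][is.finite(perm_gene[, i])])
  }, numeric(1))

  by_gene <- tibble::tibble(
    gene = rownames(m),
    median_dz = unname(obs_gene),
    p_emp = p_gene,
    p_adj = bh_adjust(p_gene)
  )
  by_gene <- dplyr::arrange(by_gene, .data$p_emp, dplyr::desc(abs(.data$median_dz)))

  structure(
    list(
      by_gene = by_gene,
      global = tibble::tibble(
        median_dz = obs_global,
        p_emp = aggregate_empirical_p(obs_global, perm_global[is.finite(perm_global)])
      ),
      n_perm = n_perm, compare = compare, method = method, sign_type = sign_type
    ),
    class = "dgc_median_dz"
  )
}

#' Write an aggregate median-dz table to TSV
#'
#' Columns: Gene, MedianZScoreDifference, EmpiricalPValue, AdjustedPValue.
#'
#' @param x A `"dgc_median_dz"` object from [median_dz_test()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_median_dz <- function(x, path) {
  stopifnot(inherits(x, "dgc_median_dz"))
  out <- tibble::tibble(
    Gene = x$by_gene$gene,
    MedianZScoreDifference = x$by_gene$median_dz,
    EmpiricalPValue = x$by_gene$p_emp,
    AdjustedPValue = x$by_gene$p_adj
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @export
print.dgc_median_dz <- function(x, ...) {
  cat("Aggregate median difference-in-z test (", x$compare[1], " vs ",
      x$compare[2], ", ", x$method, ", ", x$n_perm, " permutations)\n", sep = "")
  cat("Global median dz = ", signif(x$global$median_dz, 3),
      ", empirical p = ", format_perm_p(x$global$p_emp, x$n_perm), "\n\n", sep = "")
  print(x$by_gene, ...)
  invisible(x)
}

# p of 0 at n permutations means "below resolution"; print it that way.
format_perm_p <- function(p, n_perm) {
  ifelse(p == 0, paste0("< ", format(1 / n_perm, scientific = TRUE)), format(p))
}
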