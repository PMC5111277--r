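# Internal coercions between the user-facing tibble representation
# (gene id column + one column per sample) and the numeric matrix the
# engines work on (genes x samples with dimnames).

as_expr_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("expression matrix must have gene ids as rownames")
    if (is.null(colnames(x))) abort("expression matrix must have sample ids as colnames")
    storage.mode(x) <- "double"
    check_expr_ids(rownames(x), colnames(x))
    return(x)
  }
  if (!is.data.frame(x)) abort("expression input must be a data frame or matrix")
  if (ncol(x) < 2) abort("expression data frame needs a gene id column plus sample columns")
  genes <- as.character(x[[1]])
  body <- x[-1]
  bad <- names(body)[!vapply(body, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric expression column(s): ", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(body)
  rownames(m) <- genes
  storage.mode(m) <- "double"
  check_expr_ids(genes, colnames(m))
  m
}

check_expr_ids <- function(genes, samples) {
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(paste0("duplicate gene id(s): ", paste(dup, collapse = ", ")))
  }
  dup <- unique(samples[duplicated(samples)])
  if (length(dup) > 0) {
    abort(paste0("duplicate sample id(s): ", paste(dup, collapse = ", ")))
  }
  invisible(NULL)
}

expr_as_tibble <- function(m, gene_col = "gene") {
  out <- tibble::as_tibble(m, rownames = gene_col)
  out
}

# Design tibble: `sample` column + 0/1 indicator column per condition.
as_design_matrix <- function(design) {
  if (is.matrix(design)) {
    if (is.null(rownames(design))) abort("design matrix must have sample ids as rownames")
    m <- design
  } else {
    if (!is.data.frame(design)) abort("design must be a data frame or matrix")
    m <- as.matrix(design[-1])
    rownames(m) <- as.character(design[[1]])
  }
  storage.mode(m) <- "double"
  if (!all(m %in% c(0, 1))) abort("design indicators must be 0/1")
  m
}

condition_samples <- function(design, condition) {
  m <- as_design_matrix(design)
  if (!condition %in% colnames(m)) {
    abort(paste0("condition '", condition, "' not found in design"))
  }
  rownames(m)[m[, condition] == 1]
}

check_compare <- function(design, compare) {
  if (length(compare) != 2) abort("`compare` must name exactly two conditions")
  m <- as_design_matrix(design)
  missing <- setdiff(compare, colnames(m))
  if (length(missing) > 0) {
    abort(paste0("condition(s) not in design: ", paste(missing, collapse = ", ")))
  }
  both <- rowSums(m[, compare, drop = FALSE]) > 1
  if (any(both)) {
    abort(paste0("sample(s) assigned to both compared conditions: ",
                 paste(rownames(m)[both], collapse = ", ")))
  }
  ns <- colSums(m[, compare, drop = FALSE])
  if (any(ns < 4)) {
    abort("each compared condition requires at least 4 samples in each condition")
  }
  invisible(NULL)
}

#' Number of gene-pair hypothesis tests for a given gene count
#'
#' All-pairs differential correlation performs one test per unordered gene
#' pair, so the test count grows quadratically: choose(n, 2). For example
#' 20,000 genes imply 199,990,000 tests, which motivates permutation-based
#' empirical false discovery rates over per-test parametric corrections.
#'
#' @param n_genes Number of genes (integer >= 2).
#' @return Number of unordered gene pairs, as a double to avoid integer
#'   overflow at genome scale.
#' @examples
#' n_pair_tests(600)
#' @export
n_pair_tests <- function(n_genes) {
  stopifnot(n_genes >= 2)
  n_genes * (n_genes - 1) / 2
}
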