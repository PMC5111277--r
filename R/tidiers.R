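#' Glance at a differential correlation table
#'
#' One-row summary of a [ddcor()] result: pair counts, significant-pair
#' count at the reporting threshold, class tally of the significant pairs,
#' and the estimated proportion of true nulls when permutation adjustment
#' was used.
#'
#' @param x A `tbl_ddcor`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance tbl_ddcor
#' @export
glance.tbl_ddcor <- function(x, ...) {
  tibble::tibble(
    condition_1 = attr(x, "compare")[1],
    condition_2 = attr(x, "compare")[2],
    method = attr(x, "method"),
    sign_type = attr(x, "sign_type"),
    adjust = attr(x, "adjust"),
    n_perm = attr(x, "n_perm"),
    n_pairs = nrow(x),
    n_undefined = sum(is.na(x$dz)),
    n_sig = sum(x$sig),
    n_gain = sum(x$sig & x$dz > 0, na.rm = TRUE),
    n_loss = sum(x$sig & x$dz < 0, na.rm = TRUE),
    pi0 = attr(x, "pi0")
  )
}

#' Tidy a differential correlation table
#'
#' A `tbl_ddcor` is already tidy (one row per gene pair); this strips the
#' subclass and attributes so downstream code sees a plain tibble.
#'
#' @param x A `tbl_ddcor`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tbl_ddcor
#' @export
tidy.tbl_ddcor <- function(x, ...) {
  tibble::as_tibble(unclass_ddcor(x))
}

unclass_ddcor <- function(x) {
  attr(x, "compare") <- NULL
  attr(x, "method") <- NULL
  attr(x, "sign_type") <- NULL
  attr(x, "alpha") <- NULL
  attr(x, "adjust") <- NULL
  attr(x, "n_perm") <- NULL
  attr(x, "pi0") <- NULL
  attr(x, "sig_threshold") <- NULL
  class(x) <- setdiff(class(x), "tbl_ddcor")
  x
}

#' Tidy an aggregate median-dz result
#'
#' @param x A `"dgc_median_dz"` object from [median_dz_test()].
#' @param ... Unused.
#' @return The per-gene tibble: `gene`, `median_dz`, `p_emp`, `p_adj`.
#' @method tidy dgc_median_dz
#' @export
tidy.dgc_median_dz <- function(x, ...) {
  x$by_gene
}

#' Glance at an aggregate median-dz result
#'
#' @param x A `"dgc_median_dz"` object.
#' @param ... Unused.
#' @return One-row tibble with the global median dz, its empirical p-value,
#'   the permutation count and the comparison.
#' @method glance dgc_median_dz
#' @export
glance.dgc_median_dz <- function(x, ...) {
  tibble::tibble(
    condition_1 = x$compare[1],
    condition_2 = x$compare[2],
    method = x$method,
    n_perm = x$n_perm,
    n_genes = nrow(x$by_gene),
    global_median_dz = x$global$median_dz,
    global_p_emp = x$global$p_emp
  )
}
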