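#' Volcano-style plot of a differential correlation table
#'
#' dz against -log10 of the working p-value (empirical when available,
#' otherwise the normal p-value), colored by correlation class, with
#' non-significant pairs greyed out.
#'
#' @param object A `tbl_ddcor` from [ddcor()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tbl_ddcor
#' @export
autoplot.tbl_ddcor <- function(object, ...) {
  p <- if (!is.null(object$p_emp)) object$p_emp else object$p_diff
  df <- tibble::tibble(
    dz = object$dz,
    neglogp = -log10(p),
    class = ifelse(object$sig, object$class, "NonSig")
  )
  df <- df[!is.na(df$dz), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dz, y = .data$neglogp, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(NonSig = "grey70"),
      na.value = "grey40",
      breaks = unique(df$class)
    ) +
    ggplot2::labs(
      x = sprintf("difference in z-score (%s minus %s)",
                  attr(object, "compare")[2], attr(object, "compare")[1]),
      y = expression(-log[10](p)),
      colour = "class"
    ) +
    ggplot2::theme_minimal()
}

#' Plot one gene pair's expression in each condition
#'
#' Scatter of the two genes' expression with a per-condition linear fit --
#' the visual check behind any single differential-correlation call.
#'
#' @param expr Expression tibble or matrix.
#' @param design Design tibble/matrix.
#' @param compare The two condition names.
#' @param gene_a,gene_b Gene ids to plot (`gene_a` on the x-axis).
#' @return A ggplot object.
#' @export
plot_pair_cors <- function(expr, design, compare, gene_a, gene_b) {
  m <- as_expr_matrix(expr)
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(m)) abort(paste0("gene '", g, "' not in expression matrix"))
  }
  check_compare(design, compare)
  dfs <- purrr::map(compare, function(cond) {
    ids <- intersect(condition_samples(design, cond), colnames(m))
    tibble::tibble(x = m[gene_a, ids], y = m[gene_b, ids], condition = cond)
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$condition)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE, linewidth = 0.6) +
    ggplot2::labs(x = gene_a, y = gene_b, colour = "condition") +
    ggplot2::theme_minimal()
}

#' Lollipop plot of per-gene median difference-in-z
#'
#' @param object A `"dgc_median_dz"` object from [median_dz_test()].
#' @param top Show at most this many genes, ranked by |median dz|
#'   (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dgc_median_dz
#' @export
autoplot.dgc_median_dz <- function(object, top = 30, ...) {
  df <- dplyr::slice_max(object$by_gene, abs(.data$median_dz), n = top)
  df$gene <- stats::reorder(df$gene, df$median_dz)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_dz, y = .data$gene)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$median_dz, yend = .data$gene),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_adj < 0.05)) +
    ggplot2::labs(
      x = sprintf("median difference in z-score (%s minus %s)",
                  object$compare[2], object$compare[1]),
      y = NULL, colour = "adj. p < 0.05"
    ) +
    ggplot2::theme_minimal()
}
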