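#' Filter out low-information genes before correlation analysis
#'
#' Genes with a low expression central tendency and/or low dispersion are
#' prone to spurious correlations, so they can be removed before pair-level
#' testing. A gene is dropped when its central-tendency measure falls
#' strictly below the `central_pct` quantile of that measure across genes,
#' or (union semantics, the default) when its dispersion measure falls
#' strictly below the `dispersion_pct` quantile. Quantiles use linear
#' interpolation between order statistics; genes sitting exactly at the
#' cutoff survive. Summary statistics skip missing entries, and gene order
#' is preserved.
#'
#' Because percentile cutoffs are recomputed from whatever matrix they are
#' given, re-running a percentile filter on its own output removes another
#' slice. The realized absolute cutoffs are therefore attached to the
#' result (attribute `"cutoffs"`) and can be passed back via
#' `central_cutoff` / `dispersion_cutoff`, which makes repeated application
#' a no-op.
#'
#' @param expr Expression tibble (gene column first) or matrix.
#' @param central_measure `"median"` (default) or `"mean"`.
#' @param central_pct Fraction in `[0, 1)`; quantile of the central measure
#'   below which genes are removed. 0 disables the filter.
#' @param dispersion_measure `"dispersion_index"` (variance divided by mean;
#'   default) or `"sd"`.
#' @param dispersion_pct Fraction in `[0, 1)` for the dispersion filter.
#' @param combine `"union"` (remove genes failing either filter; default) or
#'   `"intersection"` (remove only genes failing both).
#' @param central_cutoff,dispersion_cutoff Optional absolute cutoffs that
#'   override the percentile computation (genes strictly below are
#'   removed).
#' @return Filtered expression object of the same type, with a `"cutoffs"`
#'   attribute holding the realized absolute cutoffs.
#' @details A gene with non-positive mean has no well-defined dispersion
#'   index; such genes are removed with a warning when the dispersion
#'   filter is active with `dispersion_measure = "dispersion_index"`.
#' @examples
#' expr <- simulate_pair_benchmark(n_samples = 10, seed = 1)$expression
#' nrow(filter_genes(expr, central_pct = 0.25, dispersion_pct = 0.25))
#' @export
filter_genes <- function(expr,
                         central_measure = c("median", "mean"),
                         central_pct = 0,
                         dispersion_measure = c("dispersion_index", "sd"),
                         dispersion_pct = 0,
                         combine = c("union", "intersection"),
                         central_cutoff = NULL,
                         dispersion_cutoff = NULL) {
  central_measure <- match.arg(central_measure)
  dispersion_measure <- match.arg(dispersion_measure)
  combine <- match.arg(combine)
  stopifnot(central_pct >= 0, central_pct < 1,
            dispersion_pct >= 0, dispersion_pct < 1)
  m <- as_expr_matrix(expr)

  central <- switch(central_measure,
    median = apply(m, 1, median, na.rm = TRUE),
    mean = rowMeans(m, na.rm = TRUE)
  )
  mu <- rowMeans(m, na.rm = TRUE)
  v <- apply(m, 1, var, na.rm = TRUE)
  bad_mu <- rep(FALSE, nrow(m))
  disp <- switch(dispersion_measure,
    dispersion_index = {
      bad_mu <- !is.na(mu) & mu <= 0
      ifelse(bad_mu, NA_real_, v / mu)
    },
    sd = sqrt(v)
  )

  use_central <- !is.null(central_cutoff) || central_pct > 0
  use_disp <- !is.null(dispersion_cutoff) || dispersion_pct > 0
  if (use_central && is.null(central_cutoff)) {
    central_cutoff <- quantile(central, central_pct, na.rm = TRUE, names = FALSE)
  }
  if (use_disp && is.null(dispersion_cutoff)) {
    dispersion_cutoff <- quantile(disp, dispersion_pct, na.rm = TRUE, names = FALSE)
  }

  fail_central <- if (use_central) central < central_cutoff else rep(FALSE, nrow(m))
  fail_disp <- if (use_disp) {
    out <- disp < dispersion_cutoff
    out[is.na(out)] <- FALSE
    if (any(bad_mu)) {
      warn(paste0("removing gene(s) with non-positive mean (dispersion index undefined): ",
                  paste(rownames(m)[bad_mu], collapse = ", ")))
      out | bad_mu
    } else out
  } else rep(FALSE, nrow(m))

  drop <- switch(combine,
    union = fail_central | fail_disp,
    intersection = fail_central & fail_disp
  )
  if (all(drop)) abort("filter removed all genes")
  out <- if (is.matrix(expr)) {
    expr[!drop, , drop = FALSE]
  } else {
    expr[!drop, , drop = FALSE]
  }
  attr(out, "cutoffs") <- c(
    central = if (use_central) central_cutoff else NA_real_,
    dispersion = if (use_disp) dispersion_cutoff else NA_real_
  )
  out
}
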