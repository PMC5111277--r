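#' Area under the ROC curve of a pair ranking
#'
#' AUC computed as the Mann-Whitney concordance between the scores of the
#' positive and negative classes; tied scores count one half. Equivalent to
#' integrating the ROC curve of the ranking.
#'
#' @param scores Numeric ranking values (higher = more likely positive);
#'   pairs with `NA` scores are dropped with a warning.
#' @param truth Logical (or 0/1) ground-truth labels, same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(3, 2, 1), c(TRUE, FALSE, FALSE)) # 1
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.logical(truth)
  keep <- !is.na(scores) & !is.na(truth)
  if (any(!keep)) {
    warn(paste0("dropping ", sum(!keep), " pair(s) with undefined score or label"))
    scores <- scores[keep]
    truth <- truth[keep]
  }
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) abort("need at least one positive and one negative label")
  r <- rank(scores) # average ranks: ties count 1/2
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' End-to-end detection accuracy on the pair-level benchmark
#'
#' Simulates the structured-covariance benchmark at a given sample size,
#' runs the full differential-correlation pipeline, ranks all gene pairs by
#' |dz|, and scores the ranking against the planted truth with
#' [roc_auc()]. Positives are the truly differential designated pairs;
#' everything else (including the planted-but-equal `"+/+"` and `"-/-"`
#' pairs) is negative.
#'
#' @inheritParams simulate_pair_benchmark
#' @param method Correlation method passed to [ddcor()].
#' @return AUC in `[0, 1]`.
#' @export
pair_benchmark_auc <- function(n_samples, seed = NULL,
                               method = c("pearson", "spearman"), ...) {
  method <- match.arg(method)
  sim <- simulate_pair_benchmark(n_samples, seed = seed, ...)
  res <- ddcor(sim$expression, sim$design, c("A", "B"),
               method = method, adjust = "none")
  pos <- with(sim$truth[sim$truth$is_differential, ], paste(gene_a, gene_b))
  labels <- paste(res$gene_a, res$gene_b) %in% pos
  roc_auc(abs(res$dz), labels)
}

#' Recovery metrics for detected modules against a true module
#'
#' Scores any module-detection output: sensitivity is the best
#' |detected n true| / |true| over detected modules smaller than
#' `max_size_for_sensitivity`; the Jaccard index is the best
#' |intersection| / |union| over all detected modules. When nothing is
#' detected, a pseudo-module of the whole universe is scored instead, which
#' fixes a floor Jaccard of |true| / |universe| (0.05 for a 30-gene module
#' in 600 genes).
#'
#' @param detected_modules List of character vectors of gene ids (possibly
#'   empty).
#' @param true_module Non-empty character vector.
#' @param universe All gene ids in the experiment (used for the
#'   pseudo-module fallback).
#' @param max_size_for_sensitivity Size cap on modules eligible for the
#'   sensitivity statistic (default 50).
#' @return A list with `sensitivity` and `jaccard`.
#' @examples
#' module_recovery_metrics(list(), paste0("g", 1:30), paste0("g", 1:600))
#' @export
module_recovery_metrics <- function(detected_modules, true_module, universe,
                                    max_size_for_sensitivity = 50) {
  if (length(true_module) == 0) abort("true module is empty")
  if (length(detected_modules) == 0) detected_modules <- list(universe)
  sens <- purrr::map_dbl(detected_modules, function(mod) {
    if (length(mod) >= max_size_for_sensitivity) return(NA_real_)
    length(intersect(mod, true_module)) / length(true_module)
  })
  jac <- purrr::map_dbl(detected_modules, function(mod) {
    length(intersect(mod, true_module)) / length(union(mod, true_module))
  })
  list(
    sensitivity = if (all(is.na(sens))) 0 else max(sens, na.rm = TRUE),
    jaccard = max(jac)
  )
}
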