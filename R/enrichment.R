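# 2x2 contingency counts for a signature against a gene set within a
# universe: n11 = |sig & set|, n12 = |set \ sig|, n21 = |sig \ set|,
# n22 = rest of the universe.
contingency_counts <- function(signature, set, universe) {
  set <- intersect(set, universe)
  signature <- intersect(signature, universe)
  n11 <- length(intersect(signature, set))
  n12 <- length(set) - n11
  n21 <- length(signature) - n11
  n22 <- length(universe) - n11 - n12 - n21
  c(n11 = n11, n12 = n12, n21 = n21, n22 = n22)
}

#' Log odds ratio of a 2x2 contingency table
#'
#' Natural-log odds ratio log((n11 * n22) / (n12 * n21)). Log odds ratios
#' converge to normality faster than raw odds ratios, which is why the
#' two-signature comparison works on the log scale. If any cell is zero,
#' the Haldane-Anscombe correction adds 0.5 to all four cells so the
#' estimate stays finite.
#'
#' @param counts Numeric vector of length 4: n11, n12, n21, n22
#'   (signature-and-set, set only, signature only, neither).
#' @return Log odds ratio.
#' @examples
#' log_odds_ratio(c(20, 10, 10, 20)) # log(4)
#' @export
log_odds_ratio <- function(counts) {
  counts <- haldane(counts)
  log((counts[[1]] * counts[[4]]) / (counts[[2]] * counts[[3]]))
}

#' Standard error of a log odds ratio
#'
#' sqrt(1/n11 + 1/n12 + 1/n21 + 1/n22), with the same +0.5 zero-cell
#' correction as [log_odds_ratio()].
#'
#' @inheritParams log_odds_ratio
#' @return Standard error of the log OR.
#' @examples
#' log_or_se(c(25, 25, 25, 25)) # 0.4
#' @export
log_or_se <- function(counts) {
  counts <- haldane(counts)
  sqrt(sum(1 / counts))
}

haldane <- function(counts) {
  stopifnot(length(counts) == 4, all(counts >= 0))
  if (any(counts == 0)) counts + 0.5 else counts
}

#' Compare two log odds ratios
#'
#' z = (logOR1 - logOR2) / sqrt(se1^2 + se2^2), treating the two
#' enrichments as independent estimates, with a two-sided normal p-value.
#' Swapping the signatures negates z and leaves p unchanged.
#'
#' @param or1,or2 Log odds ratios of the two signatures.
#' @param se1,se2 Their standard errors (> 0).
#' @return A list with `z` and `p`.
#' @examples
#' compare_log_or(1, 0.5, 0, 0.5)
#' @export
compare_log_or <- function(or1, se1, or2, se2) {
  stopifnot(all(se1 > 0), all(se2 > 0))
  z <- (or1 - or2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Compare gene-set enrichment between two signatures
#'
#' For each gene set (size within `[min_size, max_size]` after intersecting
#' with the universe), computes both signatures' one-sided hypergeometric
#' enrichment p-values and log odds ratios, keeps sets nominally enriched
#' (p < `p_filter`) in at least one signature, tests the difference of log
#' ORs with [compare_log_or()], and BH-adjusts the difference p-values
#' within each set category. Typical use: the two signatures are the genes
#' uniquely found in gain-of-correlation pairs of each condition.
#'
#' @param sig1,sig2 Character vectors of gene ids (subsets of `universe`).
#' @param sets Named list of gene sets (see [read_gmt()]); an optional
#'   `category` attribute groups the BH adjustment (e.g. BP/CC/MF).
#' @param universe Character vector of all candidate genes (e.g. every gene
#'   surviving the expression filter).
#' @param min_size,max_size Retained set-size range (defaults 50 and 600).
#' @param p_filter Nominal enrichment p-value required in at least one
#'   signature (default 0.05); set to 1 to keep all sets.
#' @return A tibble, one row per retained set: `set`, `category`, `n1`,
#'   `log_or_1`, `se_1`, `p_enrich_1`, and the `_2` counterparts, `z`, `p`,
#'   `fdr`; sorted by `p`.
#' @export
compare_signatures <- function(sig1, sig2, sets, universe,
                               min_size = 50, max_size = 600,
                               p_filter = 0.05) {
  if (length(universe) == 0) abort("empty universe")
  out1 <- setdiff(sig1, universe)
  out2 <- setdiff(sig2, universe)
  if (length(out1) > 0 || length(out2) > 0) {
    abort("signature gene(s) outside the universe")
  }
  category <- attr(sets, "category") %||% setNames(rep(NA_character_, length(sets)), names(sets))

  rows <- purrr::imap(sets, function(members, nm) {
    members <- intersect(members, universe)
    if (length(members) < min_size || length(members) > max_size) return(NULL)
    enr <- function(sig) {
      ct <- contingency_counts(sig, members, universe)
      # one-sided hypergeometric upper tail: P(X >= n11)
      p_hyper <- phyper(ct[["n11"]] - 1, length(members),
                        length(universe) - length(members), length(sig),
                        lower.tail = FALSE)
      list(ct = ct, log_or = log_odds_ratio(ct), se = log_or_se(ct), p = p_hyper)
    }
    e1 <- enr(sig1)
    e2 <- enr(sig2)
    if (p_filter < 1 && min(e1$p, e2$p) >= p_filter) return(NULL)
    cmp <- compare_log_or(e1$log_or, e1$se, e2$log_or, e2$se)
    tibble::tibble(
      set = nm, category = unname(category[nm]), size = length(members),
      n1 = e1$ct[["n11"]], log_or_1 = e1$log_or, se_1 = e1$se, p_enrich_1 = e1$p,
      n2 = e2$ct[["n11"]], log_or_2 = e2$log_or, se_2 = e2$se, p_enrich_2 = e2$p,
      z = cmp$z, p = cmp$p
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out$fdr <- numeric(0)
    return(out)
  }
  out <- dplyr::mutate(dplyr::group_by(out, .data$category), fdr = bh_adjust(.data$p))
  dplyr::arrange(dplyr::ungroup(out), .data$p)
}
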