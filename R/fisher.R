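#' Fisher z-transformation of a correlation coefficient
#'
#' z = atanh(r) = 0.5 * log((1 + r) / (1 - r)). The transform approximately
#' normalizes the sampling distribution of the sample correlation, with
#' variance depending only on the sample size (see [z_variance()]).
#' Coefficients with |r| >= 1 - 1e-12 are clipped to that bound (with a
#' warning) so the transform stays finite.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @return z-score(s), same shape as `r`.
#' @examples
#' fisher_z(0.5) # 0.5 * log(3)
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-12
  clip <- !is.na(r) & abs(r) >= lim
  if (any(clip)) {
    warn("correlation(s) with |r| >= 1 - 1e-12 clipped before atanh")
    r[clip] <- sign(r[clip]) * lim
  }
  atanh(r)
}

#' Variance of a Fisher z-score
#'
#' Under bivariate normality, var(z) = 1 / (n - 3) for the Pearson
#' coefficient and 1.06 / (n - 3) for the Spearman rank coefficient, where
#' n is the number of complete observations behind the correlation. The
#' denominator requires at least 4 samples.
#'
#' @param n Complete-observation count(s), all >= 4.
#' @param method `"pearson"` or `"spearman"`.
#' @return Variance(s) of the z-score.
#' @examples
#' z_variance(103, "pearson") # 0.01
#' @export
z_variance <- function(n, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (any(!is.na(n) & n < 4)) {
    abort("z_variance requires at least 4 samples in each condition")
  }
  k <- if (method == "pearson") 1 else 1.06
  k / (n - 3)
}

#' Difference-in-z statistic for one gene pair across two conditions
#'
#' Standardizes the difference of Fisher z-transformed correlations:
#' dz = (z2 - z1) / sqrt(s2_z1 + s2_z2), where s2_zx is the z-score variance
#' in condition x. Positive dz means a gain of correlation in the
#' second-listed condition. The two-sided p-value comes from the standard
#' normal distribution. With `sign_type = "positive"`, negative coefficients
#' are clamped to 0 before the transform (use when only positive
#' correlations are considered biologically meaningful, e.g. targets of a
#' transcriptional activator); `"negative"` mirrors this by clamping
#' positive coefficients.
#'
#' @param r1,r2 Correlation coefficients in conditions 1 and 2 (vectors ok).
#' @param n1,n2 Complete-observation counts behind `r1`, `r2`; all >= 4.
#' @param method `"pearson"` or `"spearman"` (sets the z variance).
#' @param sign_type `"all"` (default), `"positive"`, or `"negative"`.
#' @return A list with elements `dz` and `p` (two-sided normal p-value).
#' @examples
#' # gain of correlation in condition 2, Spearman, unequal n:
#' pair_diff_z(-0.076, 816, 0.628, 27, method = "spearman")$dz
#' @export
pair_diff_z <- function(r1, n1, r2, n2,
                        method = c("pearson", "spearman"),
                        sign_type = c("all", "positive", "negative")) {
  method <- match.arg(method)
  sign_type <- match.arg(sign_type)
  if (sign_type == "positive") {
    r1 <- pmax(r1, 0)
    r2 <- pmax(r2, 0)
  } else if (sign_type == "negative") {
    r1 <- pmin(r1, 0)
    r2 <- pmin(r2, 0)
  }
  z1 <- fisher_z(r1)
  z2 <- fisher_z(r2)
  dz <- (z2 - z1) / sqrt(z_variance(n1, method) + z_variance(n2, method))
  list(dz = dz, p = 2 * pnorm(abs(dz), lower.tail = FALSE))
}

#' Classify a gene pair by per-condition correlation state
#'
#' Each condition maps to `"+"` (p < alpha and r > 0), `"-"` (p < alpha and
#' r < 0), or `"0"` (not significant); the pair label is the Cartesian
#' product rendered `"c1/c2"`, giving 9 possible classes. Classification is
#' independent of the differential-correlation test, and uses the
#' unclamped coefficients even when a `sign_type` restriction drives the
#' dz statistic. Undefined inputs yield `"NA"`.
#'
#' @param r1,p1 Coefficient and per-condition p-value in condition 1.
#' @param r2,p2 Same for condition 2.
#' @param alpha Per-condition significance level, default 0.05.
#' @return Character label(s), e.g. `"+/0"`.
#' @examples
#' classify_pair(0.257, 2e-10, 0.01, 0.87) # "+/0"
#' @export
classify_pair <- function(r1, p1, r2, p2, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  one <- function(r, p) {
    dplyr::case_when(
      is.na(r) | is.na(p) ~ NA_character_,
      p < alpha & r > 0 ~ "+",
      p < alpha & r < 0 ~ "-",
      TRUE ~ "0"
    )
  }
  c1 <- one(r1, p1)
  c2 <- one(r2, p2)
  ifelse(is.na(c1) | is.na(c2), "NA", paste0(c1, "/", c2))
}
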