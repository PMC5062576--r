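#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' Combines per-study allelic log odds ratios under inverse-variance
#' weighting: pooled beta = sum(w * beta_s) / sum(w) with w = 1/SE_s^2;
#' pooled SE = 1/sqrt(sum(w)). The 95% confidence interval for the odds
#' ratio is exp(beta +/- 1.96 SE). Cochran's Q heterogeneity statistic is
#' computed alongside via [cochran_q()].
#'
#' @param beta Per-study log odds ratios (alleles already harmonized to a
#'   common effect allele).
#' @param se Per-study standard errors (> 0), same length.
#' @return A `fixed_meta` list: `beta`, `se`, `z`, `p`, `or`, `ci_lower`,
#'   `ci_upper`, `q`, `q_df`, `q_p`, `n_studies`.
#' @export
#' @examples
#' ivw_combine(c(0.1, 0.3), c(0.1, 0.1))
ivw_combine <- function(beta, se) {
  check_that(length(beta) >= 1, "at least one study is required")
  check_that(length(beta) == length(se), "'beta' and 'se' lengths differ")
  check_that(all(se > 0), "all standard errors must be positive")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  z <- b / s
  q <- cochran_q(beta, se, pooled_beta = b)
  structure(list(beta = b, se = s, z = z, p = 2 * stats::pnorm(-abs(z)),
                 or = exp(b),
                 ci_lower = exp(b - 1.96 * s), ci_upper = exp(b + 1.96 * s),
                 q = q$q, q_df = q$df, q_p = q$p,
                 n_studies = length(beta)),
            class = "fixed_meta")
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum over studies of w_s * (beta_s - pooled_beta)^2 with w_s = 1/SE_s^2,
#' referred to a chi-square distribution with k - 1 degrees of freedom.
#' With a single study, Q = 0, df = 0 and p = 1 by convention.
#'
#' @param beta,se Per-study effects and standard errors.
#' @param pooled_beta Fixed-effects pooled estimate; computed internally if
#'   omitted.
#' @return List with `q`, `df`, `p`.
#' @export
cochran_q <- function(beta, se, pooled_beta = NULL) {
  check_that(length(beta) >= 1, "at least one study is required")
  check_that(all(se > 0), "all standard errors must be positive")
  w <- 1 / se^2
  if (is.null(pooled_beta)) pooled_beta <- sum(w * beta) / sum(w)
  k <- length(beta)
  if (k == 1L) return(list(q = 0, df = 0L, p = 1))
  q <- sum(w * (beta - pooled_beta)^2)
  list(q = q, df = k - 1L, p = stats::pchisq(q, df = k - 1L,
                                             lower.tail = FALSE))
}
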