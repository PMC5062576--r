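#' Posterior probability of driving the association signal
#'
#' Converts per-variant Bayes factors for one distinct association signal
#' into posterior masses: pi_j = Lambda_j / sum_k Lambda_k, where Lambda_j is
#' the Bayes factor in favour of association at variant j and the summation
#' runs over all variants at the locus. Computed in log space with
#' max-subtraction, so very large Bayes factors are safe.
#'
#' @param log10_bfs Named numeric vector of log10 Bayes factors, one per
#'   variant.
#' @return Named numeric vector of posterior masses summing to 1.
#' @export
#' @examples
#' posterior_probs(c(a = 5, b = 2, c = 0))
posterior_probs <- function(log10_bfs) {
  check_that(length(log10_bfs) >= 1, "'log10_bfs' must be non-empty")
  check_that(all(is.finite(log10_bfs)), "'log10_bfs' must be finite")
  l <- log10_bfs * log(10)
  p <- exp(l - logsumexp(l))
  p / sum(p)
}

#' Construct a credible set for one association signal
#'
#' Ranks variants by descending posterior mass (ties broken by smaller
#' position, then lexicographic identifier) and takes the minimal prefix
#' whose cumulative mass reaches the level. The boundary is inclusive: a
#' variant carrying mass exactly equal to the level forms a singleton set.
#'
#' @param pi Named numeric vector of posterior masses (summing to 1 within
#'   1e-6) from [posterior_probs()].
#' @param pos Integer vector of 1-based bp positions, same order/names as
#'   `pi`.
#' @param level Credible level in (0, 1); default 0.99.
#' @param log10_bfs Optional log10 Bayes factors to carry into the output.
#' @return A `credible_set`: list with `variants` (data frame SNPID, POS,
#'   LOG10BF, PI, CUM_PI, ranked), `level`, `total_mass`, `n_snps`,
#'   `interval` (min and max position) and `distance_bp` (inclusive span,
#'   max - min + 1).
#' @export
build_credible_set <- function(pi, pos, level = 0.99, log10_bfs = NULL) {
  check_that(length(pi) >= 1, "'pi' must be non-empty")
  check_that(length(pos) == length(pi), "'pi' and 'pos' lengths differ")
  check_that(level > 0 && level < 1, "'level' must lie in (0, 1)")
  check_that(abs(sum(pi) - 1) < 1e-6, "'pi' must sum to 1")
  ids <- names(pi)
  if (is.null(ids)) ids <- sprintf("v%d", seq_along(pi))
  ord <- order(-pi, pos, ids)
  cum <- unname(cumsum(pi[ord]))
  n_in <- unname(which(cum >= level)[1])
  if (is.na(n_in)) n_in <- length(pi)  # numerical guard; cum sums to ~1
  take <- ord[seq_len(n_in)]
  vars <- data.frame(
    SNPID = ids[take], POS = pos[take],
    LOG10BF = if (is.null(log10_bfs)) NA_real_ else
      unname(log10_bfs[ids[take]]),
    PI = unname(pi[take]), CUM_PI = unname(cum[seq_len(n_in)]),
    stringsAsFactors = FALSE)
  structure(list(variants = vars, level = level,
                 total_mass = cum[n_in], n_snps = n_in,
                 interval = c(min(vars$POS), max(vars$POS)),
                 distance_bp = max(vars$POS) - min(vars$POS) + 1),
            class = "credible_set")
}

#' Summary statistics of a credible set
#'
#' @param set A `credible_set`.
#' @return List with `n_snps`, `interval` (min, max position, 1-based) and
#'   `distance_bp`, the inclusive span max - min + 1 (a single variant spans
#'   1 bp).
#' @export
#' @examples
#' s <- build_credible_set(c(a = 0.995, b = 0.005), pos = c(100L, 500L))
#' credset_summary(s)
credset_summary <- function(set) {
  check_that(inherits(set, "credible_set"), "'set' must be a credible_set")
  list(n_snps = set$n_snps, interval = set$interval,
       distance_bp = set$distance_bp)
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("%d%% credible set: %d variant(s), %d-%d (%d bp), mass %.4f\n",
              round(100 * x$level), x$n_snps, x$interval[1], x$interval[2],
              x$distance_bp, x$total_mass))
  invisible(x)
}
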