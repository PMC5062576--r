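#' One replicate of the credible-set coverage calibration
#'
#' Simulates a multi-ancestry locus with a single shared causal variant,
#' runs the per-study association and transancestral Bayes-factor scan, and
#' builds the 99% (or requested-level) credible set from the unconditional
#' meta-analysis. Under a correctly specified single-causal-variant model
#' the causal variant should fall inside the level-q credible set with
#' probability at least q, so the containment frequency over many seeded
#' replicates measures the calibration of the credible-set construction.
#'
#' @param seed Integer seed for this replicate.
#' @param n_case,n_control Per-ancestry study sizes (default 3000/3000).
#' @param n_variants Variants per locus (default 60).
#' @param region_length Region length in bp.
#' @param n_ancestral_haplotypes Ancestral panel size.
#' @param F Per-ancestry drift parameters (default `c(0.05, 0.10, 0.15)`).
#' @param switch_rate Per-ancestry mosaic switch rates.
#' @param causal_or Allelic odds ratio of the shared causal variant
#'   (default 1.3).
#' @param n_covariates Null covariates per study.
#' @param level Credible level (default 0.99).
#' @param tau Effect-prior standard deviation.
#' @return List: `contained` (logical: causal variant inside the set),
#'   `n_snps` (set size), `causal_snpid`.
#' @export
credset_coverage_replicate <- function(seed, n_case = 3000, n_control = 3000,
                                       n_variants = 60,
                                       region_length = 100000,
                                       n_ancestral_haplotypes = 400,
                                       F = c(0.05, 0.10, 0.15),
                                       switch_rate = c(2e-4, 5e-4, 1e-3),
                                       causal_or = 1.3, n_covariates = 2,
                                       level = 0.99, tau = 0.2) {
  cfg <- pipeline_config(
    seed = seed, n_variants = n_variants, region_length = region_length,
    n_ancestral_haplotypes = n_ancestral_haplotypes,
    ancestries = data.frame(
      label = sprintf("anc%d", seq_along(F)), F = F,
      switch_rate = rep_len(switch_rate, length(F)),
      n_haplotypes = 300,
      n_case = n_case, n_control = n_control),
    n_causal = 1, causal_or = causal_or, n_covariates = n_covariates,
    level = level, tau = tau)
  sim <- simulate_locus(cfg)
  sc <- meta_scan(sim$locus, tau = cfg$tau, maf_min = cfg$maf_min,
                  info_min = cfg$info_min, min_fraction = cfg$min_fraction)
  if (nrow(sc) == 0)
    return(list(contained = FALSE, n_snps = 0L,
                causal_snpid = sim$causal$snpid))
  pi <- posterior_probs(stats::setNames(sc$LOG10BF, sc$SNPID))
  cs <- build_credible_set(pi, stats::setNames(sc$POS, sc$SNPID),
                           level = level)
  list(contained = sim$causal$snpid %in% cs$variants$SNPID,
       n_snps = cs$n_snps, causal_snpid = sim$causal$snpid)
}
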