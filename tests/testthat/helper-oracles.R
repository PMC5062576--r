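# Independent oracles and small shared fixtures for the test suite.
# Oracles deliberately avoid the package's own computational paths.

# 1-D adaptive quadrature for the marginal likelihood of one study cluster
# (shared latent effect b ~ N(0, tau^2)).
oracle_cluster_ml <- function(beta, se, tau) {
  f <- function(b) vapply(b, function(bb)
    prod(stats::dnorm(beta, bb, se)) * stats::dnorm(bb, 0, tau), numeric(1))
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}

# Association Bayes factor by brute-force numerical integration over every
# enumerated partition: product of per-cluster quadrature integrals.
oracle_bf_association <- function(beta, se, partitions, tau) {
  alt <- 0
  for (p in partitions) {
    ml <- 1
    for (cl in unique(p$assignment)) {
      m <- p$assignment == cl
      ml <- ml * oracle_cluster_ml(beta[m], se[m], tau)
    }
    alt <- alt + p$prior * ml
  }
  null <- prod(stats::dnorm(beta, 0, se))
  alt / null
}

oracle_bf_heterogeneity <- function(beta, se, partitions, tau) {
  alt <- 0
  for (p in partitions) {
    ml <- 1
    for (cl in unique(p$assignment)) {
      m <- p$assignment == cl
      ml <- ml * oracle_cluster_ml(beta[m], se[m], tau)
    }
    alt <- alt + p$prior * ml
  }
  alt / oracle_cluster_ml(beta, se, tau)
}

# A small multi-ancestry locus for integration-style tests.
make_test_locus <- function(seed, n_variants = 30, n_hap = 300,
                            region_length = 60000,
                            n_case = 800, n_control = 800,
                            causal_snpid = character(),
                            causal_beta = numeric(),
                            F = c(0.05, 0.10, 0.15),
                            switch_rate = c(2e-4, 8e-4, 2e-3),
                            n_covariates = 2, alpha = -1) {
  pool <- sim_ancestral_pool(n_variants, region_length, n_hap, seed = seed)
  causal <- causal_model(causal_snpid, causal_beta, alpha = alpha)
  studies <- lapply(seq_along(F), function(i) {
    pop <- derive_population_pool(pool, label = paste0("anc", i), F = F[i],
                                  switch_rate = switch_rate[i],
                                  n_haplotypes = 250, seed = seed + 10 * i)
    simulate_study(pop, causal, n_case = n_case, n_control = n_control,
                   n_covariates = n_covariates, seed = seed + 100 * i)
  })
  list(locus = locus_data(studies), pool = pool, causal = causal)
}

# Distance matrix with labelled studies, for partition/clade tests.
toy_dist <- function(d12, d13, d23, labels = c("s1", "s2", "s3")) {
  m <- matrix(0, 3, 3, dimnames = list(labels, labels))
  m[1, 2] <- m[2, 1] <- d12
  m[1, 3] <- m[3, 1] <- d13
  m[2, 3] <- m[3, 2] <- d23
  m
}
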