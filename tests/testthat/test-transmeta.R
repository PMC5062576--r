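test_that("allele-frequency distance matches hand arithmetic", {
  m <- rbind(s1 = c(0.1, 0.5), s2 = c(0.2, 0.4))
  d <- freq_distance_matrix(m)
  expect_equal(d["s1", "s2"], 0.1)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))
  expect_equal(d, t(d))

  same <- freq_distance_matrix(rbind(a = c(0.3, 0.7), b = c(0.3, 0.7)))
  expect_equal(same["a", "b"], 0)

  expect_error(freq_distance_matrix(rbind(a = c(NA, NA), b = c(0.1, 0.2))),
               "share no variants")
})

test_that("drift separates populations in frequency distance", {
  pool <- sim_ancestral_pool(40, 80000, 300, seed = 31)
  p1 <- derive_population_pool(pool, "p1", F = 0.01, switch_rate = 1e-4,
                               n_haplotypes = 250, seed = 41)
  p2 <- derive_population_pool(pool, "p2", F = 0.01, switch_rate = 1e-4,
                               n_haplotypes = 250, seed = 42)
  p3 <- derive_population_pool(pool, "p3", F = 0.2, switch_rate = 1e-4,
                               n_haplotypes = 250, seed = 43)
  m <- rbind(p1 = p1$freqs, p2 = p2$freqs, p3 = p3$freqs)
  d <- freq_distance_matrix(m)
  expect_lt(d["p1", "p2"], d["p1", "p3"])
  expect_lt(d["p1", "p2"], d["p2", "p3"])
})

test_that("clade clustering cuts as forced by the distances", {
  d <- toy_dist(0.01, 0.2, 0.2)
  cl <- cluster_clades(d, cut_height = 0.1)
  expect_equal(cl$clades[["s1"]], cl$clades[["s2"]])
  expect_false(cl$clades[["s3"]] == cl$clades[["s1"]])

  one <- cluster_clades(d, n_clades = 1)
  expect_length(unique(one$clades), 1L)
  all_single <- cluster_clades(d, n_clades = 3)
  expect_length(unique(all_single$clades), 3L)
  expect_error(cluster_clades(d, n_clades = 4), "n_clades")
})

test_that("centre-set enumeration induces the right partitions and priors", {
  d2 <- matrix(c(0, 0.1, 0.1, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  parts <- enumerate_centre_partitions(d2)
  expect_length(parts, 2L)
  keys <- vapply(parts, function(p) paste(p$assignment, collapse = ","),
                 character(1))
  priors <- vapply(parts, `[[`, numeric(1), "prior")
  expect_setequal(keys, c("1,1", "1,2"))
  expect_equal(unname(priors[order(keys)]), c(0.5, 0.5))

  d3 <- toy_dist(0.05, 0.2, 0.18)
  parts3 <- enumerate_centre_partitions(d3)
  n_centre_sets <- sum(vapply(parts3, function(p) length(p$centres),
                              integer(1)))
  expect_equal(n_centre_sets, 7L)  # 2^3 - 1

  for (n in 2:8) {
    dn <- matrix(runif(n * n, 0.01, 0.5), n)
    dn <- (dn + t(dn)) / 2; diag(dn) <- 0
    rownames(dn) <- colnames(dn) <- paste0("s", 1:n)
    pn <- enumerate_centre_partitions(dn)
    expect_equal(sum(vapply(pn, `[[`, numeric(1), "prior")), 1,
                 tolerance = 1e-12)
  }

  d21 <- matrix(0.1, 21, 21); diag(d21) <- 0
  expect_error(enumerate_centre_partitions(d21), "enumeration bound")
})

test_that("cluster marginal likelihood matches the closed form and quadrature", {
  bf <- exp(cluster_marginal_loglik(0.2, 0.1, 0.2) -
            cluster_null_loglik(0.2, 0.1))
  expect_equal(bf, 2.215063, tolerance = 1e-6)
  expect_equal(log10(bf), 0.3453862, tolerance = 1e-6)

  bf0 <- exp(cluster_marginal_loglik(0, 0.1, 0.2) -
             cluster_null_loglik(0, 0.1))
  expect_equal(bf0, sqrt(0.01 / 0.05), tolerance = 1e-9)

  # prior collapsing onto zero makes alternative and null indistinguishable
  bf_tiny <- exp(cluster_marginal_loglik(c(0.3, -0.1), c(0.1, 0.2), 1e-6) -
                 cluster_null_loglik(c(0.3, -0.1), c(0.1, 0.2)))
  expect_equal(bf_tiny, 1, tolerance = 1e-6)

  set.seed(9)
  for (k in 1:4) {
    beta <- rnorm(k, 0.1, 0.2); se <- runif(k, 0.05, 0.3)
    closed <- cluster_marginal_loglik(beta, se, 0.2)
    quad <- log(oracle_cluster_ml(beta, se, 0.2))
    expect_equal(closed, quad, tolerance = 1e-8)
  }
  expect_error(cluster_marginal_loglik(0.1, 0.1, 0), "tau")
})

test_that("two-study association and heterogeneity BFs match enumeration", {
  d <- matrix(c(0, 0.1, 0.1, 0), 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  parts <- enumerate_centre_partitions(d)
  bm <- bayes_meta(c(0.2, 0.2), c(0.1, 0.1), parts, tau = 0.2)
  expect_equal(bm$log10bf, 0.9184391, tolerance = 1e-6)
  expect_equal(bm$log10bf_het, -0.1485978, tolerance = 1e-6)
  expect_equal(sum(bm$posterior_weights), 1, tolerance = 1e-12)
})

test_that("null data penalize the alternative and opposed effects favour heterogeneity", {
  d <- toy_dist(0.05, 0.2, 0.18)
  parts <- enumerate_centre_partitions(d)
  null_bf <- log10bf_association(c(0, 0, 0), c(0.1, 0.1, 0.1), parts)
  expect_lt(null_bf, 0)

  d2 <- matrix(c(0, 0.1, 0.1, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  parts2 <- enumerate_centre_partitions(d2)
  het <- log10bf_heterogeneity(c(0.5, -0.5), c(0.05, 0.05), parts2)
  expect_gt(het, 0)
})

test_that("Bayes factors are invariant to study order", {
  d <- toy_dist(0.05, 0.2, 0.18)
  parts <- enumerate_centre_partitions(d)
  beta <- c(0.25, 0.1, 0.18); se <- c(0.08, 0.1, 0.12)
  bm <- bayes_meta(beta, se, parts)

  perm <- c(3, 1, 2)
  dp <- d[perm, perm]
  parts_p <- enumerate_centre_partitions(dp)
  bm_p <- bayes_meta(beta[perm], se[perm], parts_p)
  expect_equal(bm_p$log10bf, bm$log10bf, tolerance = 1e-10)
  expect_equal(bm_p$log10bf_het, bm$log10bf_het, tolerance = 1e-10)
})

test_that("single-study heterogeneity BF is zero by convention", {
  single <- list(structure(list(centres = list(1L), assignment = 1L,
                                prior = 1), class = "partition"))
  bm <- bayes_meta(0.2, 0.1, single)
  expect_equal(bm$log10bf_het, 0)
})
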