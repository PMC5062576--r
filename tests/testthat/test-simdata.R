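test_that("ancestral pool satisfies its contract and is seed-deterministic", {
  pool <- sim_ancestral_pool(60, 100000, 200, seed = 1)
  expect_length(pool$positions, 60)
  expect_true(all(diff(pool$positions) > 0))
  expect_true(all(pool$freqs > 0 & pool$freqs < 1))
  expect_true(all(pool$haplotypes %in% c(0L, 1L)))

  again <- sim_ancestral_pool(60, 100000, 200, seed = 1)
  expect_identical(pool, again)

  other <- sim_ancestral_pool(60, 100000, 200, seed = 2)
  expect_true(any(pool$haplotypes != other$haplotypes))

  expect_error(sim_ancestral_pool(1, 100, 50, seed = 1), "n_variants")
  expect_error(sim_ancestral_pool(60, 10, 50, seed = 1), "region_length")
})

test_that("pool generation leaves nontrivial LD between nearby variants", {
  pool <- sim_ancestral_pool(60, 100000, 500, seed = 3)
  r2 <- stats::cor(pool$haplotypes)^2
  adj <- r2[cbind(1:59, 2:60)]
  expect_gt(max(adj, na.rm = TRUE), 0.5)
})

test_that("population drift scales with F and no drift is the identity", {
  pool <- sim_ancestral_pool(40, 80000, 200, seed = 5)
  p_anc <- colMeans(pool$haplotypes)

  nodrift <- derive_population_pool(pool, "x", F = 0, switch_rate = 0,
                                    n_haplotypes = 200, seed = 9)
  expect_equal(nodrift$freqs, p_anc, ignore_attr = TRUE)

  lo <- derive_population_pool(pool, "lo", F = 0.01, switch_rate = 1e-4,
                               n_haplotypes = 200, seed = 11)
  hi <- derive_population_pool(pool, "hi", F = 0.15, switch_rate = 1e-4,
                               n_haplotypes = 200, seed = 11)
  expect_gt(mean(abs(hi$freqs - p_anc)), mean(abs(lo$freqs - p_anc)))

  expect_true(all(hi$freqs > 0 & hi$freqs < 1))
  expect_equal(hi$freqs, colMeans(hi$haplotypes), ignore_attr = TRUE)
  expect_error(derive_population_pool(pool, "x", F = -0.1, switch_rate = 0,
                                      n_haplotypes = 100, seed = 1), "F")
})

test_that("populations derived with different mosaics have different LD", {
  pool <- sim_ancestral_pool(40, 80000, 300, seed = 6)
  a <- derive_population_pool(pool, "a", F = 0.05, switch_rate = 1e-4,
                              n_haplotypes = 250, seed = 21)
  b <- derive_population_pool(pool, "b", F = 0.05, switch_rate = 2e-3,
                              n_haplotypes = 250, seed = 22)
  r2a <- stats::cor(a$haplotypes)^2
  r2b <- stats::cor(b$haplotypes)^2
  expect_gt(max(abs(r2a - r2b), na.rm = TRUE), 0)
})

test_that("study simulation respects quotas, bounds and determinism", {
  pool <- sim_ancestral_pool(20, 40000, 200, seed = 7)
  pop <- derive_population_pool(pool, "anc", F = 0.05, switch_rate = 1e-4,
                                n_haplotypes = 150, seed = 8)
  cm <- causal_model(pool$snpid[5], log(1.3), alpha = -1)
  st <- simulate_study(pop, cm, n_case = 150, n_control = 250,
                       n_covariates = 3, seed = 31)
  expect_equal(sum(st$phenotype == 1), 150)
  expect_equal(sum(st$phenotype == 0), 250)
  expect_true(all(st$dosages >= 0 & st$dosages <= 2))
  expect_equal(dim(st$covariates), c(400L, 3L))
  expect_true(all(st$info == 1))

  st2 <- simulate_study(pop, cm, n_case = 150, n_control = 250,
                        n_covariates = 3, seed = 31)
  expect_identical(st, st2)

  expect_error(simulate_study(pop, cm, n_case = 0, n_control = 10, seed = 1),
               "n_case")
  # an absurd intercept makes the case quota unreachable
  rare <- causal_model(alpha = -30)
  expect_error(simulate_study(pop, rare, n_case = 10, n_control = 10,
                              seed = 1, max_draws = 5000),
               "case quota")
})

test_that("simulated study frequencies stay near the population frequencies", {
  pool <- sim_ancestral_pool(30, 60000, 300, seed = 12)
  pop <- derive_population_pool(pool, "anc", F = 0.08, switch_rate = 5e-4,
                                n_haplotypes = 250, seed = 13)
  st <- simulate_study(pop, causal_model(alpha = -1), n_case = 400,
                       n_control = 400, seed = 14)
  eaf <- colMeans(st$dosages) / 2
  p <- pop$freqs
  n_chr <- 2 * length(st$phenotype)
  se <- sqrt(p * (1 - p) / n_chr)
  expect_true(all(abs(eaf - p) <= 4 * se))
})

test_that("null simulations give no spurious association", {
  pool <- sim_ancestral_pool(10, 20000, 200, seed = 15)
  pop <- derive_population_pool(pool, "anc", F = 0.05, switch_rate = 1e-4,
                                n_haplotypes = 150, seed = 16)
  null_model <- causal_model(alpha = -1)
  z <- vapply(1:60, function(s) {
    st <- simulate_study(pop, null_model, n_case = 300, n_control = 300,
                         n_covariates = 2, seed = 1000 + s)
    fit <- fit_additive(st$dosages[, 4], st$phenotype, st$covariates)
    fit$beta / fit$se
  }, numeric(1))
  expect_gte(mean(abs(z) < 4), 59 / 60)
})

test_that("a planted common effect of OR 1.3 is recovered", {
  pool <- sim_ancestral_pool(10, 20000, 200, seed = 17)
  pop <- derive_population_pool(pool, "anc", F = 0.05, switch_rate = 1e-4,
                                n_haplotypes = 150, seed = 18)
  target <- pool$snpid[which.min(abs(pop$freqs - 0.5))]
  cm <- causal_model(target, log(1.3), alpha = -1)
  ok <- vapply(1:40, function(s) {
    st <- simulate_study(pop, cm, n_case = 1000, n_control = 1000,
                         n_covariates = 2, seed = 2000 + s)
    fit <- fit_additive(st$dosages[, target], st$phenotype, st$covariates)
    abs(fit$beta - log(1.3)) <= 3 * fit$se
  }, logical(1))
  expect_gte(mean(ok), 38 / 40)
})

test_that("dosage degradation hits the requested info and trips QC", {
  pool <- sim_ancestral_pool(10, 20000, 300, seed = 19)
  pop <- derive_population_pool(pool, "anc", F = 0.02, switch_rate = 1e-4,
                                n_haplotypes = 250, seed = 20)
  st <- simulate_study(pop, causal_model(alpha = -1), n_case = 1500,
                       n_control = 1500, seed = 23)

  unchanged <- degrade_dosages(st, target_info = 1.0, seed = 1)
  expect_identical(unchanged$dosages, st$dosages)
  expect_true(all(unchanged$info == 1))

  half <- degrade_dosages(st, target_info = 0.5, seed = 2)
  common <- which(pop$freqs > 0.2 & pop$freqs < 0.8)
  expect_true(all(half$info[common] >= 0.4 & half$info[common] <= 0.6))

  low <- degrade_dosages(st, target_info = 0.2, seed = 3)
  rec <- data.frame(SNPID = low$snpid, EAF = colMeans(low$dosages) / 2,
                    INFO = unname(low$info))
  expect_equal(nrow(qc_variants(rec)), 0)

  expect_error(degrade_dosages(st, target_info = 0, seed = 1), "target_info")
  expect_error(degrade_dosages(st, target_info = 1.2, seed = 1),
               "target_info")
})

test_that("annotation simulation respects coverage, overlap and emptiness", {
  # forced coverage: enrichment 1 must cover the causal position (0-based)
  tr <- sim_annotation(10000, n_elements = 3, element_length = 200,
                       causal_positions = 500, enrichment = 1, seed = 1)
  expect_true(any(tr$start <= 499 & 499 < tr$end))
  expect_true(all(tr$start < tr$end))
  # non-overlap
  if (nrow(tr) > 1)
    expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))

  expect_equal(nrow(sim_annotation(10000, 0, 200, seed = 1)), 0)

  # with enrichment 0 and elements covering <= 2% of the region, the causal
  # position is rarely covered by chance
  covered <- vapply(1:300, function(s) {
    t0 <- sim_annotation(100000, n_elements = 4, element_length = 500,
                         causal_positions = 500, enrichment = 0, seed = s)
    any(t0$start <= 499 & 499 < t0$end)
  }, logical(1))
  expect_lte(mean(covered), 0.05)
})
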