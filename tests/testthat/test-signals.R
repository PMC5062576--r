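test_that("lead scan maximizes the BF with position/identifier tie-breaks", {
  tab <- data.frame(SNPID = c("v100", "v050", "v010"),
                    POS = c(100L, 50L, 10L),
                    LOG10BF = c(6.2, 6.2, 3.0),
                    SHADOW = FALSE)
  expect_identical(scan_lead(tab), "v050")

  one <- data.frame(SNPID = "x", POS = 5L, LOG10BF = 1.0, SHADOW = FALSE)
  expect_identical(scan_lead(one), "x")

  tie_id <- data.frame(SNPID = c("b", "a"), POS = c(10L, 10L),
                       LOG10BF = c(2, 2), SHADOW = FALSE)
  expect_identical(scan_lead(tie_id), "a")

  shadowed <- data.frame(SNPID = c("s", "t"), POS = c(1L, 2L),
                         LOG10BF = c(9, 3), SHADOW = c(TRUE, FALSE))
  expect_identical(scan_lead(shadowed), "t")
  expect_error(scan_lead(shadowed[0, ]), "non-empty")
})

test_that("a null locus yields no signals and an empty trace decision", {
  fx <- make_test_locus(901, n_variants = 20, n_case = 500, n_control = 500)
  out <- stepwise_delineate(fx$locus)
  expect_length(out$signals, 0L)
  if (nrow(out$trace)) expect_identical(out$trace$DECISION, "stop")
})

test_that("meta_scan output is deterministic given the data", {
  fx <- make_test_locus(902, n_variants = 20, n_case = 400, n_control = 400)
  s1 <- meta_scan(fx$locus)
  s2 <- meta_scan(fx$locus)
  expect_identical(s1, s2)
})

test_that("one strong causal yields one signal whose lead tags the causal", {
  hits <- 0L; tagged <- 0L; n_seeds <- 6L
  for (s in seq_len(n_seeds)) {
    pool <- sim_ancestral_pool(30, 60000, 300, seed = 500 + s)
    target <- pool$snpid[which.min(abs(pool$freqs - 0.5))]
    fx <- make_test_locus(500 + s, n_variants = 30, n_case = 1500,
                          n_control = 1500, causal_snpid = target,
                          causal_beta = log(1.4))
    out <- stepwise_delineate(fx$locus)
    if (length(out$signals) == 1L) {
      hits <- hits + 1L
      idx <- out$signals[[1]]$index
      r2 <- ld_r2(fx$locus$studies[[1]]$dosages[, idx],
                  fx$locus$studies[[1]]$dosages[, target])
      if (idx == target || r2 >= 0.8) tagged <- tagged + 1L
      # the index passes both thresholds in its own conditional scan
      expect_gte(out$signals[[1]]$result$LOG10BF, 6)
      expect_lt(out$signals[[1]]$result$P, 5e-8)
      # trace: final round's lead fails the dual threshold
      last <- out$trace[nrow(out$trace), ]
      expect_identical(last$DECISION, "stop")
    }
  }
  expect_gte(hits, n_seeds - 1L)
  expect_gte(tagged, hits - 1L)
})

test_that("two distinct planted causals are delineated and refined", {
  two_found <- 0L; refined_ok <- 0L; n_seeds <- 4L
  for (s in seq_len(n_seeds)) {
    pool <- sim_ancestral_pool(40, 100000, 300, seed = 700 + s)
    # same arguments as make_test_locus below, hence the identical pool
    common <- which(pool$freqs >= 0.3 & pool$freqs <= 0.7)
    pair <- NULL
    for (a in common) {
      for (b in rev(common)) {
        if (b <= a) next
        r2 <- stats::cor(pool$haplotypes[, a], pool$haplotypes[, b])^2
        if (!is.na(r2) && r2 < 0.05) { pair <- c(a, b); break }
      }
      if (!is.null(pair)) break
    }
    expect_false(is.null(pair))
    targets <- pool$snpid[pair]
    fx <- make_test_locus(700 + s, n_variants = 40, region_length = 100000,
                          n_case = 2000, n_control = 2000,
                          causal_snpid = targets,
                          causal_beta = rep(log(1.3), 2))
    out <- stepwise_delineate(fx$locus)
    if (length(out$signals) != 2L) next
    two_found <- two_found + 1L
    refined <- refine_indexes(out$signals, fx$locus)
    idx <- vapply(refined, function(x) x$index, character(1))
    # leave-one-out structure: each signal conditions on the other index
    expect_identical(sort(refined[[1]]$conditioned_on), sort(idx[2]))
    expect_identical(sort(refined[[2]]$conditioned_on), sort(idx[1]))
    dos <- fx$locus$studies[[1]]$dosages
    r2_to_causal <- vapply(idx, function(i)
      max(ld_r2(dos[, i], dos[, targets[1]]),
          ld_r2(dos[, i], dos[, targets[2]])), numeric(1))
    if (all(r2_to_causal >= 0.8)) refined_ok <- refined_ok + 1L
  }
  expect_gte(two_found, n_seeds - 1L)
  expect_gte(refined_ok, two_found - 1L)
})

test_that("a single signal refines to the unconditional lead", {
  pool <- sim_ancestral_pool(25, 50000, 300, seed = 777)
  target <- pool$snpid[which.min(abs(pool$freqs - 0.5))]
  fx <- make_test_locus(777, n_variants = 25, region_length = 50000,
                        n_case = 1500, n_control = 1500,
                        causal_snpid = target, causal_beta = log(1.4))
  out <- stepwise_delineate(fx$locus)
  expect_length(out$signals, 1L)
  refined <- refine_indexes(out$signals, fx$locus)
  expect_length(refined[[1]]$conditioned_on, 0L)
  expect_identical(refined[[1]]$index, scan_lead(meta_scan(fx$locus)))
})
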