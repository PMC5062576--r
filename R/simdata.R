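#' Simulate an ancestral haplotype pool
#'
#' Draws a panel of binary haplotypes over a genomic region, with block-wise
#' correlation between neighbouring variants so that nontrivial linkage
#' disequilibrium (LD) exists. The pool stands in for a deep reference panel
#' from which diverged present-day populations are derived with
#' [derive_population_pool()].
#'
#' Haplotypes are generated from a latent Gaussian autoregression: variants are
#' partitioned into blocks (a new block starts at each variant with probability
#' `block_rate`), the latent value is carried along within a block with
#' correlation `block_rho`, and the allele is the indicator that the latent
#' value falls below the quantile of the variant's ancestral frequency. This
#' yields positive LD within blocks and near-independence across block
#' boundaries, mimicking haplotype-block structure.
#'
#' @param n_variants Number of variants (>= 2).
#' @param region_length Region length in bp; positions are drawn without
#'   replacement from `1:region_length` and sorted.
#' @param n_haplotypes Number of haplotypes in the pool.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   pools.
#' @param freq_range Range of the uniform distribution for ancestral allele
#'   frequencies (default `c(0.05, 0.95)`).
#' @param block_rate Per-variant probability of starting a new LD block.
#' @param block_rho Latent correlation between adjacent variants within a
#'   block.
#' @return An object of class `ancestral_pool`: a list with `snpid`,
#'   `positions` (1-based, strictly increasing), `freqs` (ancestral
#'   frequencies, all in (0,1)) and `haplotypes` (binary matrix, haplotypes x
#'   variants).
#' @export
#' @examples
#' pool <- sim_ancestral_pool(20, 50000, 100, seed = 1)
#' dim(pool$haplotypes)
sim_ancestral_pool <- function(n_variants, region_length, n_haplotypes, seed,
                               freq_range = c(0.05, 0.95),
                               block_rate = 0.1, block_rho = 0.92) {
  check_that(n_variants >= 2, "'n_variants' must be at least 2")
  check_that(n_haplotypes >= 2, "'n_haplotypes' must be at least 2")
  check_that(region_length >= n_variants,
             "'region_length' must be at least 'n_variants'")
  with_seed(seed, {
    positions <- sort(sample.int(region_length, n_variants))
    freqs <- stats::runif(n_variants, freq_range[1], freq_range[2])
    # latent AR(1) within blocks, shared block boundaries across haplotypes
    new_block <- c(TRUE, stats::runif(n_variants - 1) < block_rate)
    z <- matrix(0, n_haplotypes, n_variants)
    z[, 1] <- stats::rnorm(n_haplotypes)
    if (n_variants > 1) {
      for (j in 2:n_variants) {
        eps <- stats::rnorm(n_haplotypes)
        z[, j] <- if (new_block[j]) eps
                  else block_rho * z[, j - 1] + sqrt(1 - block_rho^2) * eps
      }
    }
    hap <- matrix(0L, n_haplotypes, n_variants)
    thr <- stats::qnorm(freqs)
    for (j in seq_len(n_variants)) hap[, j] <- as.integer(z[, j] < thr[j])
    snpid <- sprintf("snp%04d", seq_len(n_variants))
    colnames(hap) <- snpid
    structure(list(snpid = snpid, positions = positions, freqs = freqs,
                   haplotypes = hap),
              class = "ancestral_pool")
  })
}

#' Derive a drifted population haplotype pool
#'
#' Produces a present-day population pool from an ancestral pool under the
#' Balding-Nichols model of allele-frequency drift: for drift parameter
#' `F` (an FST-like quantity), the population target frequency of a variant
#' with ancestral frequency p is drawn from Beta(p(1-F)/F, (1-p)(1-F)/F);
#' at F = 0 the target equals the ancestral frequency. Haplotypes are built
#' as mosaics of ancestral haplotypes, switching template at rate
#' `switch_rate` per bp, so that LD patterns diverge between populations
#' derived with different switch rates and seeds; alleles are then flipped
#' minimally (at random positions) so each variant's realized frequency
#' matches its target.
#'
#' @param ancestral An `ancestral_pool`.
#' @param label Ancestry label (character scalar).
#' @param F Drift parameter, >= 0. Larger F gives larger expected divergence
#'   of the realized frequencies from the ancestral ones.
#' @param switch_rate Per-bp probability of switching template haplotype
#'   between adjacent variants (probability over a gap g is 1 - exp(-rate*g)).
#' @param n_haplotypes Number of haplotypes to generate.
#' @param seed Integer seed.
#' @return An object of class `population_pool`: `label`, `F`, `switch_rate`,
#'   `snpid`, `positions`, `ancestral_freqs`, `freqs` (realized, equal to
#'   column means of `haplotypes`) and `haplotypes`.
#' @export
derive_population_pool <- function(ancestral, label, F, switch_rate,
                                   n_haplotypes, seed) {
  check_that(inherits(ancestral, "ancestral_pool"),
             "'ancestral' must be an ancestral_pool")
  check_that(is.numeric(F) && length(F) == 1L && F >= 0,
             "'F' must be a single number >= 0")
  check_that(switch_rate >= 0, "'switch_rate' must be >= 0")
  anc_hap <- ancestral$haplotypes
  n_anc <- nrow(anc_hap)
  n_var <- ncol(anc_hap)
  p_anc <- colMeans(anc_hap)
  with_seed(seed, {
    target <- if (F > 0) {
      stats::rbeta(n_var, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    } else p_anc
    gaps <- diff(ancestral$positions)
    p_switch <- 1 - exp(-switch_rate * gaps)
    tmpl <- sample.int(n_anc, n_haplotypes, replace = TRUE)
    hap <- matrix(0L, n_haplotypes, n_var)
    hap[, 1] <- anc_hap[tmpl, 1]
    if (n_var > 1) {
      for (j in 2:n_var) {
        if (p_switch[j - 1] > 0) {
          sw <- stats::runif(n_haplotypes) < p_switch[j - 1]
          if (any(sw)) tmpl[sw] <- sample.int(n_anc, sum(sw), replace = TRUE)
        }
        hap[, j] <- anc_hap[tmpl, j]
      }
    }
    # minimal allele flips to hit the target count (kept inside (0,1))
    tgt_count <- pmin(pmax(round(target * n_haplotypes), 1L),
                      n_haplotypes - 1L)
    for (j in seq_len(n_var)) {
      cur <- sum(hap[, j])
      if (cur > tgt_count[j]) {
        ones <- which(hap[, j] == 1L)
        hap[sample(ones, cur - tgt_count[j]), j] <- 0L
      } else if (cur < tgt_count[j]) {
        zeros <- which(hap[, j] == 0L)
        hap[sample(zeros, tgt_count[j] - cur), j] <- 1L
      }
    }
    colnames(hap) <- ancestral$snpid
    structure(list(label = label, F = F, switch_rate = switch_rate,
                   snpid = ancestral$snpid, positions = ancestral$positions,
                   ancestral_freqs = p_anc, freqs = colMeans(hap),
                   haplotypes = hap),
              class = "population_pool")
  })
}

#' Specify the causal disease model
#'
#' Allelic effects are on the log odds-ratio scale and are shared across all
#' ancestry groups (homogeneous effects); `alpha` is the baseline log-odds of
#' disease for an individual carrying zero effect alleles.
#'
#' @param snpid Identifiers of the causal variants (may be empty for a null
#'   model).
#' @param beta Per-allele log odds ratios, same length as `snpid`.
#' @param alpha Baseline intercept on the logit scale.
#' @return An object of class `causal_model`.
#' @export
causal_model <- function(snpid = character(), beta = numeric(), alpha = -1) {
  check_that(length(snpid) == length(beta),
             "'snpid' and 'beta' must have the same length")
  check_that(all(is.finite(beta)), "'beta' must be finite")
  check_that(is.finite(alpha), "'alpha' must be finite")
  structure(list(snpid = as.character(snpid), beta = as.numeric(beta),
                 alpha = alpha),
            class = "causal_model")
}

#' Simulate a case-control study from a population pool
#'
#' Individuals are formed by pairing haplotypes drawn with replacement from
#' the population pool; disease status is Bernoulli with logit
#' `alpha + sum(beta * dosage)` at the causal variants; cases and controls
#' are accumulated by rejection sampling until both quotas are met.
#' Covariates (principal-component-like columns) are simulated independently
#' of genotype and phenotype.
#'
#' @param pool A `population_pool`.
#' @param causal A `causal_model`; every causal variant must exist in the
#'   pool.
#' @param n_case,n_control Requested case and control counts (positive).
#' @param n_covariates Number of null covariate columns (default 2).
#' @param seed Integer seed.
#' @param max_draws Cap on total individuals drawn while filling the quotas
#'   (default 1e7); exceeding it is an error naming the unmet quota.
#' @return An object of class `study_dataset`: `dosages` (individuals x
#'   variants, values in \[0,2\]), `phenotype` (1 = case), `covariates`,
#'   `ancestry`, `info` (per-variant, all 1 for undegraded hard genotypes),
#'   `snpid`, `positions`.
#' @export
simulate_study <- function(pool, causal, n_case, n_control,
                           n_covariates = 2, seed, max_draws = 1e7) {
  check_that(inherits(pool, "population_pool"),
             "'pool' must be a population_pool")
  check_that(inherits(causal, "causal_model"),
             "'causal' must be a causal_model")
  check_that(n_case >= 1, "'n_case' must be positive")
  check_that(n_control >= 1, "'n_control' must be positive")
  cidx <- match(causal$snpid, pool$snpid)
  check_that(!anyNA(cidx), "causal variants must be present in the pool")
  hap <- pool$haplotypes
  n_hap <- nrow(hap)
  with_seed(seed, {
    need_ca <- n_case; need_co <- n_control
    acc_i <- integer(0); acc_j <- integer(0); acc_y <- integer(0)
    drawn <- 0
    batch <- max(2L * (n_case + n_control), 1000L)
    while (need_ca > 0 || need_co > 0) {
      if (drawn >= max_draws) {
        quota <- if (need_ca > 0) sprintf("case quota (%d short)", need_ca)
                 else sprintf("control quota (%d short)", need_co)
        stop("simulate_study: ", quota, " unreachable within ", max_draws,
             " draws; adjust 'alpha' or sample sizes", call. = FALSE)
      }
      b <- min(batch, max_draws - drawn)
      drawn <- drawn + b
      i <- sample.int(n_hap, b, replace = TRUE)
      j <- sample.int(n_hap, b, replace = TRUE)
      eta <- rep(causal$alpha, b)
      if (length(cidx)) {
        g <- hap[i, cidx, drop = FALSE] + hap[j, cidx, drop = FALSE]
        eta <- eta + drop(g %*% causal$beta)
      }
      y <- stats::rbinom(b, 1L, stats::plogis(eta))
      keep_ca <- which(y == 1L)[seq_len(min(need_ca, sum(y == 1L)))]
      keep_co <- which(y == 0L)[seq_len(min(need_co, sum(y == 0L)))]
      keep <- c(keep_ca, keep_co)
      acc_i <- c(acc_i, i[keep]); acc_j <- c(acc_j, j[keep])
      acc_y <- c(acc_y, y[keep])
      need_ca <- need_ca - length(keep_ca)
      need_co <- need_co - length(keep_co)
    }
    ord <- order(-acc_y)  # cases first, stable
    acc_i <- acc_i[ord]; acc_j <- acc_j[ord]; acc_y <- acc_y[ord]
    dos <- hap[acc_i, , drop = FALSE] + hap[acc_j, , drop = FALSE]
    storage.mode(dos) <- "double"
    n <- length(acc_y)
    cov <- if (n_covariates > 0) {
      m <- matrix(stats::rnorm(n * n_covariates), n, n_covariates)
      colnames(m) <- sprintf("PC%d", seq_len(n_covariates))
      m
    } else matrix(numeric(0), n, 0)
    structure(list(dosages = dos, phenotype = acc_y, covariates = cov,
                   ancestry = pool$label,
                   info = stats::setNames(rep(1, ncol(dos)), pool$snpid),
                   snpid = pool$snpid, positions = pool$positions),
              class = "study_dataset")
  })
}

#' Degrade hard genotypes to emulate imputation quality
#'
#' Blends hard genotype dosages towards their mean with added Gaussian noise
#' so that the realized info metric -- the ratio of the dosage variance to the
#' expected variance 2*EAF*(1-EAF) under Hardy-Weinberg, clamped to \[0,1\] --
#' approximates the requested target. A target of exactly 1 leaves the
#' dosages untouched. The realized metric is stored in the dataset's `info`
#' field, so a low target subsequently trips the imputation-quality QC filter.
#'
#' @param study A `study_dataset`.
#' @param target_info Target info in (0, 1\]; scalar or per-variant vector.
#' @param seed Integer seed for the blending noise.
#' @return The modified `study_dataset`.
#' @export
degrade_dosages <- function(study, target_info, seed) {
  check_that(inherits(study, "study_dataset"),
             "'study' must be a study_dataset")
  nv <- ncol(study$dosages)
  target <- rep_len(target_info, nv)
  check_that(all(target > 0 & target <= 1),
             "'target_info' must lie in (0, 1]")
  if (all(target == 1)) {
    study$info[] <- 1
    return(study)
  }
  with_seed(seed, {
    dos <- study$dosages
    n <- nrow(dos)
    for (j in seq_len(nv)) {
      t <- target[j]
      if (t == 1) { study$info[j] <- 1; next }
      x <- dos[, j]
      m <- mean(x); v <- stats::var(x)
      # shrink + noise: var becomes t*v (0.9 shrinkage share, 0.1 noise share)
      a <- sqrt(0.9 * t)
      b <- sqrt(0.1 * t * v)
      x2 <- pmin(pmax(m + a * (x - m) + b * stats::rnorm(n), 0), 2)
      dos[, j] <- x2
      eaf <- mean(x2) / 2
      ev <- 2 * eaf * (1 - eaf)
      study$info[j] <- if (ev > 0) min(1, stats::var(x2) / ev) else 0
    }
    study$dosages <- dos
    study
  })
}

#' Simulate a regulatory annotation track
#'
#' Places non-overlapping elements of fixed length in a region, using the BED
#' convention (0-based, half-open intervals). With probability `enrichment`,
#' each causal position (1-based) is covered by one element; remaining
#' elements are placed uniformly at random without overlap.
#'
#' @param region_length Region length in bp.
#' @param n_elements Number of elements (0 gives an empty track).
#' @param element_length Element length in bp (positive).
#' @param causal_positions 1-based positions to (probabilistically) cover.
#' @param enrichment Probability in \[0,1\] that each causal position is
#'   covered by an element.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per element before giving up.
#' @return An `annotation_track` data frame with columns `chrom`, `start`
#'   (0-based), `end` (exclusive), `name`, `state`, `tissue`, sorted by
#'   start.
#' @export
sim_annotation <- function(region_length, n_elements, element_length,
                           causal_positions = integer(), enrichment = 0,
                           seed, max_tries = 1000L) {
  check_that(n_elements >= 0, "'n_elements' must be non-negative")
  check_that(element_length >= 1, "'element_length' must be positive")
  check_that(enrichment >= 0 && enrichment <= 1,
             "'enrichment' must lie in [0, 1]")
  check_that(region_length >= element_length,
             "'region_length' must fit at least one element")
  empty <- annotation_track(character(), integer(), integer(), character())
  if (n_elements == 0) return(empty)
  with_seed(seed, {
    starts <- integer(0)
    overlaps_any <- function(s) any(s < starts + element_length &
                                    starts < s + element_length)
    place_covering <- function(p0) {
      lo <- max(0L, p0 - element_length + 1L)
      hi <- min(p0, region_length - element_length)
      for (k in seq_len(max_tries)) {
        s <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
        if (!overlaps_any(s)) return(s)
      }
      stop("sim_annotation: cannot place element covering position ", p0 + 1L,
           " without overlap", call. = FALSE)
    }
    for (p in causal_positions) {
      if (length(starts) >= n_elements) break
      if (stats::runif(1) < enrichment)
        starts <- c(starts, place_covering(as.integer(p) - 1L))
    }
    while (length(starts) < n_elements) {
      placed <- FALSE
      for (k in seq_len(max_tries)) {
        s <- sample.int(region_length - element_length + 1L, 1L) - 1L
        if (!overlaps_any(s)) { starts <- c(starts, s); placed <- TRUE; break }
      }
      if (!placed)
        stop("sim_annotation: cannot fit ", n_elements,
             " non-overlapping elements of length ", element_length,
             " in region of length ", region_length, call. = FALSE)
    }
    starts <- sort(starts)
    annotation_track(chrom = rep("chr1", length(starts)),
                     start = starts,
                     end = starts + as.integer(element_length),
                     name = sprintf("el%03d", seq_along(starts)),
                     state = rep("enhancer", length(starts)),
                     tissue = rep("islet", length(starts)))
  })
}
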