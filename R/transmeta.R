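#' Study relatedness from allele frequencies
#'
#' Computes the symmetric matrix of pairwise mean absolute effect-allele
#' frequency differences between studies, the distance on which the Bayesian
#' partition model of study relatedness is built. Frequencies must be
#' harmonized to a common effect allele; the mean for a pair is taken over
#' the variants observed (non-missing) in both studies.
#'
#' @param eaf_matrix Numeric matrix, studies x variants, of effect-allele
#'   frequencies; row names are study labels. `NA` marks a variant missing
#'   from a study.
#' @return Symmetric matrix with zero diagonal, entries in \[0,1\], of class
#'   `matrix`.
#' @export
#' @examples
#' m <- rbind(s1 = c(0.1, 0.5), s2 = c(0.2, 0.4))
#' freq_distance_matrix(m)
freq_distance_matrix <- function(eaf_matrix) {
  eaf_matrix <- as.matrix(eaf_matrix)
  n <- nrow(eaf_matrix)
  check_that(n >= 2, "at least two studies are required")
  labs <- rownames(eaf_matrix)
  if (is.null(labs)) labs <- sprintf("study%d", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- which(!is.na(eaf_matrix[i, ]) & !is.na(eaf_matrix[j, ]))
      check_that(length(shared) >= 1,
                 sprintf("studies '%s' and '%s' share no variants",
                         labs[i], labs[j]))
      d[i, j] <- d[j, i] <-
        mean(abs(eaf_matrix[i, shared] - eaf_matrix[j, shared]))
    }
  }
  d
}

#' Cluster studies into ancestral clades
#'
#' Agglomerative average-linkage clustering of the study relatedness matrix,
#' cut either at a requested number of clades or at a distance height.
#'
#' @param dist_matrix Relatedness matrix from [freq_distance_matrix()].
#' @param n_clades Number of clades to cut at (exclusive with `cut_height`).
#' @param cut_height Distance height to cut at.
#' @return A `clade_assignment` list: `clades` (named integer vector mapping
#'   each study to a clade label), `linkage` ("average"), `cut` (the
#'   parameter used).
#' @export
cluster_clades <- function(dist_matrix, n_clades = NULL, cut_height = NULL) {
  check_that(xor(is.null(n_clades), is.null(cut_height)),
             "supply exactly one of 'n_clades' or 'cut_height'")
  n <- nrow(dist_matrix)
  if (!is.null(n_clades))
    check_that(n_clades >= 1 && n_clades <= n,
               "'n_clades' must be between 1 and the number of studies")
  hc <- stats::hclust(stats::as.dist(dist_matrix), method = "average")
  clades <- if (!is.null(n_clades)) stats::cutree(hc, k = n_clades)
            else stats::cutree(hc, h = cut_height)
  structure(list(clades = clades, linkage = "average",
                 cut = if (!is.null(n_clades)) c(k = n_clades)
                       else c(h = cut_height)),
            class = "clade_assignment")
}

#' Prior specification for the Bayesian transancestral meta-analysis
#'
#' @param tau Standard deviation of the zero-centred normal prior on the
#'   allelic log odds ratio within a cluster of studies (default 0.2, a
#'   typical scale for common-variant complex-trait effects).
#' @return A `prior_spec` list. The partition prior is uniform over the
#'   number of centres T (1..N) and uniform over centre sets of size T.
#' @export
prior_spec <- function(tau = 0.2) {
  check_that(is.numeric(tau) && length(tau) == 1L && tau > 0,
             "'tau' must be a single positive number")
  structure(list(tau = tau,
                 partition_prior = "uniform over number of centres T, uniform over centre sets given T"),
            class = "prior_spec")
}

#' Enumerate centre-based study partitions with prior masses
#'
#' The partition model assigns studies to clusters through centre sets: every
#' non-empty subset of studies is a candidate centre set; each study is
#' assigned to its nearest centre under the relatedness distance (ties broken
#' towards the lowest study index). The prior over centre sets is
#' (1/N) * (1/choose(N, T)) for a set of size T, i.e. uniform over the number
#' of centres and uniform over sets of that size. Centre sets that induce
#' the same partition of studies aggregate their prior mass, so the returned
#' priors sum to 1.
#'
#' @param dist_matrix Relatedness matrix from [freq_distance_matrix()] (its
#'   row names define the study order).
#' @param prior A [prior_spec()] (reserved for alternative partition priors).
#' @param max_studies Enumeration bound (default 20); beyond it the 2^N - 1
#'   centre sets are intractable and an error directs to a sampling scheme,
#'   which this package does not provide.
#' @return List of `partition` objects: each has `centres` (list of centre
#'   index vectors aggregated into this partition), `assignment` (integer
#'   cluster id per study, in study order), `prior` (mass).
#' @export
enumerate_centre_partitions <- function(dist_matrix, prior = prior_spec(),
                                        max_studies = 20L) {
  n <- nrow(dist_matrix)
  check_that(n >= 1, "at least one study is required")
  if (n > max_studies)
    stop("enumerate_centre_partitions: ", n, " studies exceed the ",
         "enumeration bound of ", max_studies,
         "; a sampling scheme over partitions would be required",
         call. = FALSE)
  parts <- list()
  for (mask in seq_len(2^n - 1)) {
    centres <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
    tsize <- length(centres)
    # nearest-centre assignment, ties to the lowest-index centre
    assign_centre <- integer(n)
    for (s in seq_len(n)) {
      dd <- dist_matrix[s, centres]
      assign_centre[s] <- centres[which.min(dd)]
    }
    cluster_id <- match(assign_centre, sort(unique(assign_centre)))
    mass <- (1 / n) * (1 / choose(n, tsize))
    key <- paste(cluster_id, collapse = ",")
    if (is.null(parts[[key]])) {
      parts[[key]] <- structure(list(centres = list(centres),
                                     assignment = cluster_id,
                                     prior = mass),
                                class = "partition")
    } else {
      parts[[key]]$prior <- parts[[key]]$prior + mass
      parts[[key]]$centres <- c(parts[[key]]$centres, list(centres))
    }
  }
  unname(parts)
}

#' Log marginal likelihood of one study cluster
#'
#' Under the alternative, the studies of a cluster share a latent allelic
#' effect b ~ N(0, tau^2), and each observed effect is beta_s ~ N(b, SE_s^2).
#' The marginal likelihood integrates b out in closed form: the joint
#' distribution of the beta_s is zero-mean multivariate normal with
#' covariance diag(SE^2) + tau^2 * J, evaluated via the rank-one
#' determinant and Sherman-Morrison identities. The null counterpart
#' ([cluster_null_loglik()]) fixes b = 0.
#'
#' @param beta,se Per-study effect estimates and standard errors (se > 0).
#' @param tau Effect-prior standard deviation (> 0).
#' @return Log marginal likelihood (natural log).
#' @export
cluster_marginal_loglik <- function(beta, se, tau) {
  check_that(all(se > 0), "all standard errors must be positive")
  check_that(is.numeric(tau) && tau > 0, "'tau' must be positive")
  k <- length(beta)
  w <- 1 / se^2
  sw <- sum(w)
  logdet <- sum(log(se^2)) + log1p(tau^2 * sw)
  quad <- sum(beta^2 * w) - tau^2 * sum(beta * w)^2 / (1 + tau^2 * sw)
  -k / 2 * log(2 * pi) - logdet / 2 - quad / 2
}

#' Log likelihood of a study cluster under no association
#'
#' @inheritParams cluster_marginal_loglik
#' @return Log likelihood with the shared effect fixed at zero.
#' @export
cluster_null_loglik <- function(beta, se) {
  check_that(all(se > 0), "all standard errors must be positive")
  sum(stats::dnorm(beta, 0, se, log = TRUE))
}

# Log marginal likelihood of a full partition under the alternative:
# independent latent effects per cluster.
partition_loglik <- function(beta, se, assignment, tau) {
  ll <- 0
  for (cl in unique(assignment)) {
    m <- assignment == cl
    ll <- ll + cluster_marginal_loglik(beta[m], se[m], tau)
  }
  ll
}

#' Bayesian transancestral meta-analysis of one variant
#'
#' Computes the log10 Bayes factor in favour of association by averaging the
#' partition-model marginal likelihood over all enumerated partitions:
#' the alternative marginal is sum over partitions of
#' prior x product over clusters of the cluster marginal likelihood
#' (latent effect N(0, tau^2) per cluster), and the null fixes every effect
#' at zero. The heterogeneity Bayes factor compares the unconstrained
#' partition average with the single-cluster partition (all studies share
#' one latent effect); values above zero favour between-study effect
#' differences. All arithmetic is in natural-log space with max-subtraction.
#' An inverse-variance fixed-effects companion ([ivw_combine()]) is attached.
#'
#' @param beta,se Per-study effect estimates and standard errors, in the
#'   study order of the partitions.
#' @param partitions Partitions from [enumerate_centre_partitions()]
#'   (priors must sum to 1).
#' @param tau Effect-prior standard deviation (default 0.2).
#' @return A `bayes_meta` list: `log10bf` (association), `log10bf_het`
#'   (heterogeneity; 0 for a single study), `posterior_weights`
#'   (per-partition, summing to 1), `fixed` (the `fixed_meta` companion),
#'   `n_studies`.
#' @export
#' @examples
#' d <- matrix(c(0, .1, .1, 0), 2, dimnames = list(c("a","b"), c("a","b")))
#' parts <- enumerate_centre_partitions(d)
#' bayes_meta(c(0.2, 0.2), c(0.1, 0.1), parts, tau = 0.2)$log10bf
bayes_meta <- function(beta, se, partitions, tau = 0.2) {
  k <- length(beta)
  check_that(length(se) == k, "'beta' and 'se' lengths differ")
  check_that(length(partitions) >= 1, "'partitions' must be non-empty")
  check_that(all(vapply(partitions,
                        function(p) length(p$assignment) == k, logical(1))),
             "partition assignments do not match the number of studies")
  priors <- vapply(partitions, `[[`, numeric(1), "prior")
  check_that(abs(sum(priors) - 1) < 1e-8, "partition priors must sum to 1")
  part_ll <- vapply(partitions, function(p)
    partition_loglik(beta, se, p$assignment, tau), numeric(1))
  alt <- logsumexp(log(priors) + part_ll)
  null <- cluster_null_loglik(beta, se)
  log10bf <- (alt - null) / log(10)
  log10bf_het <- if (k < 2) 0 else {
    single <- cluster_marginal_loglik(beta, se, tau)
    (alt - single) / log(10)
  }
  wts <- exp(log(priors) + part_ll - alt)
  structure(list(log10bf = log10bf, log10bf_het = log10bf_het,
                 posterior_weights = wts / sum(wts),
                 fixed = ivw_combine(beta, se), n_studies = k),
            class = "bayes_meta")
}

#' Log10 Bayes factor of association (convenience wrapper)
#'
#' @inheritParams bayes_meta
#' @return The log10 association Bayes factor, a scalar.
#' @export
log10bf_association <- function(beta, se, partitions, tau = 0.2) {
  bayes_meta(beta, se, partitions, tau)$log10bf
}

#' Log10 Bayes factor of between-study heterogeneity (convenience wrapper)
#'
#' @inheritParams bayes_meta
#' @return The log10 heterogeneity Bayes factor; 0 for a single study by
#'   convention.
#' @export
log10bf_heterogeneity <- function(beta, se, partitions, tau = 0.2) {
  bayes_meta(beta, se, partitions, tau)$log10bf_het
}
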