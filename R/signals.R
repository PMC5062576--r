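#' Bundle per-study datasets into a locus
#'
#' All studies must share the same variant panel (identifiers and
#' positions); they typically come from populations derived from the same
#' ancestral pool.
#'
#' @param studies Non-empty list of `study_dataset` objects.
#' @param chrom Chromosome label (default "chr1").
#' @return A `locus_data` list: `studies`, `snpid`, `positions`, `chrom`,
#'   `total_n` (summed sample size).
#' @export
locus_data <- function(studies, chrom = "chr1") {
  check_that(is.list(studies) && length(studies) >= 1,
             "'studies' must be a non-empty list")
  check_that(all(vapply(studies, inherits, logical(1), "study_dataset")),
             "every element of 'studies' must be a study_dataset")
  ref <- studies[[1]]
  for (s in studies[-1]) {
    check_that(identical(s$snpid, ref$snpid) &&
               identical(s$positions, ref$positions),
               "all studies must share the same variant panel")
  }
  labs <- vapply(studies, function(s) s$ancestry, character(1))
  if (anyDuplicated(labs)) labs <- make.unique(labs)
  names(studies) <- labs
  structure(list(studies = studies, snpid = ref$snpid,
                 positions = ref$positions, chrom = chrom,
                 total_n = sum(vapply(studies,
                                      function(s) length(s$phenotype),
                                      numeric(1)))),
            class = "locus_data")
}

# Study x variant EAF matrix (from raw dosages; unconditional).
locus_eaf_matrix <- function(locus) {
  m <- t(vapply(locus$studies, function(s) colMeans(s$dosages) / 2,
                numeric(length(locus$snpid))))
  colnames(m) <- locus$snpid
  m
}

#' Conditional transancestral meta-analysis scan of a locus
#'
#' Runs the full per-variant chain: per-study QC and additive logistic
#' association (conditioning each model on the dosages of the given index
#' variants, each index conditioning only on the *other* indexes), the
#' sample-completeness filter across studies, and -- for every retained
#' variant -- the partition-model Bayes factors together with the
#' fixed-effects companion.
#'
#' @param locus A `locus_data`.
#' @param conditioning_ids Index-variant identifiers to condition on.
#' @param tau Effect-prior standard deviation (default 0.2).
#' @param maf_min,info_min Per-study QC thresholds.
#' @param min_fraction Completeness threshold across studies (default 0.8).
#' @param partitions Optional pre-enumerated partitions for the full study
#'   set (computed from the locus allele-frequency distances if omitted).
#' @return Data frame, one row per retained variant: SNPID, POS, LOG10BF,
#'   LOG10BF_HET, BETA, SE, OR, CI_L, CI_U, P, Q, Q_DF, Q_P, N, N_STUDIES,
#'   SHADOW.
#' @export
meta_scan <- function(locus, conditioning_ids = character(), tau = 0.2,
                      maf_min = 0.01, info_min = 0.4, min_fraction = 0.8,
                      partitions = NULL) {
  check_that(inherits(locus, "locus_data"), "'locus' must be a locus_data")
  k <- length(locus$studies)
  tabs <- lapply(locus$studies, study_assoc,
                 conditioning_ids = conditioning_ids,
                 maf_min = maf_min, info_min = info_min, chrom = locus$chrom)
  # completeness across studies
  all_ids <- locus$snpid
  n_agg <- stats::setNames(numeric(length(all_ids)), all_ids)
  for (t in tabs) n_agg[t$SNPID] <- n_agg[t$SNPID] + t$N
  keep <- completeness_filter(n_agg, locus$total_n,
                              min_fraction = min_fraction)
  full_d <- if (k >= 2) freq_distance_matrix(locus_eaf_matrix(locus)) else NULL
  if (is.null(partitions) && k >= 2)
    partitions <- enumerate_centre_partitions(full_d)
  single_partition <- list(structure(
    list(centres = list(1L), assignment = 1L, prior = 1), class = "partition"))
  rows <- vector("list", length(keep))
  dist_cache <- new.env(parent = emptyenv())
  for (vi in seq_along(keep)) {
    id <- keep[vi]
    beta <- numeric(0); se <- numeric(0); sidx <- integer(0)
    shadow <- FALSE; pos <- NA_integer_; n_tot <- 0
    for (si in seq_len(k)) {
      t <- tabs[[si]]
      r <- match(id, t$SNPID)
      if (is.na(r)) next
      beta <- c(beta, t$BETA[r]); se <- c(se, t$SE[r])
      sidx <- c(sidx, si)
      shadow <- shadow || t$SHADOW[r]
      pos <- t$POS[r]; n_tot <- n_tot + t$N[r]
    }
    if (!length(beta)) next
    parts <- if (length(sidx) == k && !is.null(partitions)) partitions
             else if (length(sidx) == 1L) single_partition
             else {
               key <- paste(sidx, collapse = ",")
               if (is.null(dist_cache[[key]]))
                 dist_cache[[key]] <- enumerate_centre_partitions(
                   full_d[sidx, sidx, drop = FALSE])
               dist_cache[[key]]
             }
    bm <- bayes_meta(beta, se, parts, tau = tau)
    fx <- bm$fixed
    rows[[vi]] <- data.frame(
      SNPID = id, POS = pos, LOG10BF = bm$log10bf,
      LOG10BF_HET = bm$log10bf_het, BETA = fx$beta, SE = fx$se,
      OR = fx$or, CI_L = fx$ci_lower, CI_U = fx$ci_upper, P = fx$p,
      Q = fx$q, Q_DF = fx$q_df, Q_P = fx$q_p, N = n_tot,
      N_STUDIES = length(beta), SHADOW = shadow, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(SNPID = character(), POS = integer(),
                      LOG10BF = numeric(), LOG10BF_HET = numeric(),
                      BETA = numeric(), SE = numeric(), OR = numeric(),
                      CI_L = numeric(), CI_U = numeric(), P = numeric(),
                      Q = numeric(), Q_DF = integer(), Q_P = numeric(),
                      N = numeric(), N_STUDIES = integer(),
                      SHADOW = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lead variant of a meta-analysis scan
#'
#' The variant maximizing the log10 association Bayes factor; ties are
#' broken towards the smaller position, then the lexicographically smaller
#' identifier. Variants flagged as shadows of a conditioning index are
#' excluded.
#'
#' @param meta_table Scan table from [meta_scan()].
#' @return The lead variant's SNPID (length-1 character), or `NA_character_`
#'   if every variant is shadowed.
#' @export
scan_lead <- function(meta_table) {
  check_that(is.data.frame(meta_table) && nrow(meta_table) >= 1,
             "'meta_table' must be a non-empty data frame")
  t <- meta_table[!meta_table$SHADOW, , drop = FALSE]
  if (nrow(t) == 0) return(NA_character_)
  ord <- order(-t$LOG10BF, t$POS, t$SNPID)
  t$SNPID[ord[1]]
}

#' Stepwise delineation of distinct association signals
#'
#' Round r refits every study conditioning on all currently accepted index
#' variants, re-meta-analyses, and takes the lead variant of the conditional
#' scan. The lead is accepted as a new index only if it attains genome-wide
#' significance on both scales jointly: log10 Bayes factor >= `threshold_bf`
#' and fixed-effects p < `threshold_p`. Delineation stops when the lead
#' fails either threshold, or after `max_rounds` rounds.
#'
#' @param locus A `locus_data`.
#' @param threshold_bf log10 Bayes factor threshold (default 6).
#' @param threshold_p Fixed-effects p-value threshold (default 5e-8).
#' @param max_rounds Safety cap on conditioning rounds (default 10).
#' @param ... QC and prior arguments passed to [meta_scan()].
#' @return List with `signals` (list of `signal` objects: `index`,
#'   `conditioned_on`, `result` -- the index's row of the final conditional
#'   scan) and `trace` (data frame ROUND, LEAD, LOG10BF, P, DECISION; the
#'   final round's lead fails the threshold unless the round cap was hit).
#' @export
stepwise_delineate <- function(locus, threshold_bf = 6, threshold_p = 5e-8,
                               max_rounds = 10, ...) {
  indexes <- character(0)
  trace <- list()
  first_scan <- NULL
  for (r in seq_len(max_rounds)) {
    sc <- meta_scan(locus, conditioning_ids = indexes, ...)
    if (r == 1L) first_scan <- sc
    if (nrow(sc) == 0) break
    lead <- scan_lead(sc)
    if (is.na(lead)) break
    row <- sc[sc$SNPID == lead, ]
    pass <- row$LOG10BF >= threshold_bf && row$P < threshold_p
    trace[[r]] <- data.frame(ROUND = r, LEAD = lead, LOG10BF = row$LOG10BF,
                             P = row$P,
                             DECISION = if (pass) "accept" else "stop",
                             stringsAsFactors = FALSE)
    if (!pass) break
    indexes <- c(indexes, lead)
  }
  # each signal's reported result conditions on all *other* indexes
  signals <- lapply(indexes, function(id) {
    others <- setdiff(indexes, id)
    sc <- if (length(others) == 0 && !is.null(first_scan)) first_scan
          else meta_scan(locus, conditioning_ids = others, ...)
    row <- sc[sc$SNPID == id, , drop = FALSE]
    structure(list(index = id, conditioned_on = others,
                   result = if (nrow(row)) row else NULL),
              class = "signal")
  })
  list(signals = signals,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(ROUND = integer(), LEAD = character(),
                    LOG10BF = numeric(), P = numeric(),
                    DECISION = character(), stringsAsFactors = FALSE))
}

#' Leave-one-out refinement of signal index variants
#'
#' Each signal's index is re-derived by conditioning on all *other* index
#' variants at the locus and rescanning for the lead: with indexes
#' \{A, B, C\}, the middle signal is refined conditioning on \{A, C\}.
#' Refinement sweeps over the signals until the index set is stable, with a
#' cap of `max_iter` sweeps (a warning is raised and the last state
#' returned if the set still oscillates).
#'
#' @param signals Signal list from [stepwise_delineate()].
#' @param locus A `locus_data`.
#' @param max_iter Sweep cap (default 10).
#' @param ... Arguments passed to [meta_scan()].
#' @return The refined signal list (same structure).
#' @export
refine_indexes <- function(signals, locus, max_iter = 10, ...) {
  check_that(length(signals) >= 1, "at least one signal is required")
  indexes <- vapply(signals, function(s) s$index, character(1))
  scans <- stats::setNames(vector("list", length(indexes)), indexes)
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (kk in seq_along(indexes)) {
      others <- indexes[-kk]
      sc <- meta_scan(locus, conditioning_ids = others, ...)
      lead <- scan_lead(sc)
      if (!is.na(lead) && lead != indexes[kk]) {
        indexes[kk] <- lead
        changed <- TRUE
      }
      scans[[kk]] <- sc
      names(scans)[kk] <- indexes[kk]
    }
    if (!changed) break
    if (it == max_iter)
      warning("refine_indexes: index set still changing after ", max_iter,
              " sweeps; returning last state")
  }
  lapply(seq_along(indexes), function(kk) {
    sc <- scans[[kk]]
    row <- sc[sc$SNPID == indexes[kk], , drop = FALSE]
    structure(list(index = indexes[kk],
                   conditioned_on = indexes[-kk],
                   result = if (nrow(row)) row else NULL),
              class = "signal")
  })
}
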