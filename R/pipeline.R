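#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated list.
#' The defaults are the thresholds used throughout the package: MAF >= 1%,
#' info >= 0.4, 80% sample completeness, genome-wide significance at
#' log10 BF >= 6 jointly with fixed-effects p < 5e-8, 99% credible level,
#' and an effect-prior standard deviation tau = 0.2 on the log odds-ratio
#' scale.
#'
#' @param seed Mandatory integer seed; the whole pipeline is deterministic
#'   given the configuration and seed.
#' @param n_variants Variants per locus (>= 1 required, >= 2 to be useful).
#' @param region_length Region length in bp.
#' @param n_ancestral_haplotypes Size of the shared ancestral panel.
#' @param ancestries Data frame with columns `label`, `F`, `switch_rate`,
#'   `n_haplotypes`, `n_case`, `n_control`: one row per simulated study.
#' @param n_causal Number of shared causal variants (ignored if
#'   `causal_snpid` is given).
#' @param causal_or Allelic odds ratio of each causal variant.
#' @param causal_snpid Optional explicit causal variant identifiers.
#' @param alpha Baseline log-odds of disease.
#' @param n_covariates Null covariates per study.
#' @param maf_min,info_min,min_fraction QC thresholds.
#' @param tau Effect-prior standard deviation.
#' @param threshold_bf,threshold_p Dual genome-wide significance thresholds.
#' @param level Credible level.
#' @param n_clades Number of ancestral clades to cut the study dendrogram at.
#' @param annotation List with `n_elements`, `element_length`, `enrichment`
#'   for the simulated regulatory track.
#' @param out_dir Optional output directory for the report TSVs.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed,
                            n_variants = 60,
                            region_length = 100000,
                            n_ancestral_haplotypes = 400,
                            ancestries = data.frame(
                              label = c("EAsia", "EurSAsia", "Afr"),
                              F = c(0.05, 0.10, 0.15),
                              switch_rate = c(2e-4, 5e-4, 1e-3),
                              n_haplotypes = c(300, 300, 300),
                              n_case = c(3000, 3000, 3000),
                              n_control = c(3000, 3000, 3000)),
                            n_causal = 2,
                            causal_or = 1.3,
                            causal_snpid = NULL,
                            alpha = -1,
                            n_covariates = 2,
                            maf_min = 0.01, info_min = 0.4,
                            min_fraction = 0.8,
                            tau = 0.2,
                            threshold_bf = 6, threshold_p = 5e-8,
                            level = 0.99,
                            n_clades = NULL,
                            annotation = list(n_elements = 5,
                                              element_length = 1500,
                                              enrichment = 0.8),
                            out_dir = NULL) {
  check_that(!missing(seed), "'seed' is mandatory")
  check_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
             "'seed' must be a single finite number")
  check_that(n_variants >= 1, "'n_variants' must be positive")
  check_that(region_length >= n_variants,
             "'region_length' must be at least 'n_variants'")
  check_that(is.data.frame(ancestries) &&
             all(c("label", "F", "switch_rate", "n_haplotypes", "n_case",
                   "n_control") %in% names(ancestries)),
             "'ancestries' must have columns label/F/switch_rate/n_haplotypes/n_case/n_control")
  check_that(all(ancestries$F >= 0), "'F' values must be >= 0")
  check_that(maf_min >= 0 && maf_min <= 1 && info_min >= 0 && info_min <= 1,
             "QC thresholds must lie in [0, 1]")
  check_that(min_fraction > 0 && min_fraction <= 1,
             "'min_fraction' must lie in (0, 1]")
  check_that(tau > 0, "'tau' must be positive")
  check_that(level > 0 && level < 1, "'level' must lie in (0, 1)")
  check_that(causal_or > 0, "'causal_or' must be positive")
  if (is.null(n_clades)) n_clades <- min(3L, nrow(ancestries))
  check_that(n_clades >= 1 && n_clades <= nrow(ancestries),
             "'n_clades' must be between 1 and the number of studies")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; `ancestries`
#' is a list of per-study maps with the fields label/F/switch_rate/
#' n_haplotypes/n_case/n_control. Keys not present fall back to the
#' defaults. A `seed` given as an argument overrides the file.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's `seed` key.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  check_that(file.exists(path), sprintf("file not found: '%s'", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(seed)) raw$seed <- seed
  check_that(!is.null(raw$seed), "'seed' is mandatory (file key or argument)")
  if (!is.null(raw$ancestries))
    raw$ancestries <- do.call(rbind, lapply(raw$ancestries, as.data.frame))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  check_that(length(unknown) == 0,
             paste("unknown configuration key(s):",
                   paste(unknown, collapse = ", ")))
  do.call(pipeline_config, raw)
}

# Pick causal variants: common in the ancestral pool (freq in [0.2, 0.8])
# and mutually in low LD (pairwise r^2 < 0.05 among ancestral haplotypes),
# so planted signals are statistically distinct.
choose_causal_variants <- function(pool, n_causal, seed, max_tries = 200L) {
  common <- which(pool$freqs >= 0.2 & pool$freqs <= 0.8)
  check_that(length(common) >= n_causal,
             "not enough common variants to plant the causal model")
  if (n_causal == 0) return(character(0))
  with_seed(seed, {
    for (k in seq_len(max_tries)) {
      pick <- sort(sample(common, n_causal))
      if (n_causal == 1) return(pool$snpid[pick])
      ok <- TRUE
      for (a in seq_len(n_causal - 1)) {
        for (b in (a + 1):n_causal) {
          r2 <- stats::cor(pool$haplotypes[, pick[a]],
                           pool$haplotypes[, pick[b]])^2
          if (is.na(r2) || r2 >= 0.05) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) return(pool$snpid[pick])
    }
    stop("choose_causal_variants: no low-LD causal set found; ",
         "increase the region or lower n_causal", call. = FALSE)
  })
}

#' Simulate the multi-ancestry locus of a pipeline configuration
#'
#' Builds the shared ancestral pool, derives one drifted population per
#' configured ancestry, plants the causal model, and simulates each
#' case-control study. All stage seeds are derived from the configuration
#' seed.
#'
#' @param config A `pipeline_config`.
#' @return List with `locus` (a `locus_data`), `pool` (the ancestral pool),
#'   `pops` (population pools), `causal` (the `causal_model`).
#' @export
simulate_locus <- function(config) {
  check_that(inherits(config, "pipeline_config"),
             "'config' must come from pipeline_config()")
  check_that(config$n_variants >= 2,
             "at least 2 variants are required to simulate a locus")
  seed <- as.integer(config$seed)
  pool <- sim_ancestral_pool(config$n_variants, config$region_length,
                             config$n_ancestral_haplotypes, seed = seed)
  causal_ids <- if (!is.null(config$causal_snpid)) {
    check_that(all(config$causal_snpid %in% pool$snpid),
               "'causal_snpid' must exist in the simulated pool")
    config$causal_snpid
  } else choose_causal_variants(pool, config$n_causal, seed = seed + 7L)
  causal <- causal_model(causal_ids,
                         beta = rep(log(config$causal_or),
                                    length(causal_ids)),
                         alpha = config$alpha)
  anc <- config$ancestries
  pops <- vector("list", nrow(anc))
  studies <- vector("list", nrow(anc))
  for (i in seq_len(nrow(anc))) {
    pops[[i]] <- derive_population_pool(pool, label = anc$label[i],
                                        F = anc$F[i],
                                        switch_rate = anc$switch_rate[i],
                                        n_haplotypes = anc$n_haplotypes[i],
                                        seed = seed + 100L + i)
    studies[[i]] <- simulate_study(pops[[i]], causal,
                                   n_case = anc$n_case[i],
                                   n_control = anc$n_control[i],
                                   n_covariates = config$n_covariates,
                                   seed = seed + 200L + i)
  }
  list(locus = locus_data(studies), pool = pool, pops = pops,
       causal = causal)
}

#' Run the full fine-mapping pipeline
#'
#' Executes simulate -> per-study association -> transancestral meta-analysis
#' -> stepwise signal delineation with leave-one-out index refinement ->
#' credible sets (per ancestral clade and for all studies combined) ->
#' regulatory annotation overlap, from a single seeded configuration.
#' Identical configuration and seed give an identical bundle.
#'
#' @param config A `pipeline_config`.
#' @return A `report_bundle`: list with `clades`, `signals` (Table-1-style
#'   data frame: one row per distinct signal with OR, CI, p, log10 BF,
#'   heterogeneity BF, Cochran's Q p), `credsets` (nested list
#'   signal -> analysis -> `credible_set`), `credset_comparison`
#'   (Table-2-style data frame: per signal and analysis, SNP count, inclusive
#'   distance and interval), `annotation`, `overlaps`, `element_masses`,
#'   `causal`, `trace`, `provenance` (config hash, seed, package version).
#'   If `config$out_dir` is set, report TSVs are written there.
#' @export
run_pipeline <- function(config) {
  check_that(inherits(config, "pipeline_config"),
             "'config' must come from pipeline_config()")
  check_that(config$n_variants >= 2,
             "at least 2 variants are required before simulation")
  stage <- "simulate"
  bundle <- tryCatch({
    sim <- simulate_locus(config)
    locus <- sim$locus

    stage <- "clades"
    d <- freq_distance_matrix(locus_eaf_matrix(locus))
    clades <- cluster_clades(d, n_clades = config$n_clades)
    partitions <- enumerate_centre_partitions(d, prior_spec(config$tau))

    stage <- "signals"
    del <- stepwise_delineate(locus,
                              threshold_bf = config$threshold_bf,
                              threshold_p = config$threshold_p,
                              tau = config$tau,
                              maf_min = config$maf_min,
                              info_min = config$info_min,
                              min_fraction = config$min_fraction,
                              partitions = partitions)
    signals <- del$signals
    if (length(signals) > 1) {
      signals <- refine_indexes(signals, locus,
                                tau = config$tau,
                                maf_min = config$maf_min,
                                info_min = config$info_min,
                                min_fraction = config$min_fraction,
                                partitions = partitions)
    }

    stage <- "credsets"
    analyses <- c(split(names(locus$studies), clades$clades),
                  list(all_studies = names(locus$studies)))
    names(analyses) <- c(sprintf("clade_%s", unique_clade_labels(clades)),
                         "all_studies")
    credsets <- list()
    comparison <- list()
    for (s in signals) {
      credsets[[s$index]] <- list()
      for (an in names(analyses)) {
        sub <- locus_data(locus$studies[analyses[[an]]],
                          chrom = locus$chrom)
        sc <- meta_scan(sub, conditioning_ids = s$conditioned_on,
                        tau = config$tau, maf_min = config$maf_min,
                        info_min = config$info_min,
                        min_fraction = config$min_fraction)
        # shadows of the conditioning indexes carry no conditional evidence
        sc <- sc[!sc$SHADOW, , drop = FALSE]
        if (nrow(sc) == 0) next
        pi <- posterior_probs(stats::setNames(sc$LOG10BF, sc$SNPID))
        cs <- build_credible_set(pi, stats::setNames(sc$POS, sc$SNPID),
                                 level = config$level,
                                 log10_bfs = stats::setNames(sc$LOG10BF,
                                                             sc$SNPID))
        credsets[[s$index]][[an]] <- cs
        comparison[[length(comparison) + 1L]] <- data.frame(
          INDEX_SNP = s$index, ANALYSIS = an, SNPS = cs$n_snps,
          DISTANCE_BP = cs$distance_bp,
          INTERVAL = sprintf("%d-%d", cs$interval[1], cs$interval[2]),
          stringsAsFactors = FALSE)
      }
    }
    comparison <- if (length(comparison)) do.call(rbind, comparison) else
      data.frame(INDEX_SNP = character(), ANALYSIS = character(),
                 SNPS = integer(), DISTANCE_BP = integer(),
                 INTERVAL = character(), stringsAsFactors = FALSE)

    stage <- "annotate"
    causal_pos <- locus$positions[match(sim$causal$snpid, locus$snpid)]
    track <- sim_annotation(config$region_length,
                            n_elements = config$annotation$n_elements,
                            element_length = config$annotation$element_length,
                            causal_positions = causal_pos,
                            enrichment = config$annotation$enrichment,
                            seed = as.integer(config$seed) + 300L)
    overlaps <- list(); masses <- list()
    for (s in signals) {
      cs <- credsets[[s$index]][["all_studies"]]
      if (is.null(cs)) next
      rep_ <- overlap_credible(cs, track, chrom = locus$chrom)
      overlaps[[s$index]] <- rep_
      masses[[s$index]] <- element_mass(rep_)
    }

    stage <- "report"
    sig_tab <- signals_table(signals)
    bundle <- structure(list(
      clades = clades, signals = sig_tab, credsets = credsets,
      credset_comparison = comparison, annotation = track,
      overlaps = overlaps, element_masses = masses,
      causal = sim$causal, trace = del$trace,
      provenance = list(config_hash = config_hash(config),
                        seed = config$seed,
                        version = as.character(utils::packageVersion(
                          "transfinemap")))),
      class = "report_bundle")
    if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
    bundle
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed [config %s]: %s",
                 stage, config_hash(config), conditionMessage(e)),
         call. = FALSE)
  })
  bundle
}

unique_clade_labels <- function(clades) {
  as.character(sort(unique(clades$clades)))
}

signals_table <- function(signals) {
  if (!length(signals))
    return(data.frame(SIGNAL_ID = integer(), INDEX_SNP = character(),
                      CONDITIONED_ON = character(), OR = numeric(),
                      CI_L = numeric(), CI_U = numeric(), P = numeric(),
                      LOG10BF = numeric(), LOG10BF_HET = numeric(),
                      Q_P = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(signals), function(i) {
    s <- signals[[i]]
    r <- s$result
    data.frame(SIGNAL_ID = i, INDEX_SNP = s$index,
               CONDITIONED_ON = if (length(s$conditioned_on))
                 paste(s$conditioned_on, collapse = ";") else ".",
               OR = r$OR, CI_L = r$CI_L, CI_U = r$CI_U, P = r$P,
               LOG10BF = r$LOG10BF, LOG10BF_HET = r$LOG10BF_HET,
               Q_P = r$Q_P, stringsAsFactors = FALSE)
  }))
}

config_hash <- function(config) {
  plain <- config
  plain$out_dir <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(plain[order(names(plain))], f, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_summary_stats(bundle$signals, file.path(dir, "signals.tsv"))
  write_summary_stats(bundle$credset_comparison,
                      file.path(dir, "credset_comparison.tsv"))
  write_bed(bundle$annotation, file.path(dir, "annotation.bed"))
  for (id in names(bundle$credsets)) {
    for (an in names(bundle$credsets[[id]])) {
      write_summary_stats(bundle$credsets[[id]][[an]]$variants,
                          file.path(dir, sprintf("credset_%s_%s.tsv",
                                                 id, an)))
    }
  }
  jsonlite::write_json(
    list(provenance = bundle$provenance,
         clades = as.list(bundle$clades$clades),
         causal = bundle$causal[c("snpid", "beta", "alpha")]),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Transancestral fine-mapping report\n")
  cat(sprintf("  distinct signals: %d\n", nrow(x$signals)))
  if (nrow(x$signals)) {
    for (i in seq_len(nrow(x$signals))) {
      cat(sprintf("  [%d] %s  OR %.3f (%.3f-%.3f)  P %.2e  log10BF %.2f  BF_het %.2f\n",
                  x$signals$SIGNAL_ID[i], x$signals$INDEX_SNP[i],
                  x$signals$OR[i], x$signals$CI_L[i], x$signals$CI_U[i],
                  x$signals$P[i], x$signals$LOG10BF[i],
                  x$signals$LOG10BF_HET[i]))
    }
  }
  cat(sprintf("  seed %s, config %s\n", x$provenance$seed,
              x$provenance$config_hash))
  invisible(x)
}
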