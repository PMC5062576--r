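#' Variant quality control by MAF and imputation quality
#'
#' Retains variants with minor allele frequency `min(EAF, 1-EAF) >= maf_min`
#' and imputation info score `>= info_min`. Both boundaries are inclusive.
#' Defaults exclude variants with MAF below 1% and poorly imputed variants
#' with info below 0.4.
#'
#' @param records Data frame with at least columns `EAF` and `INFO` (one row
#'   per variant).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param info_min Minimum info score (default 0.4).
#' @return The retained rows of `records`.
#' @export
qc_variants <- function(records, maf_min = 0.01, info_min = 0.4) {
  check_that(is.data.frame(records) && all(c("EAF", "INFO") %in% names(records)),
             "'records' must be a data frame with EAF and INFO columns")
  check_that(maf_min >= 0 && maf_min <= 1 && info_min >= 0 && info_min <= 1,
             "thresholds must lie in [0, 1]")
  maf <- pmin(records$EAF, 1 - records$EAF)
  records[maf >= maf_min & records$INFO >= info_min, , drop = FALSE]
}

#' Sample-completeness filter for meta-analysis
#'
#' Excludes variants that pass per-study quality control in less than
#' `min_fraction` of the total meta-analysis sample size. The threshold is
#' the plain product `min_fraction * total_N` (no rounding) and the boundary
#' is inclusive: a variant observed in exactly the threshold number of
#' individuals is retained.
#'
#' @param per_variant_N Named numeric vector: aggregate sample size per
#'   variant (summed over the studies in which it passed QC).
#' @param total_N Total sample size of the meta-analysis (> 0).
#' @param min_fraction Required fraction in (0, 1\] (default 0.8).
#' @return Character vector of retained variant identifiers. The threshold
#'   used is attached as attribute `"threshold"`.
#' @export
#' @examples
#' completeness_filter(c(a = 60000, b = 51699), total_N = 64625)
completeness_filter <- function(per_variant_N, total_N, min_fraction = 0.8) {
  check_that(is.numeric(total_N) && total_N > 0, "'total_N' must be positive")
  check_that(min_fraction > 0 && min_fraction <= 1,
             "'min_fraction' must lie in (0, 1]")
  threshold <- min_fraction * total_N
  kept <- names(per_variant_N)[per_variant_N >= threshold]
  structure(kept, threshold = threshold)
}

#' Additive logistic association for one variant
#'
#' Maximum-likelihood logistic regression of case-control status on an
#' intercept, the variant dosage, optional covariates, and optional
#' conditioning dosages (genotypes at index variants of other signals at the
#' locus). Reports the Wald estimate, standard error and two-sided p-value
#' for the dosage term.
#'
#' Degenerate situations are flagged rather than thrown: a conditioning
#' column nearly collinear with the test dosage (r^2 > `shadow_r2`) marks the
#' result as a "shadow of index" so it is excluded from lead-variant scans;
#' non-convergence or separation clears the `converged` flag so the variant
#' is dropped from downstream meta-analysis for this study.
#'
#' @param dosage Numeric dosage vector (values in \[0,2\]).
#' @param phenotype Binary vector (1 = case); must contain both classes.
#' @param covariates Optional numeric matrix of covariates.
#' @param conditioning Optional numeric matrix of conditioning dosages.
#' @param shadow_r2 Collinearity guard threshold (default 0.95).
#' @return An `assoc_result` list: `beta`, `se`, `p`, `eaf`, `n`,
#'   `conditioned_on` (column names of `conditioning`, or character(0)),
#'   `converged`, `shadow`.
#' @export
fit_additive <- function(dosage, phenotype, covariates = NULL,
                         conditioning = NULL, shadow_r2 = 0.95) {
  n <- length(dosage)
  check_that(length(phenotype) == n, "'dosage' and 'phenotype' lengths differ")
  check_that(all(phenotype %in% c(0, 1)), "'phenotype' must be binary 0/1")
  check_that(length(unique(phenotype)) == 2L,
             "'phenotype' must contain both cases and controls")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    check_that(nrow(covariates) == n, "'covariates' row count mismatch")
  }
  if (!is.null(conditioning) && length(conditioning)) {
    conditioning <- as.matrix(conditioning)
    check_that(nrow(conditioning) == n, "'conditioning' row count mismatch")
  } else conditioning <- NULL

  cond_names <- if (is.null(conditioning)) character(0) else {
    cn <- colnames(conditioning)
    if (is.null(cn)) sprintf("cond%d", seq_len(ncol(conditioning))) else cn
  }
  # collinearity guard: conditioning columns nearly identical to the test
  # dosage are dropped from the model and the result flagged as a shadow of
  # the index, so it never wins a lead scan
  shadow <- FALSE
  if (!is.null(conditioning) && stats::var(dosage) > 0) {
    keep_cols <- rep(TRUE, ncol(conditioning))
    for (k in seq_len(ncol(conditioning))) {
      if (stats::var(conditioning[, k]) == 0) { keep_cols[k] <- FALSE; next }
      if (stats::cor(dosage, conditioning[, k])^2 > shadow_r2) {
        shadow <- TRUE
        keep_cols[k] <- FALSE
      }
    }
    conditioning <- if (any(keep_cols))
      conditioning[, keep_cols, drop = FALSE] else NULL
  }
  X <- cbind(1, dosage, covariates, conditioning)
  res <- list(beta = NA_real_, se = NA_real_, p = NA_real_,
              eaf = mean(dosage) / 2, n = n, conditioned_on = cond_names,
              converged = FALSE, shadow = shadow)
  if (stats::var(dosage) == 0) return(structure(res, class = "assoc_result"))
  fit <- logistic_irls(X, phenotype)
  if (is.null(fit)) return(structure(res, class = "assoc_result"))
  beta <- fit$coef[2L]
  se <- fit$se[2L]
  # separation / quasi-separation shows up as exploding estimates
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 20) {
    return(structure(res, class = "assoc_result"))
  }
  z <- beta / se
  res$beta <- unname(beta)
  res$se <- unname(se)
  res$p <- 2 * stats::pnorm(-abs(z))
  res$converged <- TRUE
  structure(res, class = "assoc_result")
}

# Newton-Raphson IRLS for logistic regression; returns NULL on
# non-convergence, rank deficiency or non-finite information.
logistic_irls <- function(X, y, max_iter = 30L, tol = 1e-9) {
  p <- ncol(X)
  b <- numeric(p)
  b[1] <- stats::qlogis(mean(y))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    delta <- tryCatch(solve(XtWX, crossprod(X, y - mu)),
                      error = function(e) NULL)
    if (is.null(delta) || any(!is.finite(delta))) return(NULL)
    b <- b + drop(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
    if (max(abs(b)) > 50) return(NULL)  # diverging (separation)
  }
  if (!converged) return(NULL)
  eta <- drop(X %*% b)
  mu <- stats::plogis(eta)
  XtWX <- crossprod(X, X * (mu * (1 - mu)))
  vcov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(vcov)) return(NULL)
  list(coef = b, se = sqrt(diag(vcov)))
}

#' Squared-correlation linkage disequilibrium between two dosage vectors
#'
#' @param dosage_a,dosage_b Equal-length numeric vectors with non-zero
#'   variance.
#' @return Squared Pearson correlation in \[0, 1\].
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  check_that(length(dosage_a) == length(dosage_b),
             "dosage vectors must have equal length")
  check_that(stats::var(dosage_a) > 0 && stats::var(dosage_b) > 0,
             "LD undefined: a dosage vector has zero variance")
  min(stats::cor(dosage_a, dosage_b)^2, 1)
}

#' Per-study association scan over all variants of a study
#'
#' Applies [qc_variants()] at the given thresholds, then fits
#' [fit_additive()] for every retained variant, optionally conditioning on
#' the dosages of the given index variants. Variants whose fit does not
#' converge are dropped from the returned table.
#'
#' @param study A `study_dataset`.
#' @param conditioning_ids Identifiers of index variants whose dosages enter
#'   every model as additional covariates (default none). The conditioning
#'   set applies verbatim to every candidate; a candidate that is (or tags,
#'   at r^2 above the collinearity guard) a conditioning index comes back
#'   flagged as a shadow of that index and is excluded from lead scans.
#' @param maf_min,info_min QC thresholds, see [qc_variants()].
#' @param chrom Chromosome label for the output table.
#' @return Data frame with columns SNPID, CHR, POS, EA, OA, EAF, BETA, SE, P,
#'   N, INFO, CONDITIONED_ON (semicolon-joined, "." if none), SHADOW.
#' @export
study_assoc <- function(study, conditioning_ids = character(),
                        maf_min = 0.01, info_min = 0.4, chrom = "chr1") {
  check_that(inherits(study, "study_dataset"),
             "'study' must be a study_dataset")
  eaf <- colMeans(study$dosages) / 2
  rec <- data.frame(SNPID = study$snpid, POS = study$positions,
                    EAF = eaf, INFO = unname(study$info),
                    stringsAsFactors = FALSE)
  rec <- qc_variants(rec, maf_min = maf_min, info_min = info_min)
  out <- vector("list", nrow(rec))
  cond_all <- intersect(conditioning_ids, study$snpid)
  cond <- if (length(cond_all))
    study$dosages[, cond_all, drop = FALSE] else NULL
  cond_label <- if (length(cond_all)) paste(cond_all, collapse = ";") else "."
  for (r in seq_len(nrow(rec))) {
    id <- rec$SNPID[r]
    fit <- fit_additive(study$dosages[, id], study$phenotype,
                        covariates = study$covariates, conditioning = cond)
    if (!fit$converged) next
    out[[r]] <- data.frame(
      SNPID = id, CHR = chrom, POS = rec$POS[r], EA = "A", OA = "G",
      EAF = fit$eaf, BETA = fit$beta, SE = fit$se, P = fit$p, N = fit$n,
      INFO = rec$INFO[r],
      CONDITIONED_ON = cond_label,
      SHADOW = fit$shadow, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(SNPID = character(), CHR = character(),
                      POS = integer(), EA = character(), OA = character(),
                      EAF = numeric(), BETA = numeric(), SE = numeric(),
                      P = numeric(), N = integer(), INFO = numeric(),
                      CONDITIONED_ON = character(), SHADOW = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
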