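#' Write a study dataset to a TSV pair
#'
#' The dosage matrix goes to `<prefix>_dosages.tsv` (columns IID then one
#' column per variant) and the phenotype with covariates to
#' `<prefix>_pheno.tsv` (IID, PHENO, then covariate columns).
#'
#' @param study A `study_dataset`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix, e.g. the ancestry label.
#' @return Character vector of the two paths, invisibly.
#' @export
write_study_tsv <- function(study, dir, prefix) {
  check_that(inherits(study, "study_dataset"),
             "'study' must be a study_dataset")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  iid <- sprintf("%s_%05d", prefix, seq_along(study$phenotype))
  dpath <- file.path(dir, paste0(prefix, "_dosages.tsv"))
  ppath <- file.path(dir, paste0(prefix, "_pheno.tsv"))
  dd <- data.frame(IID = iid, study$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(dd, dpath, sep = "\t", quote = FALSE, row.names = FALSE)
  pd <- data.frame(IID = iid, PHENO = study$phenotype, study$covariates,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(pd, ppath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(dosages = dpath, pheno = ppath))
}

#' Read a study dataset from a TSV pair
#'
#' Inverse of [write_study_tsv()]. Positions and info scores are not stored
#' in the TSV pair and must be supplied (info defaults to 1).
#'
#' @param dosage_path,pheno_path Paths written by [write_study_tsv()].
#' @param positions 1-based positions of the variants, in column order.
#' @param ancestry Ancestry label.
#' @param info Per-variant info scores (default all 1).
#' @return A `study_dataset`.
#' @export
read_study_tsv <- function(dosage_path, pheno_path, positions, ancestry,
                           info = NULL) {
  dd <- utils::read.delim(dosage_path, check.names = FALSE)
  pd <- utils::read.delim(pheno_path, check.names = FALSE)
  check_that(identical(dd$IID, pd$IID),
             "dosage and phenotype files disagree on individuals")
  dos <- as.matrix(dd[, -1, drop = FALSE])
  snpid <- colnames(dos)
  check_that(length(positions) == ncol(dos),
             "'positions' length must match the variant count")
  covs <- as.matrix(pd[, setdiff(names(pd), c("IID", "PHENO")),
                       drop = FALSE])
  if (is.null(info)) info <- rep(1, ncol(dos))
  structure(list(dosages = dos, phenotype = pd$PHENO, covariates = covs,
                 ancestry = ancestry,
                 info = stats::setNames(info, snpid),
                 snpid = snpid, positions = as.integer(positions)),
            class = "study_dataset")
}

#' Write per-study or meta-analysis summary statistics
#'
#' @param tab Data frame (e.g. from [study_assoc()] or [meta_scan()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-study association summary statistics
#'
#' Requires the columns SNPID, CHR, POS, EA, OA, EAF, BETA, SE, P, N, INFO;
#' unknown columns are kept but ignored downstream. When a reference allele
#' table is given, records whose effect/other alleles are swapped relative to
#' the reference are harmonized on load: beta is negated and EAF
#' complemented. Records whose alleles match neither orientation are
#' dropped with a warning.
#'
#' @param path TSV path.
#' @param reference Optional data frame with columns SNPID, EA, OA defining
#'   the reference effect allele per variant.
#' @return Data frame of typed association records.
#' @export
read_summary_stats <- function(path, reference = NULL) {
  check_that(file.exists(path), sprintf("file not found: '%s'", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("SNPID", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P",
                "N", "INFO")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("read_summary_stats: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$SNPID))
    stop("read_summary_stats: duplicated SNPID within study: ",
         paste(unique(tab$SNPID[duplicated(tab$SNPID)]), collapse = ", "),
         call. = FALSE)
  if (!is.null(reference)) {
    m <- match(tab$SNPID, reference$SNPID)
    ok_same <- !is.na(m) & tab$EA == reference$EA[m] &
      tab$OA == reference$OA[m]
    ok_swap <- !is.na(m) & tab$EA == reference$OA[m] &
      tab$OA == reference$EA[m]
    if (any(ok_swap)) {
      tab$BETA[ok_swap] <- -tab$BETA[ok_swap]
      tab$EAF[ok_swap] <- 1 - tab$EAF[ok_swap]
      tmp <- tab$EA[ok_swap]
      tab$EA[ok_swap] <- tab$OA[ok_swap]
      tab$OA[ok_swap] <- tmp
    }
    bad <- !(ok_same | ok_swap)
    if (any(bad)) {
      warning("read_summary_stats: dropping ", sum(bad),
              " record(s) not harmonizable against the reference")
      tab <- tab[!bad, , drop = FALSE]
    }
  }
  tab
}
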