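#' Construct an annotation track
#'
#' Intervals follow the BED convention: 0-based starts, exclusive ends.
#' Intervals are sorted by chromosome then start.
#'
#' @param chrom,start,end,name,state,tissue Equal-length vectors describing
#'   the intervals; `state` and `tissue` default to missing.
#' @return An `annotation_track` data frame.
#' @export
annotation_track <- function(chrom, start, end, name,
                             state = NA_character_, tissue = NA_character_) {
  n <- length(chrom)
  check_that(length(start) == n && length(end) == n && length(name) == n,
             "interval fields must have equal length")
  if (n > 0) check_that(all(start < end), "intervals require start < end")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), name = as.character(name),
                   state = rep_len(as.character(state), n),
                   tissue = rep_len(as.character(tissue), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_track", "data.frame")
  df
}

#' Read a BED annotation file
#'
#' Parses standard BED: tab-separated, >= 3 columns, 0-based half-open
#' coordinates; the fourth (name) column is optional. Malformed coordinates
#' raise a format error naming the offending line.
#'
#' @param path Path to a BED file.
#' @return An `annotation_track`.
#' @export
read_bed <- function(path) {
  check_that(file.exists(path), sprintf("file not found: '%s'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(annotation_track(character(), integer(), integer(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- character(length(lines)); start <- integer(length(lines))
  end <- integer(length(lines)); name <- character(length(lines))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3)
      stop(sprintf("read_bed: line %d has %d column(s), need at least 3",
                   i, length(f)), call. = FALSE)
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("read_bed: line %d has non-numeric coordinates", i),
           call. = FALSE)
    if (s >= e)
      stop(sprintf("read_bed: line %d has start >= end (%d >= %d)", i, s, e),
           call. = FALSE)
    chrom[i] <- f[1]; start[i] <- s; end[i] <- e
    name[i] <- if (length(f) >= 4) f[4] else sprintf("interval%d", i)
  }
  annotation_track(chrom, start, end, name)
}

#' Write an annotation track as BED
#'
#' @param track An `annotation_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Overlap credible-set variants with annotation intervals
#'
#' A variant at 1-based position p overlaps the 0-based half-open interval
#' \[a, b) iff a <= p - 1 < b. Overlaps are computed per chromosome with
#' `IRanges`.
#'
#' @param set A `credible_set`.
#' @param track An `annotation_track`.
#' @param chrom Chromosome of the credible-set variants (default "chr1").
#' @return An `overlap_report`: list with `hits` (data frame ELEMENT, STATE,
#'   SNPID, POS, PI, one row per variant-element overlap) and `set_mass`
#'   (the credible set's total mass). If no chromosome is shared between the
#'   set and the track, a warning is raised and the report is empty.
#' @export
overlap_credible <- function(set, track, chrom = "chr1") {
  check_that(inherits(set, "credible_set"), "'set' must be a credible_set")
  check_that(inherits(track, "annotation_track"),
             "'track' must be an annotation_track")
  empty <- data.frame(ELEMENT = character(), STATE = character(),
                      SNPID = character(), POS = integer(), PI = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(track) > 0 && !chrom %in% track$chrom) {
    warning("overlap_credible: no annotation intervals on chromosome '",
            chrom, "'; empty report")
    return(structure(list(hits = empty, set_mass = set$total_mass),
                     class = "overlap_report"))
  }
  tr <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(tr) == 0 || set$n_snps == 0)
    return(structure(list(hits = empty, set_mass = set$total_mass),
                     class = "overlap_report"))
  # BED [a, b) in 1-based closed coordinates is [a + 1, b]
  elems <- IRanges::IRanges(start = tr$start + 1L, end = tr$end)
  pts <- IRanges::IRanges(start = set$variants$POS, width = 1L)
  ov <- IRanges::findOverlaps(pts, elems)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  hits <- data.frame(ELEMENT = tr$name[sh], STATE = tr$state[sh],
                     SNPID = set$variants$SNPID[qh],
                     POS = set$variants$POS[qh],
                     PI = set$variants$PI[qh], stringsAsFactors = FALSE)
  structure(list(hits = hits, set_mass = set$total_mass),
            class = "overlap_report")
}

#' Summed posterior mass per annotation element
#'
#' For each element overlapped by at least one credible-set variant, sums the
#' posterior masses pi of the overlapping variants. An element carrying the
#' whole credible set accumulates the set's total mass.
#'
#' @param report An `overlap_report` from [overlap_credible()].
#' @return Data frame ELEMENT, STATE, N_SNPS, TOTAL_PI (empty if no
#'   overlaps).
#' @export
element_mass <- function(report) {
  check_that(inherits(report, "overlap_report"),
             "'report' must be an overlap_report")
  h <- report$hits
  if (nrow(h) == 0)
    return(data.frame(ELEMENT = character(), STATE = character(),
                      N_SNPS = integer(), TOTAL_PI = numeric(),
                      stringsAsFactors = FALSE))
  agg <- stats::aggregate(h$PI, by = list(ELEMENT = h$ELEMENT), FUN = sum)
  cnt <- stats::aggregate(h$PI, by = list(ELEMENT = h$ELEMENT), FUN = length)
  st <- h$STATE[match(agg$ELEMENT, h$ELEMENT)]
  out <- data.frame(ELEMENT = agg$ELEMENT, STATE = st,
                    N_SNPS = as.integer(cnt$x), TOTAL_PI = agg$x,
                    stringsAsFactors = FALSE)
  out[order(-out$TOTAL_PI), , drop = FALSE]
}
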