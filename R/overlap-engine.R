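# Interval overlap machinery shared by the recovery and Venn analyses.
# All public semantics are 0-based half-open; internally queries run through
# GenomicRanges (1-based closed), converted so that abutting half-open
# intervals never count as overlapping.

#' Expand an interval symmetrically by a window
#'
#' Pads an interval by `window` bp on both sides, clamping the start at 0.
#' This is the padding applied to loop anchors before testing them against
#' reference peaks (default analysis window: 50 bp).
#'
#' @param interval single-row data frame (or list) with `chrom`, `start`,
#'   `end`; vectorized over rows.
#' @param window non-negative padding in bp.
#' @return The expanded interval(s), same shape as the input.
#' @export
expand_interval <- function(interval, window) {
  if (length(window) != 1L || is.na(window) || window < 0)
    stop("window must be a single non-negative number of bp", call. = FALSE)
  interval <- as.data.frame(interval, stringsAsFactors = FALSE)
  interval$start <- pmax(0, interval$start - window)
  interval$end <- interval$end + window
  interval
}

#' Test two intervals for overlap
#'
#' Half-open semantics: `TRUE` iff the intervals share the same chromosome
#' and at least one base, i.e. `a$start < b$end && b$start < a$end`.
#' Abutting intervals do not overlap.
#'
#' @param a,b single-row data frames (or lists) with `chrom`, `start`, `end`.
#' @return logical.
#' @export
intervals_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# 0-based half-open data frame -> GRanges (1-based closed). Zero-width
# expansion never happens here because validate_intervals enforces
# start < end.
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Build a queryable overlap index over intervals
#'
#' Wraps the intervals in a per-chromosome sorted structure supporting fast
#' range queries. Duplicate intervals are retained as distinct subjects.
#'
#' @param intervals data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return An object of class `overlap_index`.
#' @export
build_index <- function(intervals) {
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  gr <- if (nrow(intervals)) intervals_to_granges(intervals) else
    GenomicRanges::GRanges()
  structure(list(intervals = intervals, gr = gr), class = "overlap_index")
}

#' Query an overlap index
#'
#' Returns, for each query interval, the indices (into the indexed interval
#' table) of all intervals overlapping it under half-open semantics.
#'
#' @param index an [build_index] result.
#' @param queries data frame with `chrom`, `start`, `end`.
#' @return List of integer vectors, one per query row, each sorted.
#' @export
query_index <- function(index, queries) {
  stopifnot(inherits(index, "overlap_index"))
  queries <- as.data.frame(queries, stringsAsFactors = FALSE)
  if (nrow(queries) == 0L) return(list())
  if (nrow(index$intervals) == 0L)
    return(rep(list(integer()), nrow(queries)))
  qgr <- intervals_to_granges(queries)
  hits <- GenomicRanges::findOverlaps(qgr, index$gr)
  out <- rep(list(integer()), nrow(queries))
  if (length(hits)) {
    sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    for (q in names(sp)) out[[as.integer(q)]] <- sort(sp[[q]])
  }
  out
}
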