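# Domain containers and readers/writers for BEDPE loop calls and BED
# reference tracks. Coordinates are BED-convention throughout: 0-based,
# half-open [start, end).

#' Construct a genomic interval table
#'
#' Validates a data frame of intervals (`chrom`, `start`, `end`) against the
#' 0-based half-open convention: `0 <= start < end`, non-empty chromosome.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-valued coordinates, 0-based half-open.
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer()) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$start) | is.na(df$end)))
    stop(what, ": non-integer coordinate", call. = FALSE)
  if (any(!nzchar(df$chrom) | is.na(df$chrom)))
    stop(what, ": empty chromosome name", call. = FALSE)
  if (any(df$start < 0))
    stop(what, ": negative start coordinate", call. = FALSE)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(what, ": start >= end at row ", bad[1], call. = FALSE)
  invisible(df)
}

#' Construct a caller-tagged, resolution-tagged loop set
#'
#' A loop set is an ordered collection of two-anchor chromatin interactions
#' from one loop caller at one matrix resolution. Anchors are canonicalized
#' on construction: within each loop the two anchors are sorted by
#' `(chrom, start)`, so all downstream matching and span computations are
#' orientation-free.
#'
#' @param caller tool name.
#' @param resolution contact-matrix bin size in bp (positive).
#' @param loops data frame with columns `chrom1,start1,end1,chrom2,start2,end2`
#'   and optionally `name` and `score`.
#' @return An object of class `loop_set` with fields `caller`, `resolution`,
#'   `loops`.
#' @export
loop_set <- function(caller, resolution, loops) {
  resolution <- as.numeric(resolution)
  if (length(resolution) != 1L || is.na(resolution) || resolution <= 0)
    stop("resolution must be a positive number of bp", call. = FALSE)
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (!all(req %in% names(loops)))
    stop("loops must have columns ", paste(req, collapse = ", "), call. = FALSE)
  loops <- as.data.frame(loops, stringsAsFactors = FALSE)
  for (col in c("start1", "end1", "start2", "end2"))
    loops[[col]] <- as.numeric(loops[[col]])
  validate_intervals(data.frame(chrom = loops$chrom1, start = loops$start1,
                                end = loops$end1), "anchor1")
  validate_intervals(data.frame(chrom = loops$chrom2, start = loops$start2,
                                end = loops$end2), "anchor2")
  loops <- canonicalize_anchors(loops)
  if (is.null(loops$name)) loops$name <- rep(NA_character_, nrow(loops))
  if (is.null(loops$score)) loops$score <- rep(NA_real_, nrow(loops))
  rownames(loops) <- NULL
  structure(list(caller = as.character(caller), resolution = resolution,
                 loops = loops),
            class = "loop_set")
}

# Sort the two anchors of every loop by (chrom, start) so anchor1 is the
# upstream anchor on intra-chromosomal loops.
canonicalize_anchors <- function(loops) {
  if (nrow(loops) == 0L) return(loops)
  swap <- (loops$chrom1 > loops$chrom2) |
    (loops$chrom1 == loops$chrom2 & loops$start1 > loops$start2)
  if (any(swap)) {
    tmp <- loops[swap, c("chrom1", "start1", "end1")]
    loops[swap, c("chrom1", "start1", "end1")] <-
      loops[swap, c("chrom2", "start2", "end2")]
    loops[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  loops
}

#' Number of loops in a loop set
#' @param ls a `loop_set`.
#' @return integer loop count.
#' @export
n_loops <- function(ls) nrow(ls$loops)

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf("<loop_set> caller=%s resolution=%g bp loops=%d\n",
              x$caller, x$resolution, n_loops(x)))
  invisible(x)
}

#' Construct a named reference feature track
#'
#' A reference set is a BED-style track of protein-associated regions
#' (e.g. CTCF, H3K27ac or RNAPII peaks) used as biological ground truth for
#' recovery analysis. Its record count is the denominator of the recovery
#' rate.
#'
#' @param feature feature name, e.g. `"CTCF"`.
#' @param intervals data frame with columns `chrom`, `start`, `end`.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(feature, intervals) {
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  intervals$start <- as.numeric(intervals$start)
  intervals$end <- as.numeric(intervals$end)
  validate_intervals(intervals, "reference interval")
  rownames(intervals) <- NULL
  structure(list(feature = as.character(feature),
                 intervals = intervals[, c("chrom", "start", "end")]),
            class = "reference_set")
}

#' Number of records in a reference set
#' @param ref a `reference_set`.
#' @return integer record count.
#' @export
n_refs <- function(ref) nrow(ref$intervals)

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> feature=%s records=%d\n", x$feature, n_refs(x)))
  invisible(x)
}

# Open a text connection, transparently gunzipping *.gz paths.
open_input <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

is_skippable_line <- function(line) {
  !nzchar(trimws(line)) | startsWith(line, "#") |
    startsWith(line, "track") | startsWith(line, "browser")
}

normalize_chroms <- function(chrom, mode) {
  switch(mode,
         none  = chrom,
         strip = sub("^chr", "", chrom),
         add   = ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom)))
}

# Parse one 1-indexed column of split fields as integer coordinates,
# reporting the original file line number on failure.
parse_coord_col <- function(fields, j, path, idx) {
  raw <- vapply(fields, `[[`, "", j)
  suppressWarnings(v <- as.numeric(raw))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad))
    stop(sprintf("%s: line %d: non-integer coordinate '%s'",
                 path, idx[bad[1]], raw[bad[1]]), call. = FALSE)
  v
}

#' Read a BEDPE loop file
#'
#' Parses a standard BEDPE file (tab-separated, at least six columns:
#' `chrom1 start1 end1 chrom2 start2 end2`) into a [loop_set]. File order is
#' preserved (loop callers conventionally sort output by confidence) and
#' anchors are canonicalized within each loop. Lines starting with `#`,
#' `track` or `browser` and blank lines are skipped. When present, column 7
#' is taken as the loop name and column 8, if numeric, as the caller score
#' (larger = more confident). Extra trailing columns are ignored.
#' `.gz` paths are decompressed transparently.
#'
#' @param path BEDPE file path.
#' @param caller tool name to tag the set with.
#' @param resolution matrix resolution in bp.
#' @param normalize_chrom one of `"none"` (default), `"strip"` (remove a
#'   `chr` prefix) or `"add"`; guards against silent dialect mismatches
#'   between loop and reference files.
#' @return A [loop_set].
#' @export
read_bedpe <- function(path, caller, resolution,
                       normalize_chrom = c("none", "strip", "add")) {
  normalize_chrom <- match.arg(normalize_chrom)
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  idx <- which(!is_skippable_line(lines))
  if (!length(idx))
    return(loop_set(caller, resolution, empty_loops_df()))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    b <- which(nf < 6L)[1]
    stop(sprintf("%s: line %d: expected >= 6 tab-separated fields, got %d",
                 path, idx[b], nf[b]), call. = FALSE)
  }
  df <- data.frame(chrom1 = vapply(fields, `[[`, "", 1L),
                   start1 = parse_coord_col(fields, 2L, path, idx),
                   end1   = parse_coord_col(fields, 3L, path, idx),
                   chrom2 = vapply(fields, `[[`, "", 4L),
                   start2 = parse_coord_col(fields, 5L, path, idx),
                   end2   = parse_coord_col(fields, 6L, path, idx),
                   stringsAsFactors = FALSE)
  bad <- which(df$start1 >= df$end1 | df$start2 >= df$end2)
  if (length(bad))
    stop(sprintf("%s: line %d: start >= end", path, idx[bad[1]]),
         call. = FALSE)
  if (any(nf >= 7L))
    df$name <- vapply(fields, function(f)
      if (length(f) >= 7L) f[[7L]] else NA_character_, "")
  if (any(nf >= 8L)) {
    raw <- vapply(fields, function(f)
      if (length(f) >= 8L) f[[8L]] else NA_character_, "")
    suppressWarnings(df$score <- as.numeric(raw))
  }
  df$chrom1 <- normalize_chroms(df$chrom1, normalize_chrom)
  df$chrom2 <- normalize_chroms(df$chrom2, normalize_chrom)
  loop_set(caller, resolution, df)
}

empty_loops_df <- function() {
  data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
             chrom2 = character(), start2 = numeric(), end2 = numeric(),
             name = character(), score = numeric(), stringsAsFactors = FALSE)
}

#' Read a BED reference track
#'
#' Parses a BED3+ file into a [reference_set]. The record count of the
#' returned set equals the number of data lines; comment/`track`/`browser`
#' and blank lines are skipped, trailing columns beyond the third ignored.
#'
#' @inheritParams read_bedpe
#' @param feature feature name to tag the set with (e.g. `"CTCF"`).
#' @return A [reference_set].
#' @export
read_bed <- function(path, feature,
                     normalize_chrom = c("none", "strip", "add")) {
  normalize_chrom <- match.arg(normalize_chrom)
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  idx <- which(!is_skippable_line(lines))
  if (!length(idx))
    return(reference_set(feature, data.frame(chrom = character(),
                                             start = numeric(),
                                             end = numeric())))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    b <- which(nf < 3L)[1]
    stop(sprintf("%s: line %d: expected >= 3 tab-separated fields, got %d",
                 path, idx[b], nf[b]), call. = FALSE)
  }
  start <- parse_coord_col(fields, 2L, path, idx)
  end <- parse_coord_col(fields, 3L, path, idx)
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("%s: line %d: start >= end", path, idx[bad[1]]),
         call. = FALSE)
  chrom <- normalize_chroms(vapply(fields, `[[`, "", 1L), normalize_chrom)
  reference_set(feature, data.frame(chrom = chrom, start = start, end = end,
                                    stringsAsFactors = FALSE))
}

#' Validate a loop set and collect data-quality warnings
#'
#' Flags conditions that commonly produce misleading downstream metrics:
#' an empty set, duplicated loops (identical anchor coordinates) and
#' inter-chromosomal loops (excluded from size statistics). Inputs whose
#' in-memory size exceeds `max_bytes` are rejected outright.
#'
#' @param ls a [loop_set].
#' @param max_bytes size guard in bytes (default 100 MB, matching typical
#'   upload limits for loop-caller output).
#' @return Character vector of warnings (length 0 when clean).
#' @export
validate_loop_set <- function(ls, max_bytes = 100 * 1024^2) {
  stopifnot(inherits(ls, "loop_set"))
  if (as.numeric(object.size(ls$loops)) > max_bytes)
    stop(sprintf("loop set '%s' exceeds the %.0f-byte size limit",
                 ls$caller, max_bytes), call. = FALSE)
  if (n_loops(ls) == 0L)
    return("empty loop set")
  warnings <- character()
  key <- paste(ls$loops$chrom1, ls$loops$start1, ls$loops$end1,
               ls$loops$chrom2, ls$loops$start2, ls$loops$end2)
  ndup <- sum(duplicated(key))
  if (ndup > 0L)
    warnings <- c(warnings, sprintf("%d duplicate loop pair(s)", ndup))
  ninter <- sum(ls$loops$chrom1 != ls$loops$chrom2)
  if (ninter > 0L)
    warnings <- c(warnings, sprintf("%d inter-chromosomal loop(s)", ninter))
  warnings
}
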