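# Recovery metrics: recovery rate delta, its per-1000-loop prefix curve,
# the Recovery Efficiency Metric Delta = delta / loop count, and the
# resolution-consistency score Lambda.

# For every reference record, the 1-based index of the first loop (in the
# given order) whose window-expanded anchor overlaps it; NA when never
# recovered. One findOverlaps pass over both anchors of all loops.
first_recovering_loop <- function(ref, ls, window) {
  nr <- n_refs(ref)
  nl <- n_loops(ls)
  if (nr == 0L || nl == 0L) return(rep(NA_integer_, nr))
  lp <- ls$loops
  anchors <- data.frame(
    chrom = c(lp$chrom1, lp$chrom2),
    start = c(lp$start1, lp$start2),
    end = c(lp$end1, lp$end2),
    stringsAsFactors = FALSE)
  anchors <- expand_interval(anchors, window)
  agr <- intervals_to_granges(anchors)
  rgr <- intervals_to_granges(ref$intervals)
  hits <- GenomicRanges::findOverlaps(agr, rgr)
  first <- rep(NA_integer_, nr)
  if (length(hits)) {
    loop_idx <- ((S4Vectors::queryHits(hits) - 1L) %% nl) + 1L
    ref_idx <- S4Vectors::subjectHits(hits)
    agg <- tapply(loop_idx, ref_idx, min)
    first[as.integer(names(agg))] <- as.integer(agg)
  }
  first
}

# Loop-mode twin: for every loop, the 1-based index of any reference it
# recovers (TRUE/FALSE per loop).
loop_hits_any_ref <- function(ref, ls, window) {
  nl <- n_loops(ls)
  if (nl == 0L || n_refs(ref) == 0L) return(logical(nl))
  lp <- ls$loops
  anchors <- data.frame(
    chrom = c(lp$chrom1, lp$chrom2),
    start = c(lp$start1, lp$start2),
    end = c(lp$end1, lp$end2),
    stringsAsFactors = FALSE)
  anchors <- expand_interval(anchors, window)
  agr <- intervals_to_granges(anchors)
  rgr <- intervals_to_granges(ref$intervals)
  hit_anchor <- GenomicRanges::countOverlaps(agr, rgr) > 0L
  hit_anchor[seq_len(nl)] | hit_anchor[nl + seq_len(nl)]
}

reorder_loops <- function(ls, order = c("file", "score_desc")) {
  order <- match.arg(order)
  if (order == "score_desc") {
    if (all(is.na(ls$loops$score)))
      stop("order = 'score_desc' requires a score column", call. = FALSE)
    # stable: ties in score keep file order
    ls$loops <- ls$loops[order(-ls$loops$score), , drop = FALSE]
    rownames(ls$loops) <- NULL
  }
  ls
}

#' Count reference records recovered by a loop set
#'
#' A reference record is recovered when at least one window-expanded anchor
#' of the first `prefix` loops overlaps it (either anchor suffices); each
#' reference record is counted at most once, so the count is bounded by the
#' reference size. `count_mode = "loop"` instead counts loops having at
#' least one anchor overlapping any reference record.
#'
#' @param ref a [reference_set].
#' @param ls a [loop_set].
#' @param window anchor padding in bp (default 50).
#' @param prefix optional number of leading loops to use (default: all).
#' @param count_mode `"reference"` (default; distinct recovered reference
#'   records) or `"loop"` (distinct recovering loops).
#' @return integer overlap count.
#' @export
count_recovered <- function(ref, ls, window = 50,
                            prefix = NULL,
                            count_mode = c("reference", "loop")) {
  count_mode <- match.arg(count_mode)
  stopifnot(inherits(ref, "reference_set"), inherits(ls, "loop_set"))
  if (!is.null(prefix)) {
    if (prefix < 0 || prefix > n_loops(ls))
      stop("prefix must be between 0 and the loop count", call. = FALSE)
    ls$loops <- ls$loops[seq_len(prefix), , drop = FALSE]
  }
  if (count_mode == "reference") {
    sum(!is.na(first_recovering_loop(ref, ls, window)))
  } else {
    sum(loop_hits_any_ref(ref, ls, window))
  }
}

#' Recovery rate of a loop set against a reference track
#'
#' The fraction of reference records recovered by the loop anchors within
#' the window: `delta = N_o / N_ref`, where `N_ref` is the reference record
#' count and `N_o` the overlap count of [count_recovered]. Bounded in
#' `[0, 1]` in the default reference-counting mode.
#'
#' @inheritParams count_recovered
#' @return recovery rate in `[0, 1]` (may exceed 1 in `"loop"` mode when
#'   loops outnumber references).
#' @export
recovery_rate <- function(ref, ls, window = 50, prefix = NULL,
                          count_mode = c("reference", "loop")) {
  if (n_refs(ref) == 0L)
    stop("recovery rate undefined: reference set '", ref$feature,
         "' is empty", call. = FALSE)
  count_recovered(ref, ls, window, prefix, count_mode) / n_refs(ref)
}

#' Cumulative recovery curve over loop prefixes
#'
#' Computes the recovery rate over the first k loops for
#' k = step, 2*step, ... (default step 1000), plus a final point at the
#' full loop count, so the endpoint equals the total recovery rate. Loops
#' are taken in file order by default (callers emit significance-sorted
#' files); `order = "score_desc"` sorts by the score column, ties stable.
#'
#' @inheritParams count_recovered
#' @param step prefix increment in loops (default 1000).
#' @param order `"file"` or `"score_desc"`.
#' @return An object of class `recovery_curve` with fields `feature`,
#'   `caller`, `resolution`, `points` (data frame `k`, `delta`) and
#'   `final_delta`.
#' @export
recovery_curve <- function(ref, ls, window = 50, step = 1000,
                           order = c("file", "score_desc")) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (n_refs(ref) == 0L)
    stop("recovery curve undefined: reference set '", ref$feature,
         "' is empty", call. = FALSE)
  ls <- reorder_loops(ls, match.arg(order))
  nl <- n_loops(ls)
  ks <- seq_len(nl %/% step) * step
  if (nl == 0L || nl %% step != 0L) ks <- c(ks, nl)
  first <- first_recovering_loop(ref, ls, window)
  first <- first[!is.na(first)]
  delta <- vapply(ks, function(k) sum(first <= k), 0) / n_refs(ref)
  structure(list(feature = ref$feature, caller = ls$caller,
                 resolution = ls$resolution,
                 points = data.frame(k = ks, delta = delta),
                 final_delta = if (length(delta)) delta[length(delta)] else 0),
            class = "recovery_curve")
}

#' Recovery Efficiency Metric (REM)
#'
#' Normalizes the recovery rate by the loop count, `Delta = delta / N_c`,
#' so that tools cannot inflate apparent recovery simply by calling an
#' excessive number of loops.
#'
#' @param delta recovery rate.
#' @param n_c loop count (positive).
#' @return REM value.
#' @export
rem <- function(delta, n_c) {
  if (length(n_c) != 1L || is.na(n_c) || n_c <= 0)
    stop("REM undefined: loop count must be positive", call. = FALSE)
  delta / n_c
}

#' Resolution-consistency score
#'
#' The absolute difference between the mean REM over the low-resolution
#' group and the mean REM over the high-resolution group,
#' `Lambda = |chi_low - chi_high|`, with each group mean taken as the
#' unweighted grand mean over its resolutions and all features. Smaller
#' values indicate more resolution-consistent loop calling. Default groups:
#' high = 5 kb and 10 kb, low = 100 kb and 250 kb; both are user-definable.
#'
#' @param rems data frame with columns `resolution`, `feature`, `rem`
#'   (one REM value per resolution-feature cell).
#' @param high,low non-empty, disjoint sets of resolutions (bp).
#' @param caller optional caller label carried into the result.
#' @return An object of class `consistency_score` with fields `caller`,
#'   `chi_low`, `chi_high`, `value`.
#' @export
consistency_lambda <- function(rems, high = c(5000, 10000),
                               low = c(100000, 250000), caller = NA_character_) {
  if (!length(high) || !length(low))
    stop("high and low resolution groups must be non-empty", call. = FALSE)
  if (length(intersect(high, low)))
    stop("high and low resolution groups must be disjoint", call. = FALSE)
  stopifnot(is.data.frame(rems),
            all(c("resolution", "feature", "rem") %in% names(rems)))
  features <- unique(rems$feature)
  wanted <- expand.grid(resolution = c(high, low), feature = features,
                        stringsAsFactors = FALSE)
  have <- paste(rems$resolution, rems$feature)
  missing <- wanted[!paste(wanted$resolution, wanted$feature) %in% have, ]
  if (nrow(missing))
    stop("missing REM cells: ",
         paste(sprintf("(%g, %s)", missing$resolution, missing$feature),
               collapse = ", "), call. = FALSE)
  chi_high <- mean(rems$rem[rems$resolution %in% high])
  chi_low <- mean(rems$rem[rems$resolution %in% low])
  structure(list(caller = caller, chi_low = chi_low, chi_high = chi_high,
                 value = abs(chi_low - chi_high)),
            class = "consistency_score")
}
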