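# Cross-caller loop comparison: tolerance-based loop matching, three-set
# Venn region counts over match-graph clusters, and the per-tool overlap
# percentage used as the consistency feature of the aggregate score.
#
# Because tolerance matching is not transitive, the Venn partition is
# defined on connected components ("loop clusters") of the match graph over
# the union of the three sets; this is symmetric and independent of set
# order.

loop_midpoints2 <- function(loops) {
  # doubled midpoints keep arithmetic integral (mid = (start+end)/2)
  list(m1 = loops$start1 + loops$end1, m2 = loops$start2 + loops$end2)
}

#' Test whether two loops represent the same interaction
#'
#' Two loops match when they lie on the same chromosome pair and, after
#' anchor canonicalization, both corresponding anchor midpoints differ by
#' at most `tol` bp.
#'
#' @param a,b single loops: one-row data frames (or lists) with
#'   `chrom1,start1,end1,chrom2,start2,end2`.
#' @param tol matching tolerance in bp (>= 0).
#' @return logical.
#' @export
loops_match <- function(a, b, tol) {
  if (tol < 0) stop("tol must be non-negative", call. = FALSE)
  a <- canonicalize_anchors(as.data.frame(a, stringsAsFactors = FALSE))
  b <- canonicalize_anchors(as.data.frame(b, stringsAsFactors = FALSE))
  a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2 &&
    abs((a$start1 + a$end1) - (b$start1 + b$end1)) <= 2 * tol &&
    abs((a$start2 + a$end2) - (b$start2 + b$end2)) <= 2 * tol
}

# Cluster the union of several loop sets by the loops_match relation.
# Returns per-loop cluster ids and set labels, in input order
# (set-by-set, file order within each).
cluster_loops <- function(sets, tol) {
  labels <- names(sets)
  combined <- do.call(rbind, lapply(seq_along(sets), function(i) {
    lp <- sets[[i]]$loops
    if (nrow(lp) == 0L)
      return(data.frame(set = character(), chrompair = character(),
                        m1 = numeric(), m2 = numeric(),
                        stringsAsFactors = FALSE))
    data.frame(set = rep(labels[i], nrow(lp)),
               chrompair = paste0(lp$chrom1, "|", lp$chrom2),
               m1 = lp$start1 + lp$end1, m2 = lp$start2 + lp$end2,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(combined)
  if (n == 0L)
    return(data.frame(set = character(), cluster = integer()))
  # candidate pairs by first-midpoint proximity, then filter on the second
  gr <- GenomicRanges::GRanges(
    seqnames = combined$chrompair,
    ranges = IRanges::IRanges(start = combined$m1, width = 2 * tol + 1))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ok <- abs(combined$m2[qi] - combined$m2[si]) <= 2 * tol
  g <- igraph::graph_from_data_frame(
    data.frame(from = qi[ok], to = si[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  data.frame(set = combined$set,
             cluster = comp$membership[as.character(seq_len(n))],
             stringsAsFactors = FALSE)
}

#' Three-way Venn counts of loop clusters
#'
#' Builds the match graph over all loops of the three sets (edges given by
#' [loops_match] at tolerance `tol`), takes connected components as loop
#' clusters, and assigns each cluster to the Venn region defined by the
#' sets it contains. Region counts are cluster counts, so a cluster merging
#' several near-identical loops from one caller is counted once.
#'
#' @param A,B,C three [loop_set]s.
#' @param tol matching tolerance in bp; `NULL` (default) uses the largest
#'   resolution among the three sets, the natural scale at which bin-level
#'   coordinates can disagree.
#' @return An object of class `triplet_overlap` with fields `set_names`,
#'   `region_counts` (named integer vector over
#'   `A, B, C, AB, AC, BC, ABC`) and `per_set_totals`.
#' @export
triplet_venn <- function(A, B, C, tol = NULL) {
  stopifnot(inherits(A, "loop_set"), inherits(B, "loop_set"),
            inherits(C, "loop_set"))
  if (is.null(tol)) tol <- max(A$resolution, B$resolution, C$resolution)
  if (tol < 0) stop("tol must be non-negative", call. = FALSE)
  cl <- cluster_loops(list(A = A, B = B, C = C), tol)
  regions <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  counts <- setNames(integer(7), regions)
  if (nrow(cl)) {
    membership <- tapply(cl$set, cl$cluster, function(s)
      paste(sort(unique(s)), collapse = ""))
    tab <- table(factor(unname(membership), levels = regions))
    counts[names(tab)] <- as.integer(tab)
  }
  structure(list(set_names = c(A = A$caller, B = B$caller, C = C$caller),
                 region_counts = counts,
                 per_set_totals = c(A = n_loops(A), B = n_loops(B),
                                    C = n_loops(C))),
            class = "triplet_overlap")
}

#' @export
print.triplet_overlap <- function(x, ...) {
  cat("<triplet_overlap>", paste(x$set_names, collapse = " / "), "\n")
  print(x$region_counts)
  invisible(x)
}

#' Percentage of a caller's loops shared by two partner callers
#'
#' Clusters the union of the target set and both partners, then reports
#' 100 x (target loops lying in a cluster containing all three sets) /
#' (target loop count).
#'
#' @param target the [loop_set] being scored.
#' @param others list of the two partner [loop_set]s.
#' @param tol matching tolerance in bp; `NULL` uses the largest resolution
#'   among the three sets.
#' @return overlap percentage in `[0, 100]`.
#' @export
overlap_percentage <- function(target, others, tol = NULL) {
  stopifnot(inherits(target, "loop_set"), length(others) == 2L)
  if (n_loops(target) == 0L)
    stop("overlap percentage undefined for an empty target set",
         call. = FALSE)
  if (is.null(tol))
    tol <- max(target$resolution,
               vapply(others, function(s) s$resolution, 0))
  cl <- cluster_loops(list(T = target, O1 = others[[1]], O2 = others[[2]]),
                      tol)
  sets_by_cluster <- tapply(cl$set, cl$cluster,
                            function(s) length(unique(s)) == 3L)
  shared_clusters <- as.integer(names(sets_by_cluster)[sets_by_cluster])
  n_shared <- sum(cl$set == "T" & cl$cluster %in% shared_clusters)
  100 * n_shared / n_loops(target)
}

#' Mean triplet overlap percentage for one caller
#'
#' Enumerates partner pairs from the pool and averages the per-triplet
#' [overlap_percentage] of the target. The default policy uses all pairs;
#' `policy = "sample"` draws `k` reproducible pairs (seeded), matching
#' workflows that score each tool against a fixed number of partner
#' triplets.
#'
#' @param target the [loop_set] being scored.
#' @param pool list of at least two other [loop_set]s.
#' @param policy `"all"` (default) or `"sample"`.
#' @param k number of sampled pairs when `policy = "sample"` (default 5).
#' @param seed RNG seed for the sampling policy (required with
#'   `"sample"`).
#' @param tol matching tolerance in bp; `NULL` resolves per triplet.
#' @return An object of class `consistency_percent` with fields `caller`,
#'   `triplets_used` (list of partner-name pairs) and `value` (0-100).
#' @export
consistency_percent <- function(target, pool, policy = c("all", "sample"),
                                k = 5, seed = NULL, tol = NULL) {
  policy <- match.arg(policy)
  if (length(pool) < 2L)
    stop("pool must contain at least two other loop sets", call. = FALSE)
  pairs <- combn(seq_along(pool), 2, simplify = FALSE)
  if (policy == "sample") {
    if (is.null(seed))
      stop("policy = 'sample' requires a seed", call. = FALSE)
    if (k > length(pairs))
      stop("k exceeds the number of available partner pairs", call. = FALSE)
    pairs <- with_local_seed(seed, sample(pairs, k))
  }
  pct <- vapply(pairs, function(p)
    overlap_percentage(target, list(pool[[p[1]]], pool[[p[2]]]), tol = tol),
    0)
  structure(list(caller = target$caller,
                 triplets_used = lapply(pairs, function(p)
                   c(pool[[p[1]]]$caller, pool[[p[2]]]$caller)),
                 value = mean(pct)),
            class = "consistency_percent")
}

# Run expr under a temporary RNG seed without disturbing global RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
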