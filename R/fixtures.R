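# Deterministic synthetic-data generators. Reference peaks and loop
# anchors are placed on a guarded lattice (not uniformly at random) so that
# planted truths -- recovery fractions, Venn region counts -- are exact,
# and metric tests can assert equality rather than statistical closeness.

#' Specification for synthetic fixtures
#'
#' @param seed integer seed; all randomness (which references are
#'   recovered, loop shuffling) derives from it. Generators never touch
#'   global RNG state.
#' @param chrom,chrom_size chromosome name and length (bp) the fixture
#'   lives on.
#' @param n_refs number of reference peaks.
#' @param recovery_fraction fraction of references to plant a recovering
#'   loop anchor in; `recovery_fraction * n_refs` is rounded to the nearest
#'   integer.
#' @param n_loops total loops to emit (>= planted recovering loops).
#' @param window_guard minimum distance (bp) between any non-recovering
#'   anchor and any reference; recovery is exact for any analysis window
#'   up to this guard. Default 200.
#' @param ref_width,anchor_width interval widths in bp.
#' @param resolution resolution tag for generated loop sets (bp).
#' @param caller caller tag for generated loop sets.
#' @param venn_design optional named integer vector over
#'   `A,B,C,AB,AC,BC,ABC` giving cluster counts per Venn region.
#' @param match_tol tolerance (bp) at which a Venn design is realized;
#'   defaults to `resolution`.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, chrom = "chrS", chrom_size = 2e8,
                         n_refs = 100L, recovery_fraction = 0.5,
                         n_loops = 200L, window_guard = 200L,
                         ref_width = 100L, anchor_width = 100L,
                         resolution = 10000L, caller = "fixture",
                         venn_design = NULL, match_tol = NULL) {
  if (recovery_fraction < 0 || recovery_fraction > 1)
    stop("recovery_fraction must be in [0, 1]", call. = FALSE)
  if (window_guard < 0) stop("window_guard must be >= 0", call. = FALSE)
  if (is.null(match_tol)) match_tol <- resolution
  structure(list(seed = as.integer(seed), chrom = chrom,
                 chrom_size = chrom_size, n_refs = as.integer(n_refs),
                 recovery_fraction = recovery_fraction,
                 n_loops = as.integer(n_loops),
                 window_guard = as.integer(window_guard),
                 ref_width = as.integer(ref_width),
                 anchor_width = as.integer(anchor_width),
                 resolution = as.numeric(resolution), caller = caller,
                 venn_design = venn_design, match_tol = match_tol),
            class = "fixture_spec")
}

# Gap between consecutive reference intervals; strictly exceeds
# 2 * (window_guard + interval length), the spacing invariant that makes
# window-expanded anchors unable to reach an unintended reference.
ref_gap <- function(spec) 2L * (spec$window_guard + spec$ref_width) + 1L

#' Generate a guarded-lattice reference track
#'
#' Places `n_refs` fixed-width peaks with inter-peak gaps strictly larger
#' than `2 * (window_guard + ref_width)`. Deterministic for a given spec.
#'
#' @param spec a [fixture_spec].
#' @return A [reference_set] named `"synthetic"`.
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$n_refs == 0L)
    return(reference_set("synthetic",
                         data.frame(chrom = character(), start = numeric(),
                                    end = numeric())))
  gap <- ref_gap(spec)
  pitch <- spec$ref_width + gap
  starts <- gap + (seq_len(spec$n_refs) - 1L) * pitch
  ends <- starts + spec$ref_width
  if (ends[spec$n_refs] > spec$chrom_size / 2)
    stop("infeasible spacing: chromosome too small for ", spec$n_refs,
         " guarded references", call. = FALSE)
  reference_set("synthetic",
                data.frame(chrom = spec$chrom, start = starts, end = ends,
                           stringsAsFactors = FALSE))
}

#' Generate loops with an exactly planted recovery fraction
#'
#' Plants one loop anchor inside each of `round(p * n_refs)` references
#' (chosen by the spec seed) and places every other anchor in a decoy zone
#' more than `window_guard` bp from all references, so that for any
#' analysis window up to the guard, [recovery_rate] returns exactly `p`.
#'
#' @param ref the [make_reference] output for the same spec.
#' @param spec a [fixture_spec].
#' @param order `"shuffled"` (seeded, default) or `"recovering_first"`.
#' @return A [loop_set] with names and descending scores in file order.
#' @export
make_loops_with_recovery <- function(ref, spec,
                                     order = c("shuffled",
                                               "recovering_first")) {
  stopifnot(inherits(ref, "reference_set"), inherits(spec, "fixture_spec"))
  order <- match.arg(order)
  p <- spec$recovery_fraction
  n_rec <- as.integer(round(p * n_refs(ref)))
  if (n_rec > spec$n_loops)
    stop("n_loops too small for the requested recovery fraction",
         call. = FALSE)
  aw <- spec$anchor_width
  # decoy anchors live beyond the reference lattice, > guard from all refs
  zone_start <- if (n_refs(ref)) max(ref$intervals$end) +
    4L * (spec$window_guard + spec$ref_width) else ref_gap(spec)
  n_decoys <- n_rec + 2L * (spec$n_loops - n_rec)
  pitch <- aw + 2L * spec$window_guard + 1L
  if (zone_start + n_decoys * pitch + aw > spec$chrom_size)
    stop("not enough free space on the chromosome for ", spec$n_loops,
         " loops", call. = FALSE)
  decoy_starts <- zone_start + (seq_len(max(n_decoys, 1L)) - 1L) * pitch
  rec_refs <- if (n_rec > 0L)
    sort(with_local_seed(spec$seed, sample(n_refs(ref), n_rec))) else integer()
  rows <- vector("list", spec$n_loops)
  di <- 1L
  for (i in seq_len(spec$n_loops)) {
    if (i <= n_rec) {
      rj <- rec_refs[i]
      a1s <- ref$intervals$start[rj] +
        (spec$ref_width - min(aw, spec$ref_width)) %/% 2L
      a1e <- a1s + min(aw, spec$ref_width)
    } else {
      a1s <- decoy_starts[di]; a1e <- a1s + aw; di <- di + 1L
    }
    a2s <- decoy_starts[di]; a2e <- a2s + aw; di <- di + 1L
    rows[[i]] <- data.frame(chrom1 = spec$chrom, start1 = a1s, end1 = a1e,
                            chrom2 = spec$chrom, start2 = a2s, end2 = a2e,
                            stringsAsFactors = FALSE)
  }
  loops <- do.call(rbind, rows)
  if (order == "shuffled" && spec$n_loops > 1L)
    loops <- loops[with_local_seed(spec$seed + 1L,
                                   sample(spec$n_loops)), , drop = FALSE]
  loops$name <- sprintf("loop_%d", seq_len(nrow(loops)))
  loops$score <- rev(seq_len(nrow(loops)))
  loop_set(spec$caller, spec$resolution, loops)
}

#' Generate three loop sets realizing an exact Venn design
#'
#' Builds one loop cluster per requested Venn region occurrence, each
#' cluster a single coordinate shared verbatim by its member sets, with
#' clusters spaced more than twice the matching tolerance apart. At
#' tolerance `spec$match_tol` (or any smaller tolerance), [triplet_venn]
#' recovers the design exactly.
#'
#' @param spec a [fixture_spec] with a `venn_design` (named counts over
#'   `A,B,C,AB,AC,BC,ABC`; absent regions default to 0).
#' @param set_names character(3) caller labels for the generated sets.
#' @return Named list of three [loop_set]s.
#' @export
make_venn_design <- function(spec, set_names = c("A", "B", "C")) {
  stopifnot(inherits(spec, "fixture_spec"))
  regions <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  design <- setNames(integer(7), regions)
  if (!is.null(spec$venn_design)) {
    bad <- setdiff(names(spec$venn_design), regions)
    if (length(bad))
      stop("unknown Venn regions: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(spec$venn_design < 0))
      stop("Venn region counts must be >= 0", call. = FALSE)
    design[names(spec$venn_design)] <- as.integer(spec$venn_design)
  }
  tol <- spec$match_tol
  aw <- spec$anchor_width
  n_clusters <- sum(design)
  pitch <- 4 * tol + 2 * aw + 1
  span <- n_clusters * pitch + 10 * tol + 10L * aw + 1000
  if (n_clusters > 0 && span + n_clusters * pitch + aw > spec$chrom_size)
    stop("infeasible Venn design: chromosome too small", call. = FALSE)
  sets <- setNames(vector("list", 3), c("A", "B", "C"))
  for (s in names(sets)) sets[[s]] <- list()
  ci <- 0L
  for (reg in regions) {
    for (k in seq_len(design[[reg]])) {
      base <- 1000 + ci * pitch
      row <- data.frame(chrom1 = spec$chrom, start1 = base,
                        end1 = base + aw, chrom2 = spec$chrom,
                        start2 = base + span, end2 = base + span + aw,
                        stringsAsFactors = FALSE)
      for (s in strsplit(reg, "")[[1]])
        sets[[s]] <- c(sets[[s]], list(row))
      ci <- ci + 1L
    }
  }
  out <- list()
  for (i in 1:3) {
    s <- c("A", "B", "C")[i]
    df <- if (length(sets[[s]])) do.call(rbind, sets[[s]]) else
      empty_loops_df()
    out[[set_names[i]]] <- loop_set(set_names[i], spec$resolution, df)
  }
  out
}

format_coord <- function(x) formatC(x, format = "d")

#' Write a loop set or reference set to a standard file
#'
#' Loop sets are written as BEDPE (name and score columns included when
#' any are present); reference sets as BED3. Paths ending in `.gz` are
#' gzip-compressed. Output re-parses with [read_bedpe]/[read_bed] to the
#' same coordinates in the same order.
#'
#' @param x a [loop_set] or [reference_set].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fixture <- function(x, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (inherits(x, "loop_set")) {
    lp <- x$loops
    lines <- paste(lp$chrom1, format_coord(lp$start1), format_coord(lp$end1),
                   lp$chrom2, format_coord(lp$start2), format_coord(lp$end2),
                   sep = "\t")
    if (any(!is.na(lp$name)) || any(!is.na(lp$score))) {
      nm <- ifelse(is.na(lp$name), ".", lp$name)
      lines <- paste(lines, nm, sep = "\t")
      if (any(!is.na(lp$score)))
        lines <- paste(lines,
                       ifelse(is.na(lp$score), ".",
                              format(lp$score, scientific = FALSE,
                                     trim = TRUE)),
                       sep = "\t")
    }
  } else if (inherits(x, "reference_set")) {
    iv <- x$intervals
    lines <- paste(iv$chrom, format_coord(iv$start), format_coord(iv$end),
                   sep = "\t")
  } else {
    stop("write_fixture handles loop_set and reference_set objects",
         call. = FALSE)
  }
  writeLines(lines, con)
  invisible(path)
}
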