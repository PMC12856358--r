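# Loop-size statistics per caller/resolution and the regression of
# resolution on mean loop size (overall and per user-defined category).
# Resolution is the dependent variable, size the independent variable.

#' Genomic span of a loop
#'
#' Distance in bp between the two anchor midpoints of an intra-chromosomal
#' loop (non-negative after canonicalization). This is the default "loop
#' size": it is robust to caller-specific anchor widths, which are largely
#' a resolution artifact. The alternative outer extent `end2 - start1` is
#' available via `mode = "extent"`.
#'
#' @param l a single loop (one-row data frame or list with the six anchor
#'   fields); vectorized over rows.
#' @param mode `"midpoint"` (default) or `"extent"`.
#' @return span(s) in bp.
#' @export
loop_span <- function(l, mode = c("midpoint", "extent")) {
  mode <- match.arg(mode)
  l <- canonicalize_anchors(as.data.frame(l, stringsAsFactors = FALSE))
  inter <- l$chrom1 != l$chrom2
  if (any(inter)) {
    warning(sum(inter), " inter-chromosomal loop(s) excluded from span",
            call. = FALSE)
  }
  span <- if (mode == "midpoint")
    (l$start2 + l$end2) / 2 - (l$start1 + l$end1) / 2
  else l$end2 - l$start1
  span[inter] <- NA_real_
  span
}

#' Mean loop size of a caller at one resolution
#'
#' Mean anchor-to-anchor span over the intra-chromosomal loops of the set,
#' reported both in kb and in matrix bins (span / resolution).
#'
#' @param ls a [loop_set].
#' @param mode span definition, see [loop_span].
#' @return An object of class `size_summary` with fields `caller`,
#'   `resolution`, `mean_size_kb`, `mean_size_bins`, `n`.
#' @export
summarize_sizes <- function(ls, mode = c("midpoint", "extent")) {
  stopifnot(inherits(ls, "loop_set"))
  spans <- suppressWarnings(loop_span(ls$loops, mode))
  spans <- spans[!is.na(spans)]
  if (!length(spans))
    stop("no intra-chromosomal loops in set '", ls$caller,
         "': mean size undefined", call. = FALSE)
  structure(list(caller = ls$caller, resolution = ls$resolution,
                 mean_size_kb = mean(spans) / 1000,
                 mean_size_bins = mean(spans) / ls$resolution,
                 n = length(spans)),
            class = "size_summary")
}

#' Ordinary least squares of resolution on size
#'
#' Fits `resolution ~ size` by OLS. One point per caller-resolution pair is
#' the intended use (mean loop size versus the resolution it was called
#' at), so tools far from the fitted line are outliers relative to the
#' size-resolution trend.
#'
#' @param points data frame with columns `size` and `resolution`.
#' @param category optional label carried into the result.
#' @return An object of class `regression_fit` with fields `category`,
#'   `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
ols_fit <- function(points, category = NA_character_) {
  stopifnot(is.data.frame(points),
            all(c("size", "resolution") %in% names(points)))
  if (nrow(points) < 2L)
    stop("need at least 2 points to fit", call. = FALSE)
  if (var(points$size) == 0)
    stop("singular fit: size has zero variance", call. = FALSE)
  fit <- lm(resolution ~ size, data = points)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((points$resolution - mean(points$resolution))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(category = category,
                 slope = unname(coef(fit)[["size"]]),
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 r_squared = r2,
                 n_points = nrow(points)),
            class = "regression_fit")
}

#' Per-category regression fits plus the overall fit
#'
#' Fits `resolution ~ size` within each user-defined category and over all
#' points. Points carry a `label` column mapped to categories by the
#' `categories` named vector (label -> category).
#'
#' @param points data frame with columns `size`, `resolution`, `label`.
#' @param categories named character vector mapping every label to a
#'   category.
#' @return Named list of `regression_fit`s, one per category (categories
#'   with fewer than 2 points or zero size variance are skipped with a
#'   warning) plus an `"overall"` fit.
#' @export
categorical_fits <- function(points, categories) {
  stopifnot(is.data.frame(points),
            all(c("size", "resolution", "label") %in% names(points)))
  unknown <- setdiff(unique(points$label), names(categories))
  if (length(unknown))
    stop("labels without a category: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  points$category <- unname(categories[points$label])
  fits <- list()
  for (cat in unique(points$category)) {
    sub <- points[points$category == cat, , drop = FALSE]
    f <- tryCatch(ols_fit(sub, category = cat), error = function(e) e)
    if (inherits(f, "error")) {
      warning("category '", cat, "' skipped: ", conditionMessage(f),
              call. = FALSE)
    } else {
      fits[[cat]] <- f
    }
  }
  fits[["overall"]] <- ols_fit(points, category = "overall")
  fits
}
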