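# Weighted aggregate scoring: combine per-caller biological, consistency
# (and optionally computational) feature scores into a single weighted mean
# and rank the tools.

#' Biological feature score of one caller
#'
#' Unweighted mean of the caller's REM values across protein reference
#' features (e.g. CTCF, H3K27ac, RNAPII).
#'
#' @param rems named numeric vector, one REM per feature.
#' @return mean REM.
#' @export
biological_score <- function(rems) {
  if (!length(rems)) stop("no REM values supplied", call. = FALSE)
  mean(unlist(rems))
}

#' Weighted aggregate score of feature scores
#'
#' `mu = sum(W_i * X_i) / sum(W_i)` over the supplied feature scores: a
#' convex combination, bounded by the component extremes, invariant under
#' rescaling all weights, and in `[0, 1]` whenever the components are.
#' Higher is better.
#'
#' @param components data frame with columns `value` (feature score,
#'   fractional scale) and `weight` (>= 0; at least one positive).
#' @return the weighted mean `mu`.
#' @export
bcc_score <- function(components) {
  stopifnot(is.data.frame(components),
            all(c("value", "weight") %in% names(components)))
  if (any(components$weight < 0))
    stop("weights must be non-negative", call. = FALSE)
  total <- sum(components$weight)
  if (total <= 0)
    stop("at least one weight must be positive", call. = FALSE)
  sum(components$weight * components$value) / total
}

#' Rank tools by aggregate score
#'
#' Orders results by decreasing `mu`; ties are broken by caller name
#' (lexicographic) so the ranking is deterministic.
#'
#' @param results list of per-caller results as returned by
#'   [compute_bcc_table] (each with fields `caller` and `mu`).
#' @return The list reordered, with a `rank` field (1 = best) set on each
#'   element.
#' @export
rank_tools <- function(results) {
  if (!length(results)) stop("no results to rank", call. = FALSE)
  mus <- vapply(results, function(r) r$mu, 0)
  callers <- vapply(results, function(r) r$caller, "")
  ord <- order(-mus, callers)
  results <- results[ord]
  for (i in seq_along(results)) results[[i]]$rank <- i
  results
}

#' Assemble and rank the weighted score table
#'
#' Combines per-caller consistency percentages (converted to fractions)
#' and biological scores into weighted aggregate scores and ranks the
#' callers. A computational feature score may be supplied (e.g. a
#' runtime-derived score measured by the user); by default only the
#' biological and consistency features carry weight.
#'
#' @param consistency named numeric vector, caller -> overlap percentage
#'   (0-100).
#' @param biological named numeric vector, caller -> mean REM (fractional
#'   scale).
#' @param weights named numeric vector of feature weights; default
#'   `c(biological = 2, consistency = 1)`.
#' @param computational optional named numeric vector, caller ->
#'   computational score (fractional scale); used only when
#'   `weights["computational"]` is positive.
#' @return List of class `bcc_result` elements, ranked (best first), each
#'   with fields `caller`, `mu`, `components` (data frame
#'   `feature`, `value`, `weight`) and `rank`.
#' @export
compute_bcc_table <- function(consistency, biological,
                              weights = c(biological = 2, consistency = 1),
                              computational = NULL) {
  callers <- sort(names(consistency))
  if (!setequal(callers, names(biological)))
    stop("caller sets differ between consistency and biological inputs: ",
         paste(union(setdiff(callers, names(biological)),
                     setdiff(names(biological), callers)), collapse = ", "),
         call. = FALSE)
  use_comp <- !is.null(computational) &&
    isTRUE(weights[["computational"]] > 0)
  if (use_comp && !setequal(callers, names(computational)))
    stop("caller sets differ between consistency and computational inputs",
         call. = FALSE)
  results <- lapply(callers, function(cl) {
    comp <- data.frame(
      feature = c("biological", "consistency"),
      value = c(biological[[cl]], consistency[[cl]] / 100),
      weight = c(weights[["biological"]], weights[["consistency"]]),
      stringsAsFactors = FALSE)
    if (use_comp)
      comp <- rbind(comp, data.frame(feature = "computational",
                                     value = computational[[cl]],
                                     weight = weights[["computational"]],
                                     stringsAsFactors = FALSE))
    structure(list(caller = cl, mu = bcc_score(comp), components = comp),
              class = "bcc_result")
  })
  rank_tools(results)
}

#' Bundled benchmark component scores for 11 loop callers
#'
#' Published consistency and biological component percentages for 11 loop
#' callers evaluated on GM12878 Hi-C data at 10 kb resolution, usable as a
#' worked example for [compute_bcc_table].
#'
#' @return data frame with columns `tool`, `consistency_pct`,
#'   `biological_pct`.
#' @export
gm12878_tool_scores <- function() {
  path <- system.file("extdata", "gm12878_tool_scores.tsv",
                      package = "loopbench", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
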