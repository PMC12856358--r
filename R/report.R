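# Machine-readable report bundle: one JSON document per analysis section
# (overlap, regression, per-feature recovery, aggregate score) with stable
# key ordering and fixed float precision, TSV twins for the tabular
# sections, and a manifest. Reports contain no timestamps, so identical
# inputs produce byte-identical files.

write_json_stable <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(10),
                          pretty = TRUE, na = "null", null = "null",
                          dataframe = "rows")
  writeLines(txt, path)
  path
}

write_tsv_stable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write an analysis result bundle to disk
#'
#' Serializes the bundle produced by [run_job] (or assembled manually) into
#' one JSON file per analysis section -- `overlap.json`, `regression.json`,
#' `recovery_<feature>.json`, `bcc.json` -- plus TSV twins for tabular
#' sections and a `manifest.json` listing the files, package version and
#' seed. Key order and float formatting (10 significant digits) are fixed,
#' so reruns on identical inputs are byte-identical.
#'
#' @param results a `loopbench_results` list (sections optional).
#' @param out_dir output directory, created if needed.
#' @param formats subset of `c("json", "tsv")`.
#' @return Character vector of written paths (manifest last), invisibly.
#' @export
write_report <- function(results, out_dir, formats = c("json", "tsv")) {
  formats <- match.arg(formats, c("json", "tsv"), several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character()
  emit_json <- function(x, name) {
    if ("json" %in% formats)
      paths <<- c(paths, write_json_stable(x, file.path(out_dir, name)))
  }
  emit_tsv <- function(df, name) {
    if ("tsv" %in% formats && is.data.frame(df) && nrow(df))
      paths <<- c(paths, write_tsv_stable(df, file.path(out_dir, name)))
  }
  if (!is.null(results$overlap)) {
    emit_json(results$overlap, "overlap.json")
    emit_tsv(results$overlap$consistency_percent, "overlap_consistency.tsv")
  }
  if (!is.null(results$regression)) {
    emit_json(results$regression, "regression.json")
    emit_tsv(results$regression$sizes, "regression_sizes.tsv")
  }
  for (feature in names(results$recovery)) {
    emit_json(results$recovery[[feature]],
              sprintf("recovery_%s.json", feature))
    emit_tsv(results$recovery[[feature]]$rem_table,
             sprintf("recovery_%s.tsv", feature))
  }
  if (!is.null(results$bcc)) {
    emit_json(results$bcc, "bcc.json")
    emit_tsv(results$bcc$table, "bcc.tsv")
  }
  manifest <- list(
    package = "loopbench",
    version = as.character(packageVersion("loopbench")),
    seed = if (is.null(results$config$seed)) NA else results$config$seed,
    sections = I(sort(setdiff(names(results),
                              c("config", "log", "skipped")))),
    skipped = if (is.null(results$skipped)) I(character()) else
      I(as.character(results$skipped)),
    files = I(sort(basename(paths))))
  paths <- c(paths,
             write_json_stable(manifest, file.path(out_dir, "manifest.json")))
  invisible(paths)
}

fit_to_list <- function(f) {
  list(category = f$category, slope = f$slope, intercept = f$intercept,
       r_squared = f$r_squared, n_points = f$n_points)
}

curve_to_list <- function(cv) {
  list(caller = cv$caller, resolution = cv$resolution,
       points = cv$points, final_delta = cv$final_delta)
}
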