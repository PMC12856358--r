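# End-to-end job runner: validate inputs, run the overlap, regression,
# recovery and scoring analyses, write the report bundle.

#' Build a validated run configuration
#'
#' Collects the inputs and parameters of one comparative analysis job.
#' Defaults follow the standard analysis settings: 50-bp anchor window,
#' high-resolution group {5 kb, 10 kb}, low-resolution group
#' {100 kb, 250 kb}, 1000-loop curve step, weights biological = 2 /
#' consistency = 1, 100 MB per-file size guard.
#'
#' @param loops data frame (or list of lists) with columns `caller`,
#'   `resolution`, `path` -- one BEDPE file per caller-resolution pair.
#' @param references optional data frame (or list of lists) with columns
#'   `feature`, `path` -- BED reference tracks.
#' @param window anchor padding in bp.
#' @param high_res,low_res disjoint resolution groups (bp) for the
#'   consistency score.
#' @param weights named feature weights for the aggregate score.
#' @param tol loop-matching tolerance in bp; `NULL` = per-triplet maximum
#'   resolution.
#' @param count_mode `"reference"` or `"loop"`, see [count_recovered].
#' @param step recovery-curve prefix step in loops.
#' @param out_dir report output directory.
#' @param seed seed echoed into reports (used only by sampling policies).
#' @param normalize_chrom chromosome-name normalization for all inputs.
#' @param max_bytes per-file size guard in bytes.
#' @param categories optional named vector mapping caller -> category for
#'   categorical regression.
#' @return An object of class `run_config`.
#' @export
run_config <- function(loops, references = NULL, window = 50,
                       high_res = c(5000, 10000),
                       low_res = c(100000, 250000),
                       weights = c(biological = 2, consistency = 1),
                       tol = NULL, count_mode = "reference", step = 1000,
                       out_dir = "loopbench_report", seed = 1L,
                       normalize_chrom = "none",
                       max_bytes = 100 * 1024^2, categories = NULL) {
  to_df <- function(x, cols) {
    if (is.null(x)) return(NULL)
    if (!is.data.frame(x))
      x <- do.call(rbind, lapply(x, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    missing <- setdiff(cols, names(x))
    if (length(missing))
      stop("config field missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    x[, cols, drop = FALSE]
  }
  loops <- to_df(loops, c("caller", "resolution", "path"))
  if (is.null(loops) || nrow(loops) == 0L)
    stop("config error: 'loops' must list at least one input file",
         call. = FALSE)
  loops$resolution <- as.numeric(loops$resolution)
  references <- to_df(references, c("feature", "path"))
  if (length(intersect(high_res, low_res)))
    stop("config error: high_res and low_res overlap", call. = FALSE)
  if (window < 0) stop("config error: window must be >= 0", call. = FALSE)
  if (step <= 0) stop("config error: step must be positive", call. = FALSE)
  if (!count_mode %in% c("reference", "loop"))
    stop("config error: count_mode must be 'reference' or 'loop'",
         call. = FALSE)
  for (p in c(loops$path, references$path))
    if (!file.exists(p))
      stop("config error: input file not found: ", p, call. = FALSE)
  structure(list(loops = loops, references = references, window = window,
                 high_res = high_res, low_res = low_res,
                 weights = weights, tol = tol, count_mode = count_mode,
                 step = step, out_dir = out_dir, seed = as.integer(seed),
                 normalize_chrom = normalize_chrom, max_bytes = max_bytes,
                 categories = categories),
            class = "run_config")
}

#' Load a run configuration from a YAML or JSON file
#'
#' The file is parsed by extension (`.yaml`/`.yml` or `.json`), merged
#' over the [run_config] defaults and validated. The resolved
#' configuration is echoed into the report for provenance and reloads to
#' an equivalent configuration.
#'
#' @param path configuration file path.
#' @return An object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.(yaml|yml)$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    stop("config must be a .yaml/.yml or .json file", call. = FALSE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("config error: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(raw$weights)) raw$weights <- unlist(raw$weights)
  if (!is.null(raw$categories)) raw$categories <- unlist(raw$categories)
  do.call(run_config, raw)
}

config_provenance <- function(cfg) {
  list(loops = cfg$loops, references = cfg$references,
       window = cfg$window, high_res = cfg$high_res,
       low_res = cfg$low_res, weights = as.list(cfg$weights),
       tol = cfg$tol, count_mode = cfg$count_mode, step = cfg$step,
       seed = cfg$seed, normalize_chrom = cfg$normalize_chrom,
       categories = as.list(cfg$categories))
}

#' Run a full comparative analysis job
#'
#' Reads and validates every input file, then runs the four analyses --
#' cross-caller overlap (all triplets per resolution), loop-size
#' regression, per-feature recovery (curve, recovery rate, REM,
#' resolution-consistency score) and the weighted aggregate score -- and
#' writes the JSON/TSV report bundle plus a plain-text log. Reports are
#' deterministic: identical inputs and configuration yield byte-identical
#' report files. When no reference tracks are configured, the recovery and
#' scoring sections are marked skipped but overlap and regression are
#' still produced. On error, partially written reports are removed.
#'
#' @param cfg a [run_config].
#' @return The result bundle (class `loopbench_results`), invisibly.
#' @export
run_job <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  sets <- lapply(seq_len(nrow(cfg$loops)), function(i) {
    ls <- read_bedpe(cfg$loops$path[i], cfg$loops$caller[i],
                     cfg$loops$resolution[i],
                     normalize_chrom = cfg$normalize_chrom)
    note("read %s: caller=%s resolution=%g loops=%d", cfg$loops$path[i],
         ls$caller, ls$resolution, n_loops(ls))
    for (w in validate_loop_set(ls, cfg$max_bytes))
      note("warning [%s@%g]: %s", ls$caller, ls$resolution, w)
    ls
  })
  refs <- lapply(seq_len(NROW(cfg$references)), function(i) {
    rf <- read_bed(cfg$references$path[i], cfg$references$feature[i],
                   normalize_chrom = cfg$normalize_chrom)
    note("read %s: feature=%s records=%d", cfg$references$path[i],
         rf$feature, n_refs(rf))
    rf
  })

  results <- structure(list(config = config_provenance(cfg)),
                       class = "loopbench_results")
  skipped <- character()

  # --- overlap / consistency-percentage analysis -------------------------
  resolutions <- sort(unique(vapply(sets, function(s) s$resolution, 0)))
  triplets <- list()
  pct_rows <- list()
  for (res in resolutions) {
    at_res <- sets[vapply(sets, function(s) s$resolution == res, TRUE)]
    if (length(at_res) < 3L) {
      note("overlap at %g bp skipped: fewer than 3 callers", res)
      next
    }
    combos <- combn(length(at_res), 3, simplify = FALSE)
    for (cmb in combos) {
      tv <- triplet_venn(at_res[[cmb[1]]], at_res[[cmb[2]]],
                         at_res[[cmb[3]]], tol = cfg$tol)
      triplets[[length(triplets) + 1L]] <- list(
        resolution = res, set_names = as.list(tv$set_names),
        region_counts = as.list(tv$region_counts),
        per_set_totals = as.list(tv$per_set_totals))
    }
    for (i in seq_along(at_res)) {
      cp <- consistency_percent(at_res[[i]], at_res[-i], tol = cfg$tol)
      pct_rows[[length(pct_rows) + 1L]] <- data.frame(
        caller = cp$caller, resolution = res, value = cp$value,
        n_triplets = length(cp$triplets_used), stringsAsFactors = FALSE)
    }
  }
  consistency_df <- if (length(pct_rows)) do.call(rbind, pct_rows) else NULL
  if (length(triplets) || !is.null(consistency_df)) {
    results$overlap <- list(tol = cfg$tol, triplets = triplets,
                            consistency_percent = consistency_df)
  } else {
    skipped <- c(skipped, "overlap")
  }

  # --- size regression ---------------------------------------------------
  sizes <- do.call(rbind, lapply(sets, function(s) {
    sm <- tryCatch(summarize_sizes(s), error = function(e) NULL)
    if (is.null(sm)) {
      note("size summary skipped for %s@%g: no intra-chromosomal loops",
           s$caller, s$resolution)
      return(NULL)
    }
    data.frame(caller = sm$caller, resolution = sm$resolution,
               mean_size_kb = sm$mean_size_kb,
               mean_size_bins = sm$mean_size_bins, n = sm$n,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(sizes) && nrow(sizes) >= 2L &&
      var(sizes$mean_size_kb) > 0) {
    pts_kb <- data.frame(size = sizes$mean_size_kb,
                         resolution = sizes$resolution,
                         label = sizes$caller, stringsAsFactors = FALSE)
    pts_bins <- data.frame(size = sizes$mean_size_bins,
                           resolution = sizes$resolution,
                           label = sizes$caller, stringsAsFactors = FALSE)
    results$regression <- list(
      sizes = sizes,
      fit_kb = fit_to_list(ols_fit(pts_kb)),
      fit_bins = fit_to_list(ols_fit(pts_bins)))
    if (!is.null(cfg$categories)) {
      results$regression$categorical_kb <-
        lapply(categorical_fits(pts_kb, cfg$categories), fit_to_list)
    }
  } else {
    skipped <- c(skipped, "regression")
    note("regression skipped: fewer than 2 size points or no variance")
  }

  # --- recovery / REM / consistency score --------------------------------
  if (length(refs)) {
    rem_rows <- list()
    results$recovery <- list()
    for (rf in refs) {
      curves <- lapply(sets, function(s)
        recovery_curve(rf, s, window = cfg$window, step = cfg$step))
      tab <- do.call(rbind, lapply(seq_along(sets), function(i) {
        s <- sets[[i]]
        d <- curves[[i]]$final_delta
        data.frame(caller = s$caller, resolution = s$resolution,
                   feature = rf$feature, delta = d, n_loops = n_loops(s),
                   rem = if (n_loops(s) > 0) rem(d, n_loops(s)) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
      rem_rows[[rf$feature]] <- tab
      results$recovery[[rf$feature]] <- list(
        feature = rf$feature, n_ref = n_refs(rf), window = cfg$window,
        curves = lapply(curves, curve_to_list), rem_table = tab)
    }
    rem_all <- do.call(rbind, rem_rows)
    lambda_rows <- list()
    for (cl in unique(rem_all$caller)) {
      sub <- rem_all[rem_all$caller == cl & !is.na(rem_all$rem), ]
      lam <- tryCatch(
        consistency_lambda(data.frame(resolution = sub$resolution,
                                      feature = sub$feature,
                                      rem = sub$rem),
                           high = cfg$high_res, low = cfg$low_res,
                           caller = cl),
        error = function(e) NULL)
      if (is.null(lam)) {
        note("consistency score skipped for %s: incomplete resolution grid",
             cl)
      } else {
        lambda_rows[[cl]] <- data.frame(
          caller = cl, chi_low = lam$chi_low, chi_high = lam$chi_high,
          lambda = lam$value, stringsAsFactors = FALSE)
      }
    }
    if (length(lambda_rows))
      results$consistency_lambda <- do.call(rbind, lambda_rows)

    # --- weighted aggregate score ---------------------------------------
    if (!is.null(consistency_df)) {
      cons <- tapply(consistency_df$value, consistency_df$caller, mean)
      bio_ok <- !is.na(rem_all$rem)
      bio <- tapply(rem_all$rem[bio_ok], rem_all$caller[bio_ok], mean)
      shared <- intersect(names(cons), names(bio))
      if (length(shared)) {
        ranked <- compute_bcc_table(
          consistency = setNames(as.numeric(cons[shared]), shared) ,
          biological = setNames(as.numeric(bio[shared]), shared),
          weights = cfg$weights)
        results$bcc <- list(
          weights = as.list(cfg$weights),
          table = do.call(rbind, lapply(ranked, function(r)
            data.frame(caller = r$caller, mu = r$mu, rank = r$rank,
                       stringsAsFactors = FALSE))),
          components = lapply(ranked, function(r)
            list(caller = r$caller, mu = r$mu, rank = r$rank,
                 components = r$components)))
      } else {
        skipped <- c(skipped, "bcc")
      }
    } else {
      skipped <- c(skipped, "bcc")
      note("aggregate score skipped: no overlap consistency available")
    }
  } else {
    skipped <- c(skipped, "recovery", "bcc")
    note("recovery and aggregate score skipped: no reference tracks")
  }

  results$skipped <- I(sort(skipped))

  # --- write reports; remove partial output on failure -------------------
  written <- character()
  tryCatch({
    written <- write_report(results, cfg$out_dir)
  }, error = function(e) {
    unlink(written)
    stop("report writing failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  })
  note("job finished in %.2f s; %d report file(s) written",
       as.numeric(difftime(Sys.time(), t0, units = "secs")),
       length(written))
  writeLines(log, file.path(cfg$out_dir, "loopbench.log"))
  invisible(results)
}
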