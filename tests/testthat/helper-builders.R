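# Small in-code builders shared across test files.

empty_loops_df_for_test <- function() {
  data.frame(chrom1 = character(), start1 = numeric(), end1 = numeric(),
             chrom2 = character(), start2 = numeric(), end2 = numeric())
}

# loop set from parallel coordinate vectors on one chromosome
mk_loops <- function(s1, s2, width = 100, chrom = "chr1", caller = "t",
                     resolution = 10000) {
  loop_set(caller, resolution, data.frame(
    chrom1 = chrom, start1 = s1, end1 = s1 + width,
    chrom2 = chrom, start2 = s2, end2 = s2 + width,
    stringsAsFactors = FALSE))
}

mk_ref <- function(starts, width = 100, chrom = "chr1", feature = "CTCF") {
  reference_set(feature, data.frame(chrom = chrom, start = starts,
                                    end = starts + width,
                                    stringsAsFactors = FALSE))
}

# a complete small job on disk: 3 callers x the high/low resolution grid,
# 2 reference features, all fixture-generated; returns a run_config
build_fixture_job <- function(dir, seed = 1,
                              resolutions = c(5000, 10000, 1e5, 2.5e5),
                              callers = c("alpha", "beta", "gamma"),
                              n_refs = 40, n_loops = 50, step = 20) {
  rows <- list()
  i <- 0
  for (caller in callers) {
    for (res in resolutions) {
      i <- i + 1
      spec <- fixture_spec(seed = seed + i, n_refs = n_refs,
                           recovery_fraction = 0.5, n_loops = n_loops,
                           resolution = res, caller = caller)
      ls <- make_loops_with_recovery(make_reference(spec), spec)
      p <- file.path(dir, sprintf("%s_%d.bedpe", caller, res))
      write_fixture(ls, p)
      rows[[i]] <- data.frame(caller = caller, resolution = res, path = p,
                              stringsAsFactors = FALSE)
    }
  }
  refs <- data.frame(
    feature = c("CTCF", "H3K27ac"),
    path = file.path(dir, c("ctcf.bed", "h3k27ac.bed")),
    stringsAsFactors = FALSE)
  write_fixture(make_reference(fixture_spec(seed = seed + 100,
                                            n_refs = n_refs)),
                refs$path[1])
  write_fixture(make_reference(fixture_spec(seed = seed + 101,
                                            n_refs = n_refs - 10)),
                refs$path[2])
  run_config(loops = do.call(rbind, rows), references = refs, step = step,
             out_dir = file.path(dir, "report"), seed = seed)
}
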