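# Independent brute-force oracles. These deliberately avoid the package's
# indexed overlap machinery so that index-based results can be checked
# against an O(n*m) scan.

# half-open overlap of two interval rows
naive_pair_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# all-pairs stabbing: for each query row, indices of overlapping intervals
# (scan over every interval per query; no sorting, no index)
naive_query_hits <- function(intervals, queries) {
  lapply(seq_len(nrow(queries)), function(qi) {
    q <- queries[qi, ]
    which(intervals$chrom == q$chrom & intervals$start < q$end &
            q$start < intervals$end)
  })
}

# brute-force recovered-reference count: a reference is recovered when any
# window-expanded anchor of the first `prefix` loops overlaps it
naive_count_recovered <- function(ref_df, loops_df, window, prefix = NULL) {
  if (!is.null(prefix)) loops_df <- loops_df[seq_len(prefix), , drop = FALSE]
  if (nrow(loops_df) == 0L || nrow(ref_df) == 0L) return(0L)
  anchors <- rbind(
    data.frame(chrom = loops_df$chrom1,
               start = pmax(0, loops_df$start1 - window),
               end = loops_df$end1 + window),
    data.frame(chrom = loops_df$chrom2,
               start = pmax(0, loops_df$start2 - window),
               end = loops_df$end2 + window))
  sum(vapply(seq_len(nrow(ref_df)), function(ri) {
    r <- ref_df[ri, ]
    any(anchors$chrom == r$chrom & anchors$start < r$end &
          r$start < anchors$end)
  }, TRUE))
}

# closed-form normal-equations OLS of y on x
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# exact-coordinate Venn oracle for tol = 0 on duplicate-free sets:
# membership by hashed coordinates
venn_hash_oracle <- function(A, B, C) {
  key <- function(ls) paste(ls$loops$chrom1, ls$loops$start1, ls$loops$end1,
                            ls$loops$chrom2, ls$loops$start2, ls$loops$end2)
  ka <- key(A); kb <- key(B); kc <- key(C)
  all_keys <- unique(c(ka, kb, kc))
  member <- vapply(all_keys, function(k)
    paste(c("A", "B", "C")[c(k %in% ka, k %in% kb, k %in% kc)],
          collapse = ""), "")
  counts <- stats::setNames(integer(7),
                            c("A", "B", "C", "AB", "AC", "BC", "ABC"))
  tab <- table(factor(member, levels = names(counts)))
  counts[names(tab)] <- as.integer(tab)
  counts
}

# seeded random interval tables on a few chromosomes
random_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                             max_pos = 10000, max_len = 300) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_loop_set <- function(n, seed, caller = "rnd", resolution = 10000,
                            chroms = c("chr1", "chr2"), max_pos = 10000) {
  a1 <- random_intervals(n, seed, chroms, max_pos)
  a2 <- random_intervals(n, seed + 1000, chroms, max_pos)
  loop_set(caller, resolution,
           data.frame(chrom1 = a1$chrom, start1 = a1$start, end1 = a1$end,
                      chrom2 = a2$chrom, start2 = a2$start, end2 = a2$end,
                      stringsAsFactors = FALSE))
}
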