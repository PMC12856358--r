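test_that("loops_match compares canonical anchor midpoints within tol", {
  a <- data.frame(chrom1 = "chr1", start1 = 1000, end1 = 2000,
                  chrom2 = "chr1", start2 = 9000, end2 = 10000)
  expect_true(loops_match(a, a, tol = 0))
  # midpoints shift by 400 and 200: inside tol 500, outside tol 100
  b <- data.frame(chrom1 = "chr1", start1 = 1400, end1 = 2400,
                  chrom2 = "chr1", start2 = 9200, end2 = 10200)
  expect_true(loops_match(a, b, tol = 500))
  expect_false(loops_match(a, b, tol = 100))
  # boundary: shift of exactly tol matches, tol+1 does not
  shift <- function(d) data.frame(chrom1 = "chr1", start1 = 1000 + d,
                                  end1 = 2000 + d, chrom2 = "chr1",
                                  start2 = 9000, end2 = 10000)
  expect_true(loops_match(a, shift(300), tol = 300))
  expect_false(loops_match(a, shift(301), tol = 300))
  # anchor order is irrelevant after canonicalization
  flipped <- data.frame(chrom1 = "chr1", start1 = 9000, end1 = 10000,
                        chrom2 = "chr1", start2 = 1000, end2 = 2000)
  expect_true(loops_match(a, flipped, tol = 0))
  other_chrom <- data.frame(chrom1 = "chr2", start1 = 1000, end1 = 2000,
                            chrom2 = "chr2", start2 = 9000, end2 = 10000)
  expect_false(loops_match(a, other_chrom, tol = 1e6))
})

test_that("triplet_venn counts disjoint and identical sets correctly", {
  A <- mk_loops(s1 = c(1e4, 2e6), s2 = c(5e6, 6e6), caller = "a")
  B <- mk_loops(s1 = c(1e7, 2e7, 3e7), s2 = c(8e7, 8.1e7, 8.2e7),
                caller = "b")
  C <- mk_loops(s1 = 4e7 + (1:4) * 1e5, s2 = 9e7 + (1:4) * 1e5,
                caller = "c")
  tv <- triplet_venn(A, B, C, tol = 0)
  expect_equal(unname(tv$region_counts[c("A", "B", "C")]), c(2L, 3L, 4L))
  expect_equal(sum(tv$region_counts[c("AB", "AC", "BC", "ABC")]), 0L)
  expect_equal(unname(tv$per_set_totals), c(2L, 3L, 4L))
  same <- mk_loops(s1 = (1:5) * 1e6, s2 = (1:5) * 1e6 + 5e6)
  tv2 <- triplet_venn(same, same, same, tol = 0)
  expect_equal(unname(tv2$region_counts["ABC"]), 5L)
  expect_equal(sum(tv2$region_counts), 5L)
})

test_that("designed fixtures reproduce their Venn regions exactly", {
  spec <- fixture_spec(seed = 2, venn_design = c(A = 2, AB = 1, ABC = 1))
  sets <- make_venn_design(spec)
  tv <- triplet_venn(sets$A, sets$B, sets$C, tol = spec$match_tol)
  expect_equal(unname(tv$region_counts),
               c(2L, 0L, 0L, 1L, 0L, 0L, 1L))
})

test_that("triplet_venn is invariant to loop order and equivariant to set relabeling", {
  spec <- fixture_spec(seed = 4,
                       venn_design = c(A = 1, B = 2, C = 1, AB = 2,
                                       BC = 1, ABC = 3))
  sets <- make_venn_design(spec)
  tv <- triplet_venn(sets$A, sets$B, sets$C, tol = spec$match_tol)
  # shuffle loops inside each set
  shuf <- lapply(sets, function(s) {
    s$loops <- s$loops[rev(seq_len(nrow(s$loops))), , drop = FALSE]
    s
  })
  tv_shuf <- triplet_venn(shuf$A, shuf$B, shuf$C, tol = spec$match_tol)
  expect_equal(tv_shuf$region_counts, tv$region_counts)
  # swap sets A and B: region keys permute accordingly
  tv_swap <- triplet_venn(sets$B, sets$A, sets$C, tol = spec$match_tol)
  expect_equal(unname(tv_swap$region_counts[c("A", "B")]),
               unname(tv$region_counts[c("B", "A")]))
  expect_equal(unname(tv_swap$region_counts[c("AC", "BC")]),
               unname(tv$region_counts[c("BC", "AC")]))
  expect_equal(unname(tv_swap$region_counts["ABC"]),
               unname(tv$region_counts["ABC"]))
})

test_that("at tol 0, duplicate-free clustering equals hash intersection", {
  for (seed in 1:15) {
    set.seed(seed)
    # build three sets sharing coordinates by construction, duplicate-free
    universe <- mk_loops(s1 = (1:40) * 1e5, s2 = (1:40) * 1e5 + 5e7)
    pick <- function() {
      s <- universe
      keep <- sort(sample(40, sample(5:30, 1)))
      s$loops <- s$loops[keep, , drop = FALSE]
      s
    }
    A <- pick(); B <- pick(); C <- pick()
    tv <- triplet_venn(A, B, C, tol = 0)
    expect_equal(tv$region_counts, venn_hash_oracle(A, B, C),
                 info = paste("seed", seed))
  }
})

test_that("overlap_percentage counts triple-shared target loops", {
  spec <- fixture_spec(seed = 5, venn_design = c(A = 6, ABC = 2))
  sets <- make_venn_design(spec)
  # 2 of 8 loops of A sit in triple-shared clusters
  expect_equal(overlap_percentage(sets$A, list(sets$B, sets$C),
                                  tol = spec$match_tol), 25)
  same <- mk_loops(s1 = (1:5) * 1e6, s2 = (1:5) * 1e6 + 5e6)
  expect_equal(overlap_percentage(same, list(same, same), tol = 0), 100)
  far_b <- mk_loops(s1 = 1e8 + (1:3) * 1e6, s2 = 1.5e8 + (1:3) * 1e6)
  expect_equal(overlap_percentage(same, list(far_b, far_b), tol = 0), 0)
  empty <- loop_set("t", 1e4, empty_loops_df_for_test())
  expect_error(overlap_percentage(empty, list(same, same)), "empty")
})

test_that("overlap_percentage is monotone non-decreasing in tol", {
  A <- random_loop_set(30, 7, chroms = "chr1", max_pos = 50000)
  B <- random_loop_set(30, 8, chroms = "chr1", max_pos = 50000)
  C <- random_loop_set(30, 9, chroms = "chr1", max_pos = 50000)
  pct <- vapply(c(0, 100, 1000, 10000, 1e5), function(tol)
    overlap_percentage(A, list(B, C), tol = tol), 0)
  expect_true(all(diff(pct) >= 0))
})

test_that("consistency_percent averages triplets under both policies", {
  spec <- fixture_spec(seed = 6, venn_design = c(A = 6, ABC = 2))
  sets <- make_venn_design(spec)
  # pool of exactly two -> one triplet, equals that overlap percentage
  cp <- consistency_percent(sets$A, list(sets$B, sets$C),
                            tol = spec$match_tol)
  expect_equal(cp$value, 25)
  expect_length(cp$triplets_used, 1)
  # identical sets -> 100 regardless of pool size
  same <- mk_loops(s1 = (1:5) * 1e6, s2 = (1:5) * 1e6 + 5e6)
  pool <- replicate(4, same, simplify = FALSE)
  expect_equal(consistency_percent(same, pool)$value, 100)
  expect_error(consistency_percent(same, pool[1]), "at least two")
  # sampling policy is reproducible and a subset of the exhaustive pairs
  pool10 <- lapply(1:10, function(i)
    random_loop_set(20, 40 + i, chroms = "chr1", max_pos = 50000))
  target <- random_loop_set(20, 39, chroms = "chr1", max_pos = 50000)
  s1 <- consistency_percent(target, pool10, policy = "sample", k = 5,
                            seed = 7, tol = 500)
  s2 <- consistency_percent(target, pool10, policy = "sample", k = 5,
                            seed = 7, tol = 500)
  expect_equal(s1$value, s2$value)
  expect_equal(s1$triplets_used, s2$triplets_used)
  expect_length(s1$triplets_used, 5)
  expect_error(consistency_percent(target, pool10, policy = "sample",
                                   k = 5), "seed")
})
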