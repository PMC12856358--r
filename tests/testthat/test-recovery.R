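test_that("count_recovered counts distinct recovered reference records", {
  ref <- mk_ref(c(100, 500))
  # anchor inside the first peak, window 0
  ls <- mk_loops(s1 = 150, s2 = 5000, width = 10)
  expect_equal(count_recovered(ref, ls, window = 0), 1)
  # anchor 10 bp past the first peak: missed at window 0, hit at window 50
  ls2 <- mk_loops(s1 = 210, s2 = 5000, width = 40)
  expect_equal(count_recovered(ref, ls2, window = 0), 0)
  expect_equal(count_recovered(ref, ls2, window = 50), 1)
  # several loops on one peak still count it once
  ls3 <- mk_loops(s1 = c(110, 120, 130), s2 = rep(5000, 3), width = 10)
  expect_equal(count_recovered(ref, ls3, window = 0), 1)
  # empty loop set recovers nothing
  expect_equal(count_recovered(ref, loop_set("t", 1e4,
                                             empty_loops_df_for_test())), 0)
})

test_that("either anchor recovers a reference; loop mode counts loops", {
  ref <- mk_ref(c(100, 5000))
  ls <- mk_loops(s1 = 120, s2 = 5020, width = 10)
  expect_equal(count_recovered(ref, ls, window = 0), 2)
  expect_equal(count_recovered(ref, ls, window = 0, count_mode = "loop"), 1)
})

test_that("count_recovered matches the brute-force scan on random data", {
  for (seed in 1:30) {
    nr <- sample(1:60, 1)
    nl <- sample(1:60, 1)
    w <- sample(c(0, 25, 50, 120), 1)
    ref <- reference_set("f", random_intervals(nr, seed))
    ls <- random_loop_set(nl, seed + 100)
    expect_equal(count_recovered(ref, ls, window = w),
                 naive_count_recovered(ref$intervals, ls$loops, w),
                 info = paste("seed", seed))
  }
})

test_that("count_recovered is monotone in prefix and window", {
  ref <- reference_set("f", random_intervals(40, 5))
  ls <- random_loop_set(50, 6)
  counts <- vapply(seq(0, 50, 10), function(k)
    count_recovered(ref, ls, window = 20, prefix = k), 0)
  expect_true(all(diff(counts) >= 0))
  by_window <- vapply(c(0, 10, 50, 200), function(w)
    count_recovered(ref, ls, window = w), 0)
  expect_true(all(diff(by_window) >= 0))
})

test_that("recovery_rate spans 0 to 1 and errors on empty references", {
  ref <- mk_ref(c(100, 500, 900, 1300))
  none <- mk_loops(s1 = 50000, s2 = 90000)
  expect_equal(recovery_rate(ref, none, window = 0), 0)
  all_hit <- mk_loops(s1 = c(110, 910), s2 = c(510, 1310), width = 10)
  expect_equal(recovery_rate(ref, all_hit, window = 0), 1)
  half <- mk_loops(s1 = c(110, 910), s2 = c(50000, 90000), width = 10)
  expect_equal(recovery_rate(ref, half, window = 0), 0.5)
  empty_ref <- reference_set("f", data.frame(chrom = character(),
                                             start = numeric(),
                                             end = numeric()))
  expect_error(recovery_rate(empty_ref, all_hit), "empty")
})

test_that("recovery_curve prefixes follow the step rule", {
  grid <- list(c(999, 1), c(1000, 1), c(1001, 2), c(2500, 3))
  for (g in grid) {
    n <- g[1]
    ls <- random_loop_set(n, seed = n, max_pos = 1e6)
    cv <- recovery_curve(mk_ref(c(100, 500)), ls, window = 0, step = 1000)
    ks <- cv$points$k
    expect_length(ks, g[2])
    expect_equal(ks[length(ks)], n)
    expect_true(all(head(ks, -1) == 1000 * seq_len(length(ks) - 1)))
  }
})

test_that("recovery_curve is cumulative, monotone and ends at the total", {
  ref <- reference_set("f", random_intervals(50, 21))
  ls <- random_loop_set(87, 22)
  cv <- recovery_curve(ref, ls, window = 30, step = 10)
  expect_true(all(diff(cv$points$delta) >= 0))
  expect_true(all(cv$points$delta >= 0 & cv$points$delta <= 1))
  expect_equal(cv$final_delta, recovery_rate(ref, ls, window = 30))
  # every point equals the prefix recovery rate computed independently
  for (i in seq_len(nrow(cv$points))) {
    expect_equal(cv$points$delta[i],
                 naive_count_recovered(ref$intervals, ls$loops, 30,
                                       prefix = cv$points$k[i]) / n_refs(ref))
  }
})

test_that("planted staged fixture gives the designed curve", {
  # 20 peaks; first 10 loops recover peaks 1-2, next 10 recover peaks 3-4
  ref <- mk_ref(seq(0, 19) * 10000 + 1000, width = 100)
  hit_starts <- ref$intervals$start[1:4] + 20
  decoys <- 5e6 + seq_len(16) * 2000
  s1 <- c(hit_starts[1:2], decoys[1:8], hit_starts[3:4], decoys[9:16])
  ls <- mk_loops(s1 = s1, s2 = 8e6 + seq_along(s1) * 2000, width = 50)
  cv <- recovery_curve(ref, ls, window = 50, step = 10)
  expect_equal(cv$points$k, c(10, 20))
  expect_equal(cv$points$delta, c(0.10, 0.20))
})

test_that("score_desc ordering reorders the curve stably", {
  ref <- mk_ref(c(1000))
  df <- data.frame(chrom1 = "chr1", start1 = c(5e5, 1010, 6e5),
                   end1 = c(5e5, 1010, 6e5) + 50,
                   chrom2 = "chr1", start2 = 7e5 + 1:3 * 1000,
                   end2 = 7e5 + 1:3 * 1000 + 50,
                   score = c(1, 9, 5))
  ls <- loop_set("t", 1e4, df)
  cv <- recovery_curve(ref, ls, window = 0, step = 1, order = "score_desc")
  # highest-scoring loop (the recovering one) comes first
  expect_equal(cv$points$delta, c(1, 1, 1))
  cv_file <- recovery_curve(ref, ls, window = 0, step = 1)
  expect_equal(cv_file$points$delta, c(0, 1, 1))
  no_score <- mk_loops(s1 = 100, s2 = 1e5)
  expect_error(recovery_curve(ref, no_score, order = "score_desc"),
               "score")
})

test_that("rem divides the rate by loop count and scales inversely", {
  expect_equal(rem(0, 100), 0)
  expect_equal(rem(0.5, 1000), 5e-4)
  expect_equal(rem(0.4, 2000), rem(0.4, 1000) / 2)
  expect_error(rem(0.5, 0), "positive")
  # Eq identity at tight tolerance
  for (seed in 1:20) {
    set.seed(seed)
    d <- runif(1)
    n <- sample(1:1e6, 1)
    expect_equal(rem(d, n) * n, d, tolerance = 1e-12)
  }
})

test_that("consistency score is the gap between group REM means", {
  rems <- expand.grid(resolution = c(5000, 10000, 100000, 250000),
                      feature = c("CTCF", "H3K27ac"),
                      stringsAsFactors = FALSE)
  rems$rem <- 3e-4
  lam <- consistency_lambda(rems)
  expect_equal(lam$value, 0)
  rems$rem <- ifelse(rems$resolution %in% c(5000, 10000), 2e-4, 5e-4)
  lam2 <- consistency_lambda(rems)
  expect_equal(lam2$chi_high, 2e-4)
  expect_equal(lam2$chi_low, 5e-4)
  expect_equal(lam2$value, 3e-4)
  # symmetric under swapping the groups
  swapped <- consistency_lambda(rems, high = c(100000, 250000),
                                low = c(5000, 10000))
  expect_equal(swapped$value, lam2$value)
})

test_that("consistency score reports missing resolution-feature cells", {
  rems <- data.frame(resolution = c(5000, 10000, 100000),
                     feature = "CTCF", rem = 1e-4)
  expect_error(consistency_lambda(rems), "250000.*CTCF")
  expect_error(consistency_lambda(rems, high = c(5000), low = c(5000)),
               "disjoint")
  expect_error(consistency_lambda(rems, high = numeric(), low = 1e5),
               "non-empty")
})
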