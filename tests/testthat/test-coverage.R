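test_that("uniform depth gives step covered_at and exact mean", {
  targets <- normalize_intervals(interval_set(
    data.frame(chrom = "1", start = 0, end = 1000)))
  prof <- depth_profile(data.frame(chrom = "1", start = 0, end = 1000,
                                   depth = 10))
  cs <- coverage_summary(prof, targets, thresholds = c(10, 11))
  expect_equal(cs$mean_coverage, 10)
  expect_equal(unname(cs$covered_at), c(1, 0))
})

test_that("mixed-depth target matches hand computation", {
  targets <- normalize_intervals(interval_set(
    data.frame(chrom = "1", start = 0, end = 10)))
  prof <- depth_profile(data.frame(chrom = "1", start = c(0, 6),
                                   end = c(6, 10), depth = c(5, 20)))
  cs <- coverage_summary(prof, targets, thresholds = c(1, 10))
  expect_equal(cs$mean_coverage, (5 * 6 + 20 * 4) / 10)  # 11.0
  expect_equal(unname(cs$covered_at["10"]), 0.4)
})

test_that("coverage summaries equal a per-base oracle on random data", {
  set.seed(14)
  L <- 10000
  targets <- normalize_intervals(random_interval_set(30, "1", L))
  runs <- data.frame(start = seq(0, L - 100, by = 100))
  runs$end <- runs$start + 100
  runs$chrom <- "1"
  runs$depth <- rpois(nrow(runs), 12)
  prof <- depth_profile(runs)
  thresholds <- c(1, 5, 10, 20)
  cs <- coverage_summary(prof, targets, thresholds)
  # per-base oracle
  depth_vec <- numeric(L)
  for (i in seq_len(nrow(runs))) {
    depth_vec[(runs$start[i] + 1):runs$end[i]] <- runs$depth[i]
  }
  tmask <- unlist(oracle_membership(targets, "1", L))
  expect_equal(cs$mean_coverage, sum(depth_vec[tmask]) / sum(tmask))
  for (t in thresholds) {
    expect_equal(unname(cs$covered_at[as.character(t)]),
                 mean(depth_vec[tmask] >= t))
  }
  # bases missing from the profile count as zero depth
  half <- depth_profile(runs[runs$start < L / 2, ])
  cs2 <- coverage_summary(half, targets, 1)
  depth_vec2 <- depth_vec
  depth_vec2[(L / 2 + 1):L] <- 0
  expect_equal(cs2$mean_coverage, sum(depth_vec2[tmask]) / sum(tmask))
})

test_that("covered_at is monotone non-increasing in the threshold", {
  set.seed(15)
  tg <- sim_targets(300, seed = 1)
  prof <- sim_depth_profile(tg, mean_depth = 40, dispersion = 0.3,
                            seed = 2)
  cs <- coverage_summary(prof, tg, thresholds = c(1, 5, 10, 20, 30, 60))
  expect_true(all(diff(cs$covered_at) <= 0))
  expect_error(coverage_summary(
    prof, interval_set(data.frame(chrom = character(), start = numeric(),
                                  end = numeric()))), "empty")
})

test_that("binomial thinning never increases covered_at on average", {
  set.seed(16)
  tg <- sim_targets(300, seed = 3)
  prof <- sim_depth_profile(tg, mean_depth = 30, dispersion = 0.2,
                            seed = 4)
  full <- coverage_summary(prof, tg, 10)$covered_at
  thinned <- vapply(1:5, function(s) {
    set.seed(100 + s)
    thin <- prof
    thin$depth <- rbinom(nrow(thin), size = round(thin$depth), prob = 0.6)
    coverage_summary(depth_profile(thin), tg, 10)$covered_at
  }, numeric(1))
  expect_lte(mean(thinned), full)
})

test_that("category fractions sum to one and recover generator rates", {
  cc <- read_category_counts(data.frame(
    sample = "s", on_target = 90, off_target = 7, duplicates = 2,
    un_aligned = 1))
  f <- category_fractions(cc)
  expect_equal(unlist(f[1, -1], use.names = FALSE),
               c(0.90, 0.07, 0.02, 0.01))
  all_on <- category_fractions(read_category_counts(data.frame(
    sample = "s", on_target = 10, off_target = 0, duplicates = 0,
    un_aligned = 0)))
  expect_equal(unlist(all_on[1, -1], use.names = FALSE), c(1, 0, 0, 0))
  expect_error(category_fractions(read_category_counts(data.frame(
    sample = "s", on_target = 0, off_target = 0, duplicates = 0,
    un_aligned = 0))), "zero")
  # multinomial sampling at n reads: recovered fraction within 4 sd
  n <- 50000
  sim <- sim_read_categories(1, total_reads = n,
                             fractions = c(on_target = 0.865,
                                           off_target = 0.071,
                                           duplicates = 0.059,
                                           un_aligned = 0.005),
                             seed = 8)
  fr <- category_fractions(sim)
  for (cat in c("off_target", "duplicates")) {
    p <- c(off_target = 0.071, duplicates = 0.059)[[cat]]
    expect_lt(abs(fr[[cat]] - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("read-category tables must balance and round-trip", {
  expect_error(read_category_counts(data.frame(
    sample = "s", on_target = 9, off_target = 0, duplicates = 0,
    un_aligned = 0, total = 10)), "sum")
  sim <- sim_read_categories(3, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(sim, path)
  back <- read_counts_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(sim))
})

test_that("gc_depth_grid bins, excludes bounds, and normalizes", {
  g <- gc_depth_grid(0.5, 500)
  expect_equal(g$n_points_in_bounds, 1)
  expect_equal(sum(g$grid == 1), 1)
  expect_equal(sum(g$grid), 1)
  expect_equal(dim(g$grid), c(200, 100))
  # points on or outside the open rectangle are excluded
  out <- gc_depth_grid(c(0.5, 0, 1, 0.3), c(1500, 500, 500, 1000))
  expect_equal(out$n_points_in_bounds, 0)
  expect_equal(max(out$grid), 0)
})

test_that("grid counts are conserved and min-max normalized", {
  set.seed(18)
  n <- 10000
  gc <- runif(n, -0.1, 1.1)
  depth <- runif(n, -50, 1200)
  g <- gc_depth_grid(gc, depth)
  expect_equal(sum(g$counts), g$n_points_in_bounds)
  expect_equal(g$n_points_in_bounds,
               sum(gc > 0 & gc < 1 & depth > 0 & depth < 1000))
  expect_equal(max(g$grid), 1)
  expect_equal(min(g$grid), 0)
  expect_equal(g$grid, (g$counts - min(g$counts)) /
                 (max(g$counts) - min(g$counts)))
})

test_that("pool quantile function is the sorted empirical CDF", {
  pq <- pool_quantile(c(4, 2, 3, 1))
  expect_equal(pq$points$total, 1:4)
  expect_equal(pq$points$prop, c(0.25, 0.5, 0.75, 1))
  expect_equal(pq$delta, 3)
  expect_true(all(diff(pq$points$prop) >= 0))
  expect_equal(fraction_below(pq, 1), 0)
  expect_equal(fraction_below(pq, 4.5), 1)
  expect_equal(fraction_below(pq, 3), 0.5)
  flat <- pool_quantile(rep(7, 5))
  expect_equal(flat$delta, 0)
  expect_equal(unique(flat$points$total), 7)
  expect_error(pool_quantile(numeric()), "empty")
})

test_that("imbalanced pools show larger delta and earlier quantile mass", {
  bal <- sim_pool(12, imbalance_sigma = 0.05, seed = 9)
  imb <- sim_pool(12, imbalance_sigma = 0.6, seed = 9)
  pq_bal <- pool_quantile(bal$total_mb)
  pq_imb <- pool_quantile(imb$total_mb)
  expect_gt(pq_imb$delta, pq_bal$delta)
  expect_gt(fraction_below(pq_imb, 12000), fraction_below(pq_bal, 12000))
})

test_that("bedGraph writing round-trips through the reader", {
  set.seed(19)
  tg <- sim_targets(50, seed = 5)
  prof <- sim_depth_profile(tg, seed = 6)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(prof, path)
  back <- read_bedgraph(path)
  expect_equal(as.data.frame(back), as.data.frame(prof))
})
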