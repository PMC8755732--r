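test_that("generators are reproducible for a fixed seed", {
  t1 <- sim_targets(100, seed = 5)
  t2 <- sim_targets(100, seed = 5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  tr1 <- sim_truth(t1, seed = 6)
  tr2 <- sim_truth(t2, seed = 6)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  em <- error_model(miss_rate = 0.1, spurious_per_mb = 30)
  c1 <- sim_calls(tr1, t1, em, seed = 7)
  c2 <- sim_calls(tr2, t2, em, seed = 7)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_false(identical(as.data.frame(sim_calls(tr1, t1, em, seed = 8)),
                         as.data.frame(c1)))
})

test_that("target generator honours size and GC distributions", {
  fixed <- sim_targets(200, median_size = 210, size_sdlog = 0, seed = 1)
  expect_true(all(fixed$end - fixed$start == 210))
  expect_equal(interval_summary(fixed)$median_region_size, 210)
  # targets are disjoint and sorted by construction
  expect_equal(total_bases(fixed), sum(fixed$end - fixed$start))
  big <- sim_targets(10000, seed = 2)
  expect_true(all(big$gc > 0 & big$gc < 1))
  # bimodal mixture: oracle sample from the same mixture, KS-compatible
  set.seed(99)
  comp <- rbinom(10000, 1, 0.45) + 1
  want <- pmin(0.99, pmax(0.01, rnorm(
    10000, c(0.38, 0.55)[comp], c(0.06, 0.07)[comp])))
  ks <- suppressWarnings(ks.test(big$gc, want))
  expect_gt(ks$p.value, 0.01)
})

test_that("truth generator matches requested densities and genotypes", {
  tg <- sim_targets(2000, median_size = 500, seed = 3)
  expect_equal(nrow(sim_truth(tg, snv_per_mb = 0, indel_per_mb = 0,
                              seed = 1)), 0)
  mb <- total_bases(tg) / 1e6
  tr <- sim_truth(tg, snv_per_mb = 1000, indel_per_mb = 0, seed = 4)
  lam <- 1000 * mb
  expect_lt(abs(nrow(tr) - lam), 4 * sqrt(lam))  # Poisson CI
  allhet <- sim_truth(tg, het_fraction = 1, seed = 5)
  expect_true(all(allhet$genotype == "0/1"))
  # positions land inside targets and are collision-free
  allhet$depth <- 60
  allhet$qual <- 60
  f <- filter_variants(allhet, min_depth = -1, min_qual = -1,
                       targets = tg, strict = FALSE)
  expect_equal(nrow(f), nrow(allhet))
  expect_false(any(duplicated(paste(allhet$chrom, allhet$pos))))
})

test_that("zero-error calls reproduce the truth exactly", {
  tg <- sim_targets(400, seed = 6)
  tr <- sim_truth(tg, seed = 7)
  cl <- sim_calls(tr, tg, zero_error_model(), seed = 8)
  expect_equal(cl[c("chrom", "pos", "ref", "alt", "genotype")],
               as.data.frame(tr)[c("chrom", "pos", "ref", "alt",
                                   "genotype")],
               ignore_attr = TRUE)
  expect_true(all(cl$depth == 60) && all(cl$qual == 60))
  jc <- match_truth(cl, tr)
  expect_equal(jc$in_pg_snv + jc$in_pg_indel, nrow(tr))
  expect_equal(unlist(compute_metrics(jc)),
               c(snv_sensitivity = 1, snv_precision = 1, snv_f = 1,
                 indel_sensitivity = 1, indel_precision = 1,
                 indel_f = 1))
})

test_that("a total class swap sends every call to the other class", {
  tg <- sim_targets(300, seed = 9)
  tr <- sim_truth(tg, indel_per_mb = 0, seed = 10)  # SNVs only
  cl <- sim_calls(tr, tg, error_model(type_swap_rate = 1), seed = 11)
  jc <- match_truth(cl, tr)
  expect_equal(jc$not_in_pg_indel, nrow(tr))
  expect_equal(jc$in_pg_snv + jc$in_pg_indel + jc$not_in_pg_snv, 0)
  expect_equal(jc$pg_specific_snv, nrow(tr))
})

test_that("miss rate 1 leaves only spurious calls", {
  tg <- sim_targets(300, median_size = 2000, seed = 12)
  tr <- sim_truth(tg, seed = 13)
  cl <- sim_calls(tr, tg, error_model(miss_rate = 1,
                                      spurious_per_mb = 100), seed = 14)
  jc <- match_truth(cl, tr)
  expect_equal(jc$pg_specific_snv + jc$pg_specific_indel, nrow(tr))
  expect_equal(jc$in_pg_snv + jc$in_pg_indel +
                 jc$not_in_pg_snv + jc$not_in_pg_indel, 0)
  expect_equal(jc$sample_specific_snv + jc$sample_specific_indel,
               nrow(cl))
  expect_gt(nrow(cl), 0)
})

test_that("emitted plus missed truth variants conserve the truth size", {
  tg <- sim_targets(300, seed = 15)
  tr <- sim_truth(tg, seed = 16)
  em <- error_model(miss_rate = 0.3)
  cl <- sim_calls(tr, tg, em, seed = 17)
  expect_equal(nrow(cl) + attr(cl, "n_missed"), nrow(tr))
})

test_that("expected_confusion matches trivial boundary models", {
  ec0 <- expected_confusion(100, 10, zero_error_model(), target_mb = 1)
  expect_equal(ec0$expected,
               c(in_pg_snv = 100, not_in_pg_snv = 0, in_pg_indel = 10,
                 not_in_pg_indel = 0, pg_specific_snv = 0,
                 pg_specific_indel = 0, sample_specific_snv = 0,
                 sample_specific_indel = 0))
  ec1 <- expected_confusion(100, 10, error_model(miss_rate = 1,
                                                 spurious_per_mb = 5),
                            target_mb = 2)
  expect_equal(unname(ec1$expected["pg_specific_snv"]), 100)
  expect_equal(unname(ec1$expected["pg_specific_indel"]), 10)
  expect_equal(unname(ec1$expected["in_pg_snv"]), 0)
  expect_equal(unname(ec1$expected[["sample_specific_snv"]] +
                        ec1$expected[["sample_specific_indel"]]), 10)
})

test_that("simulated tallies agree with the closed form (Monte Carlo)", {
  tg <- sim_targets(500, median_size = 2000, seed = 18)
  tr <- sim_truth(tg, snv_per_mb = 2000, indel_per_mb = 200, seed = 19)
  n_snv <- sum(tr$vclass == "SNV")
  n_indel <- nrow(tr) - n_snv
  em <- error_model(miss_rate = 0.1, spurious_per_mb = 20,
                    type_swap_rate = 0.02, genotype_error_rate = 0.03)
  ec <- expected_confusion(n_snv, n_indel, em,
                           target_mb = total_bases(tg) / 1e6)
  reps <- 40
  sums <- NULL
  for (r in seq_len(reps)) {
    jc <- match_truth(sim_calls(tr, tg, em, seed = 1000 + r), tr)
    sums <- rbind(sums, unlist(jc)[names(ec$expected)])
  }
  mc_mean <- colMeans(sums)
  tol <- 3 * ec$sd / sqrt(reps) + 1e-9
  for (k in names(ec$expected)) {
    expect_lt(abs(mc_mean[[k]] - ec$expected[[k]]), tol[[k]] + 0.5)
  }
})

test_that("GC bias curve is unimodal, normalized, and shapes coverage", {
  bias <- gc_bias_curve()
  expect_equal(bias(0.5), 1)
  expect_lt(bias(0.1), bias(0.3))
  expect_lt(bias(0.95), bias(0.6))
  expect_true(all(bias(seq(0, 1, 0.01)) >= 0))
  # simulated depth shows depressed coverage at GC extremes; spread the
  # per-target GC over the whole unit interval to probe both shoulders
  tg <- sim_targets(3000, seed = 20)
  tg$gc <- seq(0.002, 0.998, length.out = nrow(tg))
  prof <- sim_depth_profile(tg, bias = bias, mean_depth = 200,
                            dispersion = 0.05, seed = 21)
  extreme <- tg$gc < 0.2 | tg$gc > 0.8
  expect_lt(mean(prof$depth[extreme]), mean(prof$depth[!extreme]))
  mid <- tg$gc > 0.35 & tg$gc < 0.65
  expect_gt(mean(prof$depth[mid]), 0.9 * 200)
  # monotone trend below the low-GC shoulder: rank correlation > 0
  low <- tg$gc < 0.25
  expect_gt(cor(tg$gc[low], prof$depth[low], method = "spearman"), 0.3)
})

test_that("degenerate simulator settings behave deterministically", {
  tg <- sim_targets(200, seed = 22)
  flat <- sim_depth_profile(tg, bias = function(gc) rep(1, length(gc)),
                            mean_depth = 50, dispersion = 0, seed = 23)
  expect_true(all(flat$depth == 50))
  cs <- coverage_summary(flat, tg, thresholds = c(50, 51))
  expect_equal(unname(cs$covered_at), c(1, 0))
  even <- sim_pool(6, imbalance_sigma = 0, seed = 24)
  expect_equal(pool_quantile(even$total_mb)$delta, 0)
})

test_that("a full miniature study assembles and writes fixture files", {
  study <- sim_study(seed = 2, n_regions = 120)
  expect_named(study$protocols, c("p1", "p2", "p3"))
  expect_length(study$protocols$p1$samples, 8)
  dir <- withr::local_tempdir()
  write_study_fixtures(study, dir)
  expect_true(file.exists(file.path(dir, "exons.bed")))
  expect_true(file.exists(file.path(dir, "p2", "depth.bedGraph")))
  back <- read_vcf(file.path(dir, "truth_reference.vcf"))
  expect_equal(nrow(back), nrow(study$truths$reference))
  # identity chain on re-read fixtures: zero-error calls == truth
  tr <- study$truths$reference
  cl <- sim_calls(tr, study$designs$exons, zero_error_model(), seed = 3)
  p <- file.path(dir, "ident.vcf")
  write_vcf(cl, p)
  jc <- match_truth(read_vcf(p), tr)
  expect_equal(jc$in_pg_snv + jc$in_pg_indel, nrow(tr))
})
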