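# Depth-based deletion detection: segmentation, Welch flank tests,
# breakpoint refinement, depth-ratio genotyping, discordant-pair clustering.

flat_profile <- function(n = 100, level = 30, window = 1000, chrom = "chr14") {
  depth_profile(chrom, window, seq(1, by = window, length.out = n),
                rep(level, n))
}

test_that("segment_scan finds implanted dips and nothing in flat profiles", {
  expect_equal(nrow(segment_scan(flat_profile())), 0)
  expect_error(segment_scan(depth_profile("c", 1000, seq(1, by = 1000,
                            length.out = 50), rep(0, 50))), "baseline")
  expect_error(segment_scan(flat_profile(20)), "too short")

  fam <- simulate_default_family(seed = 42)
  prof <- simulate_depth(fam$truth, "sire", mean_depth = 30, seed = 3)
  segs <- segment_scan(prof)
  expect_equal(nrow(segs), 1)
  d <- fam$truth$deletion
  # window-resolution localization; base-pair edges come from the per-base
  # refinement, so several windows of slack is the expected scan accuracy
  # at this overdispersion
  expect_lte(abs(segs$start - d$start), 8 * prof$window_size)
  expect_lte(abs(segs$end - d$end), 8 * prof$window_size)
  expect_gte(interval_overlap <- min(segs$end, d$end) - max(segs$start, d$start) + 1,
             0.85 * (d$end - d$start + 1))

  # two separated implanted dips give two segments
  set.seed(4)
  counts <- rnbinom(300, mu = 30, size = 10)
  counts[100:129] <- rnbinom(30, mu = 15, size = 10)
  counts[200:239] <- rnbinom(40, mu = 15, size = 10)
  p2 <- depth_profile("c", 1000, seq(1, by = 1000, length.out = 300), counts)
  expect_equal(nrow(segment_scan(p2)), 2)
})

test_that("flank tests report stratum means and Welch p-values", {
  counts <- c(30, 31, 29, 30, 15, 16, 14, 15, 30, 31, 29, 30)
  prof <- depth_profile("c", 1000, seq(1, by = 1000, length.out = 12), counts)
  rep <- flank_tests(prof, segment = c(4001, 8000),
                     flank_up = c(1, 4000), flank_down = c(8001, 12000))
  expect_equal(rep$mean_upstream, 30)
  expect_equal(rep$mean_inside, 15)
  expect_lt(rep$up_vs_in["p"], 0.001)
  expect_lt(rep$in_vs_down["p"], 0.001)
  expect_gt(rep$up_vs_down["p"], 0.05)

  # zero-variance and single-window strata are errors, not epsilon-fudges
  prof0 <- depth_profile("c", 1000, seq(1, by = 1000, length.out = 12),
                         rep(c(30, 15, 30), each = 4))
  expect_error(flank_tests(prof0, c(4001, 8000), c(1, 4000), c(8001, 12000)),
               "zero variance")
  expect_error(flank_tests(prof, c(4001, 8000), c(1, 1000), c(8001, 12000)),
               "fewer than 2")
})

test_that("up-vs-down comparison is calibrated under the null", {
  reject <- 0
  for (s in 1:100) {
    set.seed(s)
    counts <- rnbinom(150, mu = 30, size = 10)
    prof <- depth_profile("c", 1000, seq(1, by = 1000, length.out = 150),
                          counts)
    counts[51:100] <- rnbinom(50, mu = 15, size = 10)
    prof$count <- counts
    rep <- flank_tests(prof, c(50001, 100000), c(1, 50000), c(100001, 150000))
    if (rep$up_vs_down["p"] <= 0.05) reject <- reject + 1
  }
  expect_lte(reject, 12)  # ~5% nominal size, binomial slack
})

test_that("Welch implementation matches the reference formula to 1e-10", {
  set.seed(13)
  for (i in 1:200) {
    x <- rnorm(sample(3:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 4))
    y <- rnorm(sample(3:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 4))
    tt <- t.test(x, y, var.equal = FALSE)
    ref <- welch_reference(x, y)
    expect_lt(abs(unname(tt$statistic) - ref["t"]), 1e-10)
    expect_lt(abs(tt$p.value - ref["p"]), 1e-10)
  }
})

test_that("breakpoint refinement recovers exact and noisy steps", {
  # noiseless step 30 -> 15 at p = 5000, back up at 9000
  pos <- 1:12000
  counts <- ifelse(pos >= 5000 & pos <= 8999, 15, 30)
  pb <- data.frame(pos = pos, count = counts)
  bp <- refine_breakpoints(pb, 5000, 9000, search_radius = 2000)
  expect_equal(unname(bp["left"]), 5000)
  expect_equal(unname(bp["right"]), 8999)

  # flat noise: no resolvable step
  set.seed(21)
  pb_flat <- data.frame(pos = 1:8000, count = rpois(8000, 30))
  expect_error(refine_breakpoints(pb_flat, 3000, 6000, 1500),
               "not resolvable")
  expect_error(refine_breakpoints(pb, 50000, 60000, 100), "missing around")
})

test_that("depth-ratio genotyping uses the 0.25/0.75 midpoint thresholds", {
  het <- genotype_from_depth(17.79, 32.98)
  expect_equal(het$genotype, "+/-")
  expect_equal(het$depth_ratio, 17.79 / 32.98, tolerance = 1e-12)
  expect_equal(genotype_from_depth(0.3, 30)$genotype, "-/-")
  expect_equal(genotype_from_depth(30, 30)$genotype, "+/+")
  expect_equal(genotype_from_depth(7.5, 30)$genotype, "+/-")   # r = 0.25 inclusive
  expect_equal(genotype_from_depth(22.5, 30)$genotype, "+/-")  # r = 0.75 inclusive
  expect_error(genotype_from_depth(10, 0), "positive")
})

test_that("discordant-pair clustering recovers the implied deletion span", {
  fam <- simulate_default_family(seed = 42)
  pairs <- simulate_discordant_pairs(fam$truth, 1, 20, 400, 30, seed = 5)
  cl <- cluster_discordant_pairs(pairs, 400)
  expect_equal(cl$pair_support, 20)
  expect_lt(abs(cl$implied_span - 50173), 100)

  # concordant-only pairs: no support
  conc <- data.frame(left_end = c(1000, 2000), right_start = c(1200, 2200),
                     nominal_insert = c(400, 400))
  expect_equal(cluster_discordant_pairs(conc, 400)$pair_support, 0)
  expect_equal(cluster_discordant_pairs(conc[0, ], 400)$pair_support, 0)

  # two distinct deletions: largest cluster reported, both visible verbosely
  t2 <- fam$truth
  t2$deletion <- list(chrom = "chr14", start = 10e6, end = 10e6 + 19999)
  pairs2 <- simulate_discordant_pairs(t2, 1, 8, 400, 30, seed = 6)
  both <- cluster_discordant_pairs(rbind(pairs, pairs2), 400, verbose = TRUE)
  expect_equal(both$pair_support, 20)
  expect_equal(nrow(both$clusters), 2)
  expect_lt(abs(sort(both$clusters$implied_span)[1] - 20000), 150)
})

test_that("call_deletion characterizes the default heterozygous sire", {
  fam <- simulate_default_family(seed = 42)
  prof <- simulate_depth(fam$truth, "sire", mean_depth = 30, seed = 3)
  pairs <- simulate_discordant_pairs(fam$truth, 1, 20, 400, 30, seed = 5)
  call <- call_deletion(prof, pairs, inserted_seq = fam$truth$inserted_seq)
  expect_equal(call$genotype, "+/-")
  expect_lt(abs(call$start - fam$truth$deletion$start), 100)
  expect_lt(abs(call$end - fam$truth$deletion$end), 100)
  expect_equal(call$pair_support, 20)
  expect_lt(call$report$up_vs_in["p"], 0.001)
  expect_gt(call$report$up_vs_down["p"], 0.05)
})
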