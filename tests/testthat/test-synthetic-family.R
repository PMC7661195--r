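# Generator invariants: reproducibility, Mendelian structure, depth and
# read-pair expectations.

test_that("population model is reproducible and satisfies its invariants", {
  m1 <- simulate_population(1, 80e6, 1500, seed = 1)
  m2 <- simulate_population(1, 80e6, 1500, seed = 1)
  expect_identical(m1, m2)
  expect_equal(nrow(m1$snps), 1500)
  expect_true(all(diff(m1$snps$pos) > 0))
  expect_true(all(m1$snps$freq_a > 0 & m1$snps$freq_a < 1))
  # mean of Uniform(0.05, 0.5) is 0.275 with SE 0.45/sqrt(12)/sqrt(1500)
  se <- 0.45 / sqrt(12) / sqrt(1500)
  expect_lt(abs(mean(m1$snps$freq_a) - 0.275), 3 * se)
  expect_error(simulate_population(0, 80e6, 100), "positive")
  expect_error(simulate_population(1, 80e6, 1), "at least 2")
})

test_that("backcross family has affection status equal to two deletion copies", {
  for (s in c(1, 7, 42)) {
    fam <- simulate_default_family(seed = s)
    cs <- fam$truth$carrier_status
    aff <- setNames(fam$pedigree$affected, fam$pedigree$id)
    expect_identical(unname(aff[names(cs)]), unname(cs == 2L))
  }
})

test_that("default family mirrors the study layout", {
  fam <- simulate_default_family(seed = 42)
  ped <- fam$pedigree
  off <- ped[grepl("offspring", ped$id), ]
  expect_equal(nrow(off), 24)
  expect_equal(sum(off$affected), 6)
  dams <- sprintf("dam_%d", 1:5)
  expect_equal(sum(fam$truth$carrier_status[dams] == 1L), 3)
  expect_equal(fam$truth$carrier_status[["sire"]], 1L)
  expect_equal(sum(ped$genotyped & ped$affected), 3)
  expect_equal(sum(ped$genotyped & !ped$affected & grepl("offspring", ped$id)), 9)
  expect_equal(fam$truth$deletion$end - fam$truth$deletion$start + 1, 50173)
})

test_that("unconstrained daughters are carriers at the Mendelian rate", {
  model <- simulate_population(1, 80e6, 50, seed = 7)
  fam <- simulate_backcross(model, list("chr1", 40e6, 40e6 + 50172),
                            n_dams = 2000, n_offspring_per_dam = 0, seed = 7)
  dtr <- fam$truth$carrier_status[grepl("^dam_", names(fam$truth$carrier_status))]
  frac <- mean(dtr == 1L)
  expect_gte(frac, 0.47)
  expect_lte(frac, 0.53)
})

test_that("affected fraction among carrier-dam offspring is binomial 1/4", {
  model <- simulate_population(1, 80e6, 50, seed = 11)
  # 300 carrier daughters x 20 offspring = 6000 offspring of carrier dams
  fam <- simulate_backcross(model, list("chr1", 40e6, 40e6 + 50172),
                            n_dams = 300, n_offspring_per_dam = 20, seed = 11,
                            carrier_daughters = 300)
  off <- fam$truth$carrier_status[grepl("^offspring", names(fam$truth$carrier_status))]
  n <- length(off)
  frac <- mean(off == 2L)
  expect_gte(n, 5000)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("backcross simulation is bit-reproducible for a fixed seed", {
  f1 <- simulate_default_family(seed = 42)
  f2 <- simulate_default_family(seed = 42)
  expect_identical(f1$genotypes$calls, f2$genotypes$calls)
  expect_identical(f1$truth, f2$truth)
  expect_error(simulate_backcross(simulate_population(seed = 1),
                                  list("chrX", 1, 100), seed = 1),
               "not in model")
})

test_that("depth ratios match copy-number expectations", {
  fam <- simulate_default_family(seed = 42)
  truth <- fam$truth
  d <- truth$deletion
  inside <- function(p) {
    w_end <- p$window_start + p$window_size - 1
    mean(p$count[p$window_start >= d$start & w_end <= d$end])
  }
  flank <- function(p) {
    w_end <- p$window_start + p$window_size - 1
    mean(p$count[w_end < d$start | p$window_start > d$end])
  }
  het <- simulate_depth(truth, "sire", mean_depth = 30, seed = 3)
  expect_gte(sum(het$window_start >= d$start &
                 het$window_start + het$window_size - 1 <= d$end), 50)
  r <- inside(het) / flank(het)
  expect_gte(r, 0.45)
  expect_lte(r, 0.55)

  wt <- simulate_depth(truth, "founder_dam_1", mean_depth = 30, seed = 3)
  # no signal implanted: no window mean beyond 4 sigma of the NB
  sigma <- sqrt(30 + 0.1 * 900)
  expect_true(all(abs(wt$count - 30) <= 4 * sigma))

  hom <- simulate_depth(truth, names(which(truth$carrier_status == 2L))[1],
                        mean_depth = 30, seed = 3)
  expect_lte(inside(hom), 0.1 * flank(hom))

  expect_error(simulate_depth(truth, "sire", window_size = 0), "positive")
  expect_error(simulate_depth(truth, "nobody"), "unknown sample")
})

test_that("discordant pairs straddle the deletion with the expected apparent insert", {
  fam <- simulate_default_family(seed = 42)
  truth <- fam$truth   # 50,173-bp deletion replaced by TGACAA
  p <- simulate_discordant_pairs(truth, 1, 20, 400, 30, seed = 5)
  expect_equal(nrow(p), 20)
  expect_true(all(p$right_start > p$left_end))
  expect_true(all(p$left_end < truth$deletion$start))
  expect_true(all(p$right_start > truth$deletion$end))
  apparent <- p$right_start - p$left_end - 1 + 2 * 100
  expect_lt(abs(median(apparent) - 50573), 60)

  expect_equal(nrow(simulate_discordant_pairs(truth, 0, 20, seed = 5)), 0)
  expect_identical(simulate_discordant_pairs(truth, 1, 20, seed = 9),
                   simulate_discordant_pairs(truth, 1, 20, seed = 9))
  expect_error(simulate_discordant_pairs(truth, 1, -1), "non-negative")
})

test_that("control cohort is reproducible and respects exclusions", {
  model <- simulate_population(1, 10e6, 50, seed = 2)
  c1 <- simulate_control_cohort(model, 100, seed = 9)
  c2 <- simulate_control_cohort(model, 100, seed = 9)
  expect_identical(c1, c2)
  expect_gt(nrow(c1), 0)
  expect_equal(nrow(simulate_control_cohort(model, 100, site_density = 0,
                                            seed = 9)), 0)
  priv <- c1[1:5, c("chrom", "pos", "ref", "alt")]
  c3 <- simulate_control_cohort(model, 100, seed = 9, exclude_sites = priv)
  expect_equal(nrow(merge(c3, priv)), 0)
})

test_that("sire variant table keeps private sites out of excluded intervals", {
  model <- simulate_population(1, 10e6, 50, seed = 2)
  cohort <- simulate_control_cohort(model, 100, seed = 9)
  excl <- data.frame(chrom = "chr1", start = 2e6, end = 8e6)
  sv <- simulate_sire_variants(model, cohort, n_shared = 50, n_private = 20,
                               exclude = excl, seed = 4)
  priv <- sv[!(paste(sv$chrom, sv$pos) %in% paste(cohort$chrom, cohort$pos)), ]
  expect_true(all(priv$genotype == "het"))
  expect_false(any(priv$pos >= 2e6 & priv$pos <= 8e6))
})
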