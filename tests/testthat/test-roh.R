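# ROH scanning, shared-allele intersection and pedigree-consistency
# filtering.

test_that("detect_roh handles the canonical qualification cases", {
  # all heterozygous: nothing to report
  expect_equal(nrow(detect_roh(rep(1L, 50), seq_len(50) * 1000)), 0)

  # 30 consecutive homozygous SNPs spanning 80 kb qualify on marker count
  pos <- seq(1, by = 80000 / 29, length.out = 30)
  runs <- detect_roh(rep(0L, 30), pos)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$n_snps, 30)
  expect_lt(runs$length_bp, 100000)

  # 20 homozygous SNPs spanning 150 kb qualify on length
  pos <- round(seq(1, 150000, length.out = 20))
  runs <- detect_roh(rep(2L, 20), pos)
  expect_equal(nrow(runs), 1)
  expect_gt(runs$length_bp, 100000)

  # 20 homozygous SNPs spanning only 90 kb qualify on neither criterion
  pos <- round(seq(1, 90000, length.out = 20))
  expect_equal(nrow(detect_roh(rep(2L, 20), pos)), 0)

  expect_error(detect_roh(c(0L, 0L), c(5, 2)), "increasing")
})

test_that("allowances tolerate interior missing/het but never at run ends", {
  calls <- c(1L, 0L, 0L, NA, 0L, NA, 0L, 0L, 1L)
  pos <- c(1, 200000, 250000, 300000, 350000, 400000, 450000, 600000, 900000)
  runs <- detect_roh(calls, pos, params = roh_params(min_snps = 5))
  expect_equal(nrow(runs), 1)
  expect_equal(runs$start, 200000)  # flanking hets excluded
  expect_equal(runs$end, 600000)

  # a third missing call breaks the budget; semantics match the oracle
  calls2 <- c(0L, NA, 0L, NA, 0L, NA, 0L, 0L)
  pos2 <- c(1, 2, 3, 4, 5, 6, 200000, 500000) * 1000
  p2 <- roh_params(min_snps = 3)
  expect_equal(detect_roh(calls2, pos2, params = p2),
               brute_force_roh(calls2, pos2, params = p2))
})

test_that("scanner agrees with the brute-force enumeration on random matrices", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(50:300, 1)
    calls <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                    prob = c(0.4, 0.15, 0.4, 0.05))
    pos <- sort(sample.int(5e6, n))
    params <- roh_params(min_snps = sample(3:10, 1),
                         min_length_bp = sample(c(5e4, 1e5, 2e5), 1),
                         max_missing_per_run = sample(0:2, 1),
                         max_het_per_run = sample(0:1, 1))
    expect_equal(detect_roh(calls, pos, params = params),
                 brute_force_roh(calls, pos, params = params))
  }
})

test_that("shared regions require identical homozygous alleles in all cases", {
  # two cases homozygous for opposite alleles at one interior SNP: the
  # intersection splits there (bridging off) or excises the SNP (default)
  calls <- rbind(case1 = rep(0L, 40), case2 = rep(0L, 40))
  calls[2, 20] <- 2L
  g <- toy_genotypes(calls, pos = seq_len(40) * 5000)
  roh <- lapply(setNames(rownames(calls), rownames(calls)), function(id) {
    detect_roh_sample(g, id, roh_params(min_snps = 5))
  })
  strict <- shared_case_regions(roh, g, roh_params(min_snps = 5),
                                max_bridge_snps = 0)
  expect_equal(nrow(strict), 2)
  expect_true(all(strict$end < 100000 | strict$start > 100000))
  bridged <- shared_case_regions(roh, g, roh_params(min_snps = 5))
  expect_equal(nrow(bridged), 1)
  expect_false(100000 %in% bridged$haplotype[[1]]$pos)

  # a single case's qualifying runs are returned as its own regions
  solo <- shared_case_regions(roh["case1"], g, roh_params(min_snps = 5))
  expect_equal(nrow(solo), 1)
  expect_equal(solo$n_snps, 40)
  expect_error(shared_case_regions(list(), g), "at least one")
})

test_that("adding a case can never grow a shared region", {
  fam <- simulate_default_family(seed = 5, geno_error = 0, missing_rate = 0)
  g <- fam$genotypes
  cases <- fam$pedigree$id[fam$pedigree$affected & fam$pedigree$genotyped]
  roh <- lapply(setNames(cases, cases), function(id) detect_roh_sample(g, id))
  two <- shared_case_regions(roh[1:2], g)
  three <- shared_case_regions(roh, g)
  for (r in seq_len(nrow(three))) {
    covered <- any(two$chrom == three$chrom[r] &
                   two$start <= three$start[r] & two$end >= three$end[r])
    expect_true(covered)
  }
})

test_that("pedigree filter applies the recessive-model exclusion rules", {
  # region haplotype: all-0 homozygous across 10 SNPs
  calls <- rbind(case = rep(0L, 10),
                 dam = c(rep(0L, 9), 1L),      # het at one SNP: no exclusion
                 sib = rep(0L, 10))            # full match: excludes
  g <- toy_genotypes(calls, pos = seq_len(10) * 20000)
  ped <- pedigree(data.frame(
    id = c("sire0", "dam", "sib_dam", "case", "sib"),
    sire = c(NA, NA, NA, "sire0", "sire0"),
    dam = c(NA, NA, NA, "dam", "sib_dam"),
    sex = c("M", "F", "F", "F", "M"),
    affected = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    genotyped = c(FALSE, TRUE, FALSE, TRUE, TRUE)))
  roh <- list(case = detect_roh_sample(g, "case", roh_params(min_snps = 5)))
  regions <- shared_case_regions(roh, g, roh_params(min_snps = 5))
  expect_equal(nrow(regions), 1)

  surv <- pedigree_filter(regions, g, ped)
  expect_equal(nrow(surv), 0)   # the sib match excludes the region

  # with a discordant sib the region survives; the het dam cannot exclude
  g2 <- g
  g2$calls["sib", 4] <- 1L
  surv2 <- pedigree_filter(regions, g2, ped)
  expect_equal(nrow(surv2), 1)
  expect_equal(surv2$n_sibs_checked, 1)
})

test_that("an obligate-carrier dam matching the case haplotype excludes a region", {
  calls <- rbind(case = rep(2L, 10), dam = rep(2L, 10))
  g <- toy_genotypes(calls, pos = seq_len(10) * 20000)
  ped <- pedigree(data.frame(
    id = c("sire0", "dam", "case"), sire = c(NA, NA, "sire0"),
    dam = c(NA, NA, "dam"), sex = c("M", "F", "F"),
    affected = c(FALSE, FALSE, TRUE), genotyped = c(FALSE, TRUE, TRUE)))
  roh <- list(case = detect_roh_sample(g, "case", roh_params(min_snps = 5)))
  regions <- shared_case_regions(roh, g, roh_params(min_snps = 5))
  expect_equal(nrow(pedigree_filter(regions, g, ped)), 0)
})

test_that("pooling joins fragments closer than their larger span", {
  mk <- function(start, end, n) data.frame(
    chrom = "chr1", start = start, end = end, n_snps = n,
    haplotype = I(list(data.frame(snp_id = "x", pos = start, call = 0L))))
  r <- do.call(rbind, list(mk(1e6, 9e6, 100), mk(10e6, 10.4e6, 5),
                           mk(40e6, 40.5e6, 6)))
  class(r) <- c("candidate_regions", "data.frame")
  pooled <- pool_candidate_regions(r)
  expect_equal(nrow(pooled), 2)
  expect_equal(pooled$end[1], 10.4e6)
  expect_equal(pooled$start[2], 40e6)
})
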