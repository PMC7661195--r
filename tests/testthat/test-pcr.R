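# In-silico PCR product prediction, band genotyping and segregation tests.

test_that("amplicon lengths reproduce the two-assay design", {
  p <- assay_primers()
  wt <- allele_model()
  mt <- allele_model(data.frame(del_start = 56451029, del_end = 56501201,
                                inserted_seq = "TGACAA"))
  # wild-type-specific assay: 56,451,423 - 56,450,454 + 1 = 970 bp
  expect_equal(amplicon_length(p$fw, p$rv_wt, wt), 970)
  # reverse footprint inside the deleted interval: no product
  expect_true(is.na(amplicon_length(p$fw, p$rv_wt, mt)))
  # wild-type allele with the distal reverse primer: 50,909 bp > max product
  expect_true(is.na(amplicon_length(p$fw, p$rv_mt, wt)))
  # deletion-specific product by segment arithmetic: 575 + 6 + 161
  expect_equal(amplicon_length(p$fw, p$rv_mt, mt), 742)

  expect_error(amplicon_length(p$rv_wt, p$fw, wt), "orientations")
  expect_error(amplicon_length(p$fw, primer("r", "AC", "reverse", 56450000),
                               wt), "precede")
})

test_that("product length is invariant under joint translation", {
  shift <- 1234567
  fw <- primer("f", "ACGTACGTACGTACGTACGT", "forward", 56450454 + shift)
  rv <- primer("r", "ACGTACGTACGTACGTACGT", "reverse", 56501362 + shift)
  mt <- allele_model(data.frame(del_start = 56451029 + shift,
                                del_end = 56501201 + shift,
                                inserted_seq = "TGACAA"))
  expect_equal(amplicon_length(fw, rv, mt), 742)
})

test_that("band patterns map to genotypes with failure on empty patterns", {
  expect_equal(genotype_from_bands(TRUE, FALSE), "+/+")
  expect_equal(genotype_from_bands(TRUE, TRUE), "+/-")
  expect_equal(genotype_from_bands(FALSE, TRUE), "-/-")
  expect_error(genotype_from_bands(FALSE, FALSE), "assay failure")
})

test_that("pcr genotyping recovers simulated carrier status exactly", {
  fam <- simulate_default_family(seed = 42)
  p <- assay_primers()
  truth_gt <- c("+/+", "+/-", "-/-")[fam$truth$carrier_status + 1L]
  names(truth_gt) <- names(fam$truth$carrier_status)
  called <- vapply(names(truth_gt), function(id) {
    pcr_genotype(truth_gt[[id]], p$fw, p$rv_wt, p$rv_mt,
                 assay_deletion, "TGACAA")$genotype
  }, character(1))
  expect_identical(called, truth_gt)
  bands <- pcr_genotype("+/-", p$fw, p$rv_wt, p$rv_mt, assay_deletion,
                        "TGACAA")$bands
  expect_equal(bands, c(742, 970))
})

test_that("cosegregation check enumerates recessive-model violations", {
  fam <- simulate_default_family(seed = 42)
  ped <- fam$pedigree
  gt <- c("+/+", "+/-", "-/-")[fam$truth$carrier_status + 1L]
  names(gt) <- names(fam$truth$carrier_status)
  gt <- gt[ped$id[ped$genotyped]]
  res <- cosegregation_check(gt, ped)
  expect_true(res$perfect)
  expect_equal(nrow(res$violations), 0)

  # an unaffected individual called -/- is a violation
  gt_bad <- gt
  unaff <- names(gt)[!setNames(ped$affected, ped$id)[names(gt)]][1]
  gt_bad[unaff] <- "-/-"
  res_bad <- cosegregation_check(gt_bad, ped)
  expect_false(res_bad$perfect)
  expect_equal(res_bad$violations$id, unaff)

  # an affected individual not homozygous is a violation
  gt_bad2 <- gt
  aff <- names(gt)[setNames(ped$affected, ped$id)[names(gt)]][1]
  gt_bad2[aff] <- "+/-"
  res2 <- cosegregation_check(gt_bad2, ped)
  expect_false(res2$perfect)
  expect_true(any(grepl("not homozygous", res2$violations$rule)))

  # an obligate-carrier parent without the allele is a violation
  gt_bad3 <- gt
  gt_bad3["sire"] <- "+/+"
  expect_true(any(grepl("carrier", cosegregation_check(gt_bad3,
                                                       ped)$violations$rule)))
})

test_that("exact binomial segregation test matches direct enumeration", {
  mk_ped <- function(n_off, n_aff) pedigree(data.frame(
    id = c("s", "d", sprintf("o%02d", seq_len(n_off))),
    sire = c(NA, NA, rep("s", n_off)), dam = c(NA, NA, rep("d", n_off)),
    sex = c("M", "F", rep("U", n_off)),
    affected = c(FALSE, FALSE, seq_len(n_off) <= n_aff),
    genotyped = TRUE))
  # two-sided exact p: sum of outcome probabilities <= that of the observed
  enum_p <- function(x, n, p0) {
    pmf <- dbinom(0:n, n, p0)
    sum(pmf[pmf <= pmf[x + 1] * (1 + 1e-7)])
  }
  for (x in c(0, 3, 6, 12)) {
    res <- segregation_ratio_test(mk_ped(24, x), "d")
    expect_equal(res$p_value, enum_p(x, 24, 0.25), tolerance = 1e-9)
  }
  expect_gt(segregation_ratio_test(mk_ped(24, 6), "d")$p_value, 0.05)
  expect_error(segregation_ratio_test(mk_ped(24, 6), "nobody"),
               "no offspring")
  expect_error(segregation_ratio_test(mk_ped(24, 6), "d", p0 = 0),
               "impossible under null")
})

test_that("population screen counts carriers", {
  expect_equal(population_screen(rep("+/+", 182)), 0)
  expect_equal(population_screen(c(rep("+/+", 100), "+/-")), 1)
  expect_equal(population_screen(character(0)), 0)
})
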