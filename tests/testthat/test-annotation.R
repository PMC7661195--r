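# Exon overlap, coding impact and HGVS-style naming.

test_that("overlap_exons returns transcript-order indices with partial flags", {
  gm <- fixture_gene()
  # deletion spanning exons 2-4 entirely
  ov <- overlap_exons(list("chr14", 5000, 50000), gm)
  expect_equal(ov$exon, c(2, 3, 4))
  expect_false(any(ov$partial))
  # intronic deletion
  expect_equal(nrow(overlap_exons(list("chr14", 2000, 7000), gm)), 0)
  # whole gene
  expect_equal(overlap_exons(list("chr14", 1, 70000), gm)$exon, 1:6)
  # partial overlap flagged
  ov2 <- overlap_exons(list("chr14", 8100, 8500), gm)
  expect_true(ov2$partial[ov2$exon == 2])
  # chromosome mismatch: empty with warning
  expect_warning(ov3 <- overlap_exons(list("chr2", 5000, 50000), gm), "chr2")
  expect_equal(nrow(ov3), 0)
})

test_that("minus-strand exon indices follow transcript order", {
  gm <- gene_model("neg", "chr1", "-",
                   exons = data.frame(start = c(100, 500), end = c(200, 600)),
                   cds = data.frame(start = c(150, 500), end = c(200, 550)))
  ov <- overlap_exons(list("chr1", 90, 250), gm)   # reference-first exon
  expect_equal(ov$exon, 2)                          # last in transcript order
})

test_that("coding impact reproduces the 174-aa / 71.6% fixture arithmetic", {
  gm <- fixture_gene()
  imp <- coding_impact(list("chr14", 5000, 50000), gm)
  expect_equal(imp$cds_bp_deleted, 522)
  expect_equal(imp$aa_deleted, 174)
  expect_equal(imp$total_aa, 243)
  expect_equal(imp$protein_pct, 71.6)
  expect_true(imp$in_frame)

  none <- coding_impact(list("chr14", 2000, 7000), gm)
  expect_equal(none$aa_deleted, 0)
  expect_equal(none$protein_pct, 0)

  all <- coding_impact(list("chr14", 1, 70000), gm)
  expect_equal(all$protein_pct, 100)

  fs <- coding_impact(list("chr14", 8000, 8000), gm)  # 1 coding bp
  expect_false(fs$in_frame)
  expect_equal(fs$aa_deleted, 0)
})

test_that("coding impact is invariant under joint translation", {
  d0 <- coding_impact(list("chr14", 5000, 50000), fixture_gene())
  d1 <- coding_impact(list("chr14", 5000 + 1e6, 50000 + 1e6),
                      fixture_gene(offset = 1e6))
  expect_equal(d0$protein_fraction, d1$protein_fraction)
  expect_equal(d0$cds_bp_deleted, d1$cds_bp_deleted)
})

test_that("gene model validation rejects malformed structures", {
  expect_error(gene_model("g", "c", "+",
                          exons = data.frame(start = c(1, 50), end = c(60, 80)),
                          cds = data.frame(start = 1, end = 60)), "overlapping")
  expect_error(gene_model("g", "c", "+",
                          exons = data.frame(start = 1, end = 100),
                          cds = data.frame(start = 50, end = 150)),
               "not contained")
  expect_error(gene_model("g", "c", "+",
                          exons = data.frame(start = 1, end = 100),
                          cds = data.frame(start = 1, end = 100)),
               "divisible by 3")
})

test_that("hgvs names follow delins conventions without separators", {
  expect_equal(hgvs_name(list(start = 56451029, end = 56501201,
                              inserted_seq = "TGACAA")),
               "g.56451029_56501201delinsTGACAA")
  expect_equal(hgvs_name(list(start = 100, end = 200, inserted_seq = "")),
               "g.100_200del")
  expect_equal(hgvs_name(list(start = 100, end = 100, inserted_seq = "A")),
               "g.100_100delinsA")
  expect_error(hgvs_name(list(start = 200, end = 100)), "start")
  expect_error(hgvs_name(list()), "empty")
})
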