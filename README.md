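# recessmap

Homozygosity mapping and structural-variant evidence for autosomal-recessive
lesions in livestock backcross families.

## The problem

A rare, fully penetrant recessive disorder appears in a backcross family — a
sire mated to several of its own daughters. Affected offspring must be
homozygous, identical by descent, for a chromosomal segment carrying the
causal allele. `recessmap` implements the complete localization workflow for
this setting:

1. **Genotype QC** on SNP-chip calls: remove SNPs with call rate < 90% or
   minor allele frequency < 1%.
2. **Runs of homozygosity (ROH)** per affected case: maximal stretches of
   homozygous calls (with small missing/het allowances) that contain ≥ 30
   SNPs or span > 100 kb.
3. **Shared-allele intersection**: intersect all cases' ROH and keep only
   sub-intervals where every case is homozygous for the *identical* alleles.
4. **Pedigree-consistency filtering**: discard a region if any obligate
   carrier (a parent of a case) or any unaffected sibling is homozygous for
   the case haplotype across it; pool surviving fragments of one
   identity-by-descent complex into a single candidate locus.
5. **Small-variant triage**: keep the sequenced sire's heterozygous
   variants, subtract every site observed in a control cohort, and restrict
   to the candidate region. An empty result escalates the analysis to
   structural variants.
6. **Read-depth deletion calling**: scan windowed depth for a step-shaped
   drop, test it against both flanks with two-sided Welch *t*-tests, refine
   both breakpoints at base resolution by least-squares change-point fits,
   genotype samples by the depth ratio (copy-number midpoint thresholds
   0.25 / 0.75), and corroborate with discordant read-pair clusters.
7. **In-silico PCR co-segregation**: predict product sizes per allele from
   primer 5′ coordinates, genotype individuals from band patterns, check
   perfect recessive co-segregation, and test the 1/4 segregation ratio with
   an exact binomial test.
8. **Consequence annotation**: deleted exons, deleted coding length, amino
   acids lost, fraction of the protein affected, and an HGVS-style
   `g.<start>_<end>delins<SEQ>` name.

Because the original animal data are not publicly deposited, the package
ships a **synthetic family generator** (`simulate_default_family()`) that
emulates the study design — 5 daughter-dams (3 deletion carriers),
24 offspring (6 affected), chip-density markers with genotyping error and
missingness, a heterozygous 50,173-bp deletion replaced by `TGACAA` in the
sire, ~30× depth with half-depth over the deletion, and breakpoint-spanning
read pairs — with full ground truth, so every stage is testable end to end.

## Worked example

```r
library(recessmap)
report <- run_pipeline(default_pipeline_config(seed = 42))
print(report)
```

```
mapping_report
  qc: 1500 SNPs -> 1206 retained
  roh: 20 shared -> 1 candidate region(s)
    chr14:52193231-60348428 (138 SNPs)
  variants: 30 private het; 0 in candidate region — no small variant in the candidate region; escalating to structural-variant analysis
  sv: chr14 g.56451029_56501201delinsTGACAA +/-, depth ratio 0.518, pair support 20
  pcr: wt 970 bp / del 742 bp; co-segregation perfect; ratio 6/14, p = 0.129
  annotation: synthetic_rspo_like, 3 exons deleted, 174/243 aa (71.6%)
```

Reading the report: QC retains 1206 of 1500 simulated markers; the three
genotyped cases share exactly one identical-homozygous region that survives
the pedigree filter (8.2 Mb on chr14, containing the implanted deletion).
No sire-private small variant falls inside it, so the pipeline escalates to
depth evidence and recovers the deletion at the exact implanted breakpoints,
heterozygous in the sire (depth ratio 0.518, 20 supporting read pairs). PCR
product prediction gives the 970-bp wild-type and 742-bp deletion-allele
products; genotypes co-segregate perfectly with the phenotype and 6 affected
among 14 offspring of carrier dams is compatible with the recessive 1/4
ratio (exact binomial p = 0.129). The deletion removes three exons encoding
174 of 243 amino acids — 71.6% of the protein.

Individual stages are exported and composable: `qc_filter()`,
`detect_roh()`, `shared_case_regions()`, `pedigree_filter()`,
`select_heterozygous()` / `subtract_cohort()` / `restrict_to_intervals()`,
`segment_scan()` / `flank_tests()` / `refine_breakpoints()` /
`genotype_from_depth()` / `cluster_discordant_pairs()` / `call_deletion()`,
`amplicon_length()` / `cosegregation_check()` / `segregation_ratio_test()`,
`overlap_exons()` / `coding_impact()` / `hgvs_name()`. Readers and writers
cover PLINK PED/MAP, bedGraph, BED, TSV, JSON and a symbolic-ALT VCF record.

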