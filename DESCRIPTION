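Package: recessmap
Title: Homozygosity Mapping and Structural-Variant Evidence for Recessive Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing an autosomal-recessive lesion in a livestock
    backcross family from SNP-array genotypes and whole-genome sequencing
    evidence. Implements run-of-homozygosity detection with shared-allele
    intersection across affected individuals, pedigree-consistency filtering
    of candidate regions, subtraction of control-cohort variation from a
    carrier parent's variant set, read-depth deletion detection with Welch
    flank tests, per-base breakpoint refinement and depth-ratio genotyping,
    discordant read-pair corroboration, in-silico PCR genotyping with
    Mendelian co-segregation and exact binomial segregation-ratio tests, and
    exon-level consequence annotation of a deletion. A synthetic backcross
    family generator with a known implanted deletion makes every stage
    testable end to end without access to the original animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
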