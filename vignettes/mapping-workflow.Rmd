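---
title: "Mapping a recessive lesion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive lesion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recessmap)
```

`recessmap` localizes an autosomal-recessive lesion in a sire-by-daughter
backcross family from chip genotypes, then characterizes the causal
structural variant from sequencing-derived evidence. This vignette explains
the underlying models, the tunable parameters, what the synthetic data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## The genetic model

Under full-penetrance autosomal-recessive inheritance in a backcross
(sire × daughter) family, every affected individual carries two copies of
one ancestral chromosome segment: the segment is identical by descent (IBD)
through both the paternal and the maternal route, because the dams are
themselves daughters of the sire. Three consequences drive the pipeline:

* affected individuals are **homozygous for identical alleles** across the
  IBD segment — the target of ROH detection and shared-allele intersection;
* each **parent of an affected individual is an obligate carrier** and must
  be heterozygous somewhere in the true region — a region where an obligate
  carrier is homozygous for the case haplotype cannot be causal;
* **unaffected siblings** may be heterozygous or homozygous for different
  alleles, but never homozygous for the case haplotype across the true
  region.

Among offspring of carrier-dam × carrier-sire matings the expected affected
fraction is 1/4, tested with `segregation_ratio_test()` — an exact two-sided
binomial test whose two-sidedness sums the probabilities of all outcomes no
more likely than the observed one (`stats::binom.test` implements exactly
this definition).

## Run-of-homozygosity detection

`detect_roh()` uses exact maximal-run semantics rather than a sliding-window
heuristic: a run starts and ends in a homozygous call and may contain at
most `max_missing_per_run` missing (default 2) and `max_het_per_run`
heterozygous calls (default 0), never at its ends. A run qualifies when it
has at least `min_snps` markers (default 30) **or** spans more than
`min_length_bp` (default 100 kb). Overlapping maximal runs — possible
because the allowances can be spent at either end — are merged into
non-overlapping reported intervals. These semantics are deliberately simple
enough to be checked exactly against a quadratic brute-force enumeration,
which the test suite does on hundreds of random inputs.

`shared_case_regions()` intersects the cases' qualifying runs and trims each
intersection to maximal stretches where all cases carry the identical
homozygous genotype. Two allowances reflect how chip data actually behave:

* a SNP where some case has a **missing call** does not break a stretch
  (no observed discordance), and contributes `NA` to the shared haplotype;
* stretches separated by at most `max_bridge_snps` (default 1) discordant
  markers are merged with the discordant marker excised. At a per-call
  error rate of ~0.2%, an isolated discordant call inside a multi-megabase
  shared block is overwhelmingly a genotyping artefact, whereas a genuine
  IBD boundary shows several consecutive discordant markers. Window-based
  ROH callers used for chip data achieve the same robustness through their
  per-window heterozygote allowance; with strict splitting
  (`max_bridge_snps = 0`) the expected ~1 error among three cases across a
  ~150-marker block would split the true region in most families.

`pedigree_filter()` applies the obligate-carrier and sibling exclusions. A
relative matches the case haplotype only if every *called* genotype agrees
(at least half the region's markers must be called): one observed
discordant call rescues a region from exclusion, and a missing call is not
treated as discordance. Both parents of cases count as obligate carriers —
the sire as much as the dams. Finally, surviving regions are pooled
(`pool_candidate_regions()`): two regions are reported as one candidate
locus when the gap between them is smaller than the span of the larger of
the two. At the edges of a single IBD complex, individual cases lose
identity over multi-marker stretches while the others still share it, which
fragments one locus into pieces; the pooling rule is scale-free (no
threshold in base pairs) and mirrors the ROH-grouping step of chip-based
homozygosity mapping. Genuinely independent loci sit much farther apart
than their own span.

## The synthetic family

`simulate_default_family()` generates the study design end to end: one
80-Mb chromosome carrying 1500 markers (the density of a 50k-class chip on
a ~2.7-Gb genome), allele frequencies uniform on (0.05, 0.5), a sire
heterozygous for a 50,173-bp deletion whose junction carries the
replacement insertion `TGACAA`, five daughter-dams of which three inherit
the deletion, 24 offspring of which six (two per carrier dam) are affected,
and a genotyped subset of three cases, nine unaffected siblings, the five
dams and the sire. Genotypes carry symmetric call-flip errors (0.2%) and
independent missingness (1%).

Meioses use Poisson crossover counts (`length × recomb_rate`, default
1 cM/Mb) with uniform positions and no interference. Two kinds of
conditioning reproduce the study structure at any seed:

* **deletion-locus transmission** is forced (carrier daughters, affected
  offspring) by choosing which parental strand the meiosis starts on —
  the crossover process itself is untouched;
* meioses forced to transmit the deletion receive **two bounding
  crossovers**, placed uniformly 4–12 Mb up- and downstream of it, and a
  daughter-to-offspring bound always falls inside the bound of the deletion
  haplotype the daughter herself received. This implants a shared IBD block
  on the ~10-Mb scale around the lesion. The bounding is a deliberate
  modelling choice: on a single simulated chromosome of 0.8 Morgans, ~45%
  of unconditioned gametes have no crossover at all, so the family would
  frequently share the deletion haplotype chromosome-wide — an artefact of
  truncating the genome to one chromosome that has no analogue in a full
  multi-chromosome genome, where mapping resolves blocks of exactly this
  ~10-Mb scale. The inner-bound coupling prevents the complementary
  artefact (manufactured IBD of the sire's *other* haplotype just outside
  the block). With the layout arguments set to `NULL` transmission is fully
  stochastic; the segregation-ratio properties are verified in that mode.

Depth profiles are negative binomial per window (dispersion 0.1, i.e.
variance $\mu + 0.1\mu^2$, matching typical WGS overdispersion at 1-kb
windows), with the in-deletion mean scaled by copy number/2 and floored at
2% of the diploid mean to emulate mismapped reads; per-base counts are
Poisson over ±2-kb focal windows around each breakpoint. Discordant pairs
are drawn from fragments of length Normal(400, 30) placed across the
junction; on the reference the apparent insert equals fragment length +
deletion length − insertion length.

What the generator does **not** emulate: linkage disequilibrium beyond
pedigree transmission, chip ascertainment bias, batch effects, GC-dependent
coverage waves, read-level artefacts (soft clips, split reads), or
population structure in the control cohort. Passing tests therefore show
that the *logic* of each stage is correct under a faithful abstraction of
the study design, not that the pipeline is robust to every artefact of real
chips and sequencers.

## Read-depth deletion calling

`segment_scan()` thresholds a running-median-smoothed profile (window 9) at
`max_ratio` (default 0.75) times the baseline. The baseline is a two-pass
median: windows flagged low by a provisional global median are excluded and
the median recomputed, because in a deletion-focused analysis region the
deletion itself can occupy a quarter of the windows and drag a naive global
median down. Interruptions of ≤ 2 windows inside a low run are closed, and
each run edge is then refined at window resolution by a least-squares
two-segment step fit on the raw counts. At this overdispersion the
window-scale edges still carry several windows of noise — base-pair
precision comes from `refine_breakpoints()`, which fits the same step model
to per-base counts (ties broken to the leftmost position; a step must
reduce the residual sum of squares by at least 5% or the breakpoint is
declared not resolvable rather than silently guessed).

`flank_tests()` runs three two-sided Welch *t*-tests on window counts:
upstream vs inside, inside vs downstream, upstream vs downstream. The
default flanks are 100 kb upstream and 50 kb downstream of the called
segment. The third test is the negative control and should not reject for
a genuine deletion. Raw p-values are reported; the three tests are planned
comparisons and no multiplicity adjustment is applied. Strata with fewer
than two windows or zero variance are errors, not epsilon-fudged.

`genotype_from_depth()` thresholds the inside/flank ratio at 0.25 and 0.75
— the midpoints between the copy-number expectations 0, 0.5 and 1 —
symmetric and requiring no tuning. `cluster_discordant_pairs()` flags pairs
whose apparent insert exceeds the nominal fragment length by more than
4 SD, clusters them by span overlap (single linkage), and reports the
largest cluster's size and median implied deletion length.

## In-silico PCR

`amplicon_length()` works in coordinate arithmetic. The locked convention:
a primer's printed 5′-start is its leftmost reference base for forward
primers and its *rightmost* reference base for reverse primers; the product
length is then the end-inclusive span between the two 5′-starts, adjusted
by enclosed edits (− deleted length + inserted length), with any overlap of
a primer footprint with a deleted interval abolishing the product and a
5-kb practical product-size cap. This is the unique convention under which
the wild-type assay's primer pair (5′-starts 56,450,454 and 56,451,423)
yields its documented 970-bp product. Under the same convention the
deletion-specific pair yields 742 bp (575 bp upstream of the deletion +
6 bp insertion + 161 bp downstream), a 686-bp figure sometimes quoted for this assay
cannot be reconciled with these coordinates, and the package follows the
coordinates. Coordinate arithmetic also settles
which reverse primer lies inside the deletion: the one at 56,451,423.

## Problem sizes and reproducibility

Every generator takes an explicit seed and is bit-reproducible; internal
stages derive sub-seeds deterministically from the master seed, so a
pipeline run is reproducible end to end from one integer. The test suite
exercises the scaled-down study conditions: families of 35 individuals with
1500 markers (the real chip's per-chromosome density), 100-seed breakpoint
and equivalence sweeps, and 20-seed end-to-end recovery. These sizes keep
the default test run around half a minute while leaving every statistical
check comfortably powered.

## Known limitations

* The ROH scanner's allowances are global per run, not per window; very
  long runs therefore tolerate no more missing calls than short ones.
* Depth genotyping assumes a single diploid baseline; it would misread
  mosaic or multi-copy states.
* The inserted junction sequence is not discoverable from depth or pair
  evidence; it enters a `deletion_call` only from the simulator truth or
  user input, mirroring the dependence of delins resolution on Sanger
  sequencing.
* Coordinates live on one assembly throughout; cross-assembly liftover is
  out of scope.
* The candidate-region pooling rule assumes a single causal locus per
  family — appropriate for a fully penetrant monogenic disorder, wrong for
  oligogenic traits.
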