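# Small-variant triage: heterozygous selection, control-cohort subtraction,
# candidate-interval restriction. All three are pure row filters keyed on
# (chrom, pos, ref, alt), so they commute and compose.

# Canonical site key. Multi-allelic records must be pre-split, one alt per
# record, so keys are unambiguous.
site_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

validate_variants <- function(variants) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop_arg("variant table needs columns: %s", paste(need, collapse = ", "))
  }
  bad <- which(variants$ref == variants$alt | variants$pos < 1)
  if (length(bad)) stop_arg("malformed variant record at line %d", bad[1])
  invisible(variants)
}

#' Keep only heterozygous variant records
#'
#' @param variants Data frame with at least columns `chrom`, `pos`, `ref`,
#'   `alt`, `genotype` (`"hom_ref"`, `"het"`, `"hom_alt"`).
#' @return The heterozygous records, order preserved.
#' @export
select_heterozygous <- function(variants) {
  validate_variants(variants)
  out <- variants[variants$genotype == "het", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove variants present in a control cohort
#'
#' Site-level presence/absence subtraction: a record is removed when its
#' `(chrom, pos, ref, alt)` key appears in the cohort table, regardless of
#' cohort allele frequency. A site with the same position but a different
#' alternate allele is retained.
#'
#' @param variants Variant data frame (see [select_heterozygous()]).
#' @param cohort_sites Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return The records absent from the cohort, order preserved.
#' @export
subtract_cohort <- function(variants, cohort_sites) {
  validate_variants(variants)
  validate_variants(cohort_sites)
  out <- variants[!(site_key(variants) %in% site_key(cohort_sites)), ,
                  drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict variants to candidate intervals
#'
#' Keeps records whose position falls inside any of the given 1-based closed
#' intervals. Overlapping or unsorted intervals are merged first. An empty
#' result is a valid, meaningful outcome: it is the signal to escalate from
#' small-variant to structural-variant analysis.
#'
#' @param variants Variant data frame.
#' @param intervals Data frame with columns `chrom`, `start`, `end`.
#' @return The records inside the intervals, order preserved.
#' @export
restrict_to_intervals <- function(variants, intervals) {
  validate_variants(variants)
  iv <- merge_intervals(intervals)
  inside <- vapply(seq_len(nrow(variants)), function(i) {
    any(iv$chrom == variants$chrom[i] & iv$start <= variants$pos[i] &
        variants$pos[i] <= iv$end)
  }, logical(1))
  out <- variants[inside, , drop = FALSE]
  rownames(out) <- NULL
  out
}
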