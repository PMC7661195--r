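# SNP-array quality control: call-rate and minor-allele-frequency filters.

#' Per-SNP call rate and minor allele frequency
#'
#' Call rate is the fraction of non-missing calls; MAF is the minor allele
#' frequency over all called alleles in the matrix, pooling every genotyped
#' sample. A SNP with no calls has call rate 0 and MAF reported as 0.
#'
#' @param x A [genotype_matrix()].
#' @return Data frame with columns `snp_id`, `call_rate`, `maf`.
#' @export
compute_snp_stats <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (nrow(x$calls) == 0L) stop_arg("genotype matrix has no samples")
  called <- colSums(!is.na(x$calls))
  call_rate <- called / nrow(x$calls)
  b_count <- colSums(x$calls, na.rm = TRUE)       # B-allele dose sum
  f_b <- ifelse(called > 0L, b_count / (2 * called), 0)
  maf <- pmin(f_b, 1 - f_b)
  maf[called == 0L] <- 0
  data.frame(snp_id = x$map$snp_id, call_rate = call_rate, maf = maf,
             row.names = NULL)
}

#' Filter SNPs on call rate and minor allele frequency
#'
#' Removes every SNP whose call rate is strictly below `min_call_rate` or
#' whose MAF is strictly below `min_maf` (standard chip-QC semantics: failing
#' either criterion removes the SNP). A SNP at exactly the threshold is
#' retained. Sample set and SNP order are unchanged.
#'
#' @param x A [genotype_matrix()].
#' @param min_call_rate Minimum call rate (default 0.90).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @return List with `genotypes` (the filtered matrix) and `report`
#'   (class `qc_report`): input/removed/retained counts and the per-SNP
#'   statistics. A SNP failing both criteria is counted once, under call rate.
#' @export
qc_filter <- function(x, min_call_rate = 0.90, min_maf = 0.01) {
  if (min_call_rate < 0 || min_call_rate > 1 || min_maf < 0 || min_maf > 1) {
    stop_arg("thresholds must lie in [0, 1]")
  }
  stats <- compute_snp_stats(x)
  fail_cr <- stats$call_rate < min_call_rate
  fail_maf <- !fail_cr & stats$maf < min_maf
  keep <- !fail_cr & !fail_maf
  report <- structure(list(
    n_input_snps = nrow(stats),
    n_removed_callrate = sum(fail_cr),
    n_removed_maf = sum(fail_maf),
    n_retained = sum(keep),
    min_call_rate = min_call_rate, min_maf = min_maf,
    snp_stats = stats), class = "qc_report")
  list(genotypes = subset_genotypes(x, snps = keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("qc_report: %d SNPs in; removed %d (call rate < %.2f) + ",
                     "%d (MAF < %.3f); %d retained\n"),
              x$n_input_snps, x$n_removed_callrate, x$min_call_rate,
              x$n_removed_maf, x$min_maf, x$n_retained))
  invisible(x)
}
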