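# Consequence annotation: exon overlap, coding impact and HGVS-style naming
# of a deletion against a gene model.

#' Define a gene model
#'
#' @param name Gene name.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame `start`, `end` (1-based inclusive), sorted and
#'   non-overlapping in reference order.
#' @param cds Data frame `start`, `end`: coding sub-intervals of the exons;
#'   total length must be divisible by 3.
#' @return Object of class `gene_model` with `total_aa` precomputed.
#' @export
gene_model <- function(name, chrom, strand = c("+", "-"), exons, cds) {
  strand <- match.arg(strand)
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop_arg("overlapping exons")
  }
  for (i in seq_len(nrow(cds))) {
    inside <- any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
    if (!inside) stop_arg("CDS interval %d not contained in an exon", i)
  }
  cds_len <- sum(interval_length(cds$start, cds$end))
  if (cds_len == 0L) stop_arg("zero-length CDS")
  if (cds_len %% 3 != 0) stop_arg("CDS length %d not divisible by 3", cds_len)
  structure(list(name = name, chrom = chrom, strand = strand, exons = exons,
                 cds = cds, cds_len = cds_len, total_aa = cds_len / 3),
            class = "gene_model")
}

#' Exons overlapped by a deletion
#'
#' @param deletion List or vector `(chrom, start, end)`.
#' @param model A [gene_model()].
#' @return Data frame `exon` (index in transcript, i.e. strand-aware, order),
#'   `partial` (TRUE when the exon is only partially deleted); zero rows,
#'   with a warning, on chromosome mismatch.
#' @export
overlap_exons <- function(deletion, model) {
  d <- normalize_interval(deletion)
  empty <- data.frame(exon = integer(0), partial = logical(0))
  if (!identical(d$chrom, model$chrom)) {
    warning(sprintf("deletion on %s but gene '%s' on %s", d$chrom,
                    model$name, model$chrom))
    return(empty)
  }
  ov <- interval_overlap(model$exons$start, model$exons$end, d$start, d$end)
  ref_idx <- which(ov > 0)
  if (length(ref_idx) == 0L) return(empty)
  exon_len <- interval_length(model$exons$start, model$exons$end)
  n_ex <- nrow(model$exons)
  # transcript order: reference order on '+', reversed on '-'
  tx_of_ref <- if (model$strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  out <- data.frame(exon = tx_of_ref[ref_idx],
                    partial = ov[ref_idx] < exon_len[ref_idx])
  out[order(out$exon), , drop = FALSE]
}

normalize_interval <- function(x) {
  x <- as.list(x)
  if (!is.null(x$chrom)) {
    list(chrom = x$chrom, start = as.numeric(x$start), end = as.numeric(x$end))
  } else {
    list(chrom = as.character(x[[1]]), start = as.numeric(x[[2]]),
         end = as.numeric(x[[3]]))
  }
}

#' Coding impact of a deletion on a gene model
#'
#' Sums the overlap of the deletion with the CDS intervals and reports the
#' deleted coding length, amino acids lost, the fraction of the protein
#' affected, and whether the remaining CDS stays in frame. When the deleted
#' coding length is not a multiple of 3, `aa_deleted` is the floor and
#' `in_frame` is `FALSE`.
#'
#' @param deletion List or vector `(chrom, start, end)`.
#' @param model A [gene_model()].
#' @return Object of class `impact_report`: `gene`, `n_exons_deleted`,
#'   `cds_bp_deleted`, `aa_deleted`, `total_aa`, `protein_fraction`,
#'   `protein_pct` (the fraction as a percentage rounded to 1 decimal),
#'   `in_frame`, `exons` (the [overlap_exons()] table).
#' @export
coding_impact <- function(deletion, model) {
  d <- normalize_interval(deletion)
  ex <- overlap_exons(deletion, model)
  cds_bp <- 0
  if (identical(d$chrom, model$chrom)) {
    cds_bp <- sum(interval_overlap(model$cds$start, model$cds$end,
                                   d$start, d$end))
  }
  in_frame <- cds_bp %% 3 == 0
  aa <- floor(cds_bp / 3)
  frac <- aa / model$total_aa
  structure(list(gene = model$name, n_exons_deleted = nrow(ex),
                 cds_bp_deleted = cds_bp, aa_deleted = aa,
                 total_aa = model$total_aa, protein_fraction = frac,
                 protein_pct = round(100 * frac, 1), in_frame = in_frame,
                 exons = ex), class = "impact_report")
}

#' @export
print.impact_report <- function(x, ...) {
  cat(sprintf(paste0("impact_report: %s — %d exon(s) deleted, %d CDS bp, ",
                     "%d of %d aa (%.1f%% of the protein)%s\n"),
              x$gene, x$n_exons_deleted, x$cds_bp_deleted, x$aa_deleted,
              x$total_aa, x$protein_pct,
              if (x$in_frame) "" else "; frameshift"))
  invisible(x)
}

#' HGVS-style genomic name of a deletion call
#'
#' @param call A `deletion_call`, or any list with `start`, `end` and
#'   optionally `inserted_seq`.
#' @return `"g.<start>_<end>del"` or `"g.<start>_<end>delins<SEQ>"`; no
#'   thousands separators.
#' @export
hgvs_name <- function(call) {
  if (is.null(call$start) || is.null(call$end)) stop_arg("empty deletion call")
  if (call$start > call$end) stop_arg("start must be <= end")
  ins <- call$inserted_seq
  base <- sprintf("g.%s_%sdel", format(call$start, scientific = FALSE),
                  format(call$end, scientific = FALSE))
  if (is.null(ins) || !nzchar(ins)) base else paste0(base, "ins", ins)
}
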