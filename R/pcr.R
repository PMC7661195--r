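# In-silico PCR genotyping and Mendelian segregation tests.
#
# Coordinate conventions: a forward primer's printed 5'-start is its leftmost
# reference base; a reverse primer's printed 5'-start is its RIGHTMOST
# reference base. This is the unique convention under which the reference
# span between a forward and a reverse 5'-start, end-inclusive, equals the
# amplicon length.

#' Define a PCR primer
#'
#' @param name Primer name.
#' @param sequence Primer sequence, 5' to 3'.
#' @param orientation `"forward"` or `"reverse"`.
#' @param five_prime_pos 1-based reference coordinate of the primer's 5'
#'   base; for reverse primers this is the rightmost reference base of the
#'   footprint.
#' @return Object of class `primer` with the footprint interval attached.
#' @export
primer <- function(name, sequence, orientation = c("forward", "reverse"),
                   five_prime_pos) {
  orientation <- match.arg(orientation)
  if (five_prime_pos < 1) stop_arg("five_prime_pos must be >= 1")
  len <- nchar(sequence)
  if (len < 1) stop_arg("empty primer sequence")
  fp <- if (orientation == "forward") {
    c(five_prime_pos, five_prime_pos + len - 1)
  } else {
    c(five_prime_pos - len + 1, five_prime_pos)
  }
  if (fp[1] < 1) stop_arg("primer footprint runs off the sequence start")
  structure(list(name = name, sequence = sequence, orientation = orientation,
                 five_prime_pos = five_prime_pos, length = len,
                 footprint = fp), class = "primer")
}

#' Define an allele as a set of edits to the reference
#'
#' An allele model is a list of non-overlapping `(del_start, del_end,
#' inserted_seq)` replacement edits in 1-based inclusive reference
#' coordinates; an empty edit list is the wild-type allele.
#'
#' @param edits Data frame with columns `del_start`, `del_end`,
#'   `inserted_seq`, or `NULL` for wild type.
#' @return Object of class `allele_model`.
#' @export
allele_model <- function(edits = NULL) {
  if (is.null(edits) || nrow(edits) == 0L) {
    edits <- data.frame(del_start = numeric(0), del_end = numeric(0),
                        inserted_seq = character(0))
  }
  edits <- edits[order(edits$del_start), , drop = FALSE]
  if (any(edits$del_start > edits$del_end)) stop_arg("edit with start > end")
  if (nrow(edits) > 1L &&
      any(edits$del_start[-1] <= edits$del_end[-nrow(edits)])) {
    stop_arg("overlapping edits")
  }
  structure(list(edits = edits), class = "allele_model")
}

#' Allele models implied by a deletion genotype
#'
#' @param deletion List or vector `(chrom, start, end)` (chrom optional).
#' @param inserted_seq Junction replacement sequence.
#' @param genotype `"+/+"`, `"+/-"` or `"-/-"`.
#' @return List of two `allele_model`s, one per chromosome copy.
#' @export
alleles_for_genotype <- function(deletion, inserted_seq = "",
                                 genotype = c("+/+", "+/-", "-/-")) {
  genotype <- match.arg(genotype)
  d <- as.list(deletion)
  if (!is.null(d$start)) {
    s <- as.numeric(d$start); e <- as.numeric(d$end)
  } else {
    v <- as.numeric(unlist(deletion)[c(length(d) - 1L, length(d))])
    s <- v[1]; e <- v[2]
  }
  wt <- allele_model()
  mt <- allele_model(data.frame(del_start = s, del_end = e,
                                inserted_seq = inserted_seq))
  switch(genotype, "+/+" = list(wt, wt), "+/-" = list(wt, mt),
         "-/-" = list(mt, mt))
}

#' Predicted amplicon length for one primer pair on one allele
#'
#' Both primer footprints must survive the allele's edits: any overlap of a
#' footprint with a deleted interval yields no product. The product length
#' is the end-inclusive reference span between the two 5'-starts, adjusted
#' by each enclosed edit (minus the deleted length, plus the inserted
#' length). Products longer than `max_product` are not amplified.
#'
#' @param forward,reverse [primer()] objects with matching orientations.
#' @param allele An [allele_model()].
#' @param max_product Maximum amplifiable product in bp (default 5000).
#' @return Product length in bp, or `NA_real_` for no product.
#' @export
amplicon_length <- function(forward, reverse, allele, max_product = 5000) {
  if (forward$orientation != "forward" || reverse$orientation != "reverse") {
    stop_arg("primer orientations must be forward + reverse")
  }
  if (forward$five_prime_pos >= reverse$five_prime_pos) {
    stop_arg("forward 5'-start must precede reverse 5'-start on the reference")
  }
  edits <- allele$edits
  for (p in list(forward, reverse)) {
    if (nrow(edits) && any(interval_overlap(p$footprint[1], p$footprint[2],
                                            edits$del_start, edits$del_end) > 0)) {
      return(NA_real_)
    }
  }
  len <- reverse$five_prime_pos - forward$five_prime_pos + 1
  if (nrow(edits)) {
    enclosed <- edits$del_start > forward$five_prime_pos &
                edits$del_end < reverse$five_prime_pos
    len <- len - sum(interval_length(edits$del_start[enclosed],
                                     edits$del_end[enclosed])) +
           sum(nchar(edits$inserted_seq[enclosed]))
  }
  if (len > max_product) return(NA_real_)
  len
}

#' Genotype an individual from its two assay bands
#'
#' A wild-type-specific band alone is `+/+`, a deletion-specific band alone
#' is `-/-`, both bands together are `+/-`, and no band at all is an assay
#' failure.
#'
#' @param wt_band,del_band Logical: band observed in the wild-type-specific
#'   and deletion-specific assay.
#' @return `"+/+"`, `"+/-"` or `"-/-"`.
#' @export
genotype_from_bands <- function(wt_band, del_band) {
  if (!wt_band && !del_band) stop_arg("assay failure: no band in either assay")
  if (wt_band && del_band) "+/-" else if (wt_band) "+/+" else "-/-"
}

#' Run both assays of a two-primer-pair deletion test on one genotype
#'
#' @param genotype `"+/+"`, `"+/-"` or `"-/-"` (the true allele state).
#' @param forward Shared forward [primer()].
#' @param reverse_wt,reverse_mt Reverse primers of the wild-type-specific and
#'   deletion-specific assay.
#' @param deletion `(chrom, start, end)` of the deletion.
#' @param inserted_seq Junction replacement sequence.
#' @param max_product Maximum amplifiable product in bp.
#' @return List with `bands` (sorted unique product lengths across both
#'   assays) and `genotype` (the call from [genotype_from_bands()]).
#' @export
pcr_genotype <- function(genotype, forward, reverse_wt, reverse_mt,
                         deletion, inserted_seq = "", max_product = 5000) {
  alleles <- alleles_for_genotype(deletion, inserted_seq, genotype)
  sizes <- function(rev) {
    s <- vapply(alleles, function(a) amplicon_length(forward, rev, a,
                                                     max_product), numeric(1))
    s[!is.na(s)]
  }
  wt_sizes <- sizes(reverse_wt)
  mt_sizes <- sizes(reverse_mt)
  list(bands = sort(unique(c(wt_sizes, mt_sizes))),
       genotype = genotype_from_bands(length(wt_sizes) > 0,
                                      length(mt_sizes) > 0))
}

#' Check perfect co-segregation of a deletion genotype with the phenotype
#'
#' Under full-penetrance autosomal-recessive inheritance, every affected
#' individual must be `-/-`, every unaffected individual `+/+` or `+/-`,
#' and every genotyped parent of an affected individual must carry at least
#' one deletion allele.
#'
#' @param genotypes Named character vector of `"+/+"`, `"+/-"`, `"-/-"` calls.
#' @param ped A [pedigree()]; phenotypes must be known for all genotyped
#'   individuals.
#' @return List with `perfect` (logical) and `violations` (data frame `id`,
#'   `rule`).
#' @export
cosegregation_check <- function(genotypes, ped) {
  ids <- names(genotypes)
  if (!all(ids %in% ped$id)) {
    stop_arg("genotyped individual(s) missing from pedigree: %s",
             paste(setdiff(ids, ped$id), collapse = ", "))
  }
  aff <- stats::setNames(ped$affected, ped$id)[ids]
  viol <- list()
  bad <- ids[aff & genotypes != "-/-"]
  for (id in bad) {
    viol[[length(viol) + 1L]] <- data.frame(id = id,
                                            rule = "affected not homozygous for the deletion")
  }
  bad <- ids[!aff & genotypes == "-/-"]
  for (id in bad) {
    viol[[length(viol) + 1L]] <- data.frame(id = id,
                                            rule = "unaffected homozygous for the deletion")
  }
  case_parents <- unique(c(ped$sire[ped$affected], ped$dam[ped$affected]))
  for (id in intersect(case_parents, ids)) {
    if (!(genotypes[[id]] %in% c("+/-", "-/-"))) {
      viol[[length(viol) + 1L]] <- data.frame(id = id,
                                              rule = "obligate carrier without a deletion allele")
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(id = character(0), rule = character(0))
  list(perfect = nrow(violations) == 0L, violations = violations)
}

#' Exact binomial test of the recessive segregation ratio
#'
#' Among offspring of carrier dam x carrier sire matings, the expected
#' affected fraction under autosomal-recessive inheritance is 1/4. The
#' observed affected count among offspring of carrier dams is tested against
#' `p0` with an exact two-sided binomial test (two-sidedness by summing the
#' probabilities of all outcomes no more likely than the observed one).
#'
#' @param ped A [pedigree()] (the sire is assumed heterozygous).
#' @param carrier_dams Character vector of carrier dam ids.
#' @param p0 Null per-offspring affected probability for carrier-dam matings
#'   (default 0.25).
#' @return List with `n_offspring`, `n_affected`, `p_value` and the `htest`
#'   object in `test`.
#' @export
segregation_ratio_test <- function(ped, carrier_dams, p0 = 0.25) {
  off <- ped[!is.na(ped$dam) & ped$dam %in% carrier_dams, , drop = FALSE]
  if (nrow(off) == 0L) stop_arg("no offspring of carrier dams in pedigree")
  x <- sum(off$affected)
  if (p0 <= 0) {
    if (x > 0) stop_arg("impossible under null: affected offspring with p0 = 0")
    stop_arg("p0 must be positive")
  }
  bt <- stats::binom.test(x, nrow(off), p = p0, alternative = "two.sided")
  list(n_offspring = nrow(off), n_affected = x, p_value = bt$p.value,
       test = bt)
}

#' Count deletion carriers in a population screen
#'
#' @param genotypes Character vector of `"+/+"`, `"+/-"`, `"-/-"` calls from
#'   unrelated control individuals.
#' @return Number of individuals carrying at least one deletion allele.
#' @export
population_screen <- function(genotypes) {
  sum(genotypes %in% c("+/-", "-/-"))
}
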