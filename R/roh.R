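# Runs-of-homozygosity detection, shared-allele intersection across cases,
# and pedigree-consistency filtering of candidate regions.

#' ROH detection parameters
#'
#' A run qualifies when it contains at least `min_snps` markers OR spans more
#' than `min_length_bp`. Within a run, up to `max_missing_per_run` missing
#' and `max_het_per_run` heterozygous calls are tolerated, never at the run
#' ends.
#'
#' @param min_snps Minimum markers per qualifying run (default 30).
#' @param min_length_bp Length threshold in bp; runs strictly longer qualify
#'   (default 100000).
#' @param max_missing_per_run Missing calls tolerated inside a run (default 2).
#' @param max_het_per_run Heterozygous calls tolerated inside a run
#'   (default 0).
#' @return An object of class `roh_params`.
#' @export
roh_params <- function(min_snps = 30, min_length_bp = 100000,
                       max_missing_per_run = 2, max_het_per_run = 0) {
  if (min_snps < 0 || min_length_bp < 0 || max_missing_per_run < 0 ||
      max_het_per_run < 0) {
    stop_arg("roh_params must be non-negative")
  }
  structure(list(min_snps = min_snps, min_length_bp = min_length_bp,
                 max_missing_per_run = max_missing_per_run,
                 max_het_per_run = max_het_per_run), class = "roh_params")
}

#' Detect runs of homozygosity on one chromosome
#'
#' Scans one sample's calls for maximal stretches that start and end in a
#' homozygous call and contain at most the allowed numbers of missing and
#' heterozygous calls, then keeps stretches that qualify on marker count or
#' length (see [roh_params()]). Overlapping maximal stretches (possible when
#' the het/missing allowance can be spent at either end) are merged into
#' non-overlapping reported intervals.
#'
#' @param calls Integer vector of calls (0/1/2, `NA` missing) for one sample.
#' @param pos Strictly increasing 1-based positions, same length as `calls`.
#' @param chrom Chromosome name for the output.
#' @param params A [roh_params()].
#' @return Data frame with columns `chrom`, `start`, `end` (positions of the
#'   first and last SNP of the run), `n_snps` (markers spanned) and
#'   `length_bp`; non-overlapping and sorted.
#' @export
detect_roh <- function(calls, pos, chrom = "chr", params = roh_params()) {
  if (length(calls) != length(pos)) stop_arg("calls/pos length mismatch")
  if (is.unsorted(pos, strictly = TRUE)) stop_arg("positions must be strictly increasing")
  n <- length(calls)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      length_bp = numeric(0))
  if (n == 0L) return(empty)
  hom <- which(!is.na(calls) & calls != 1L)
  if (length(hom) == 0L) return(empty)
  cmiss <- cumsum(is.na(calls))
  chet <- cumsum(!is.na(calls) & calls == 1L)
  count_in <- function(cs, i, j) cs[j] - if (i > 1L) cs[i - 1L] else 0L

  # two-pointer over homozygous indices: e(i) is non-decreasing in i
  runs_i <- integer(0); runs_j <- integer(0)
  jp <- 1L
  for (ip in seq_along(hom)) {
    i <- hom[ip]
    if (jp < ip) jp <- ip
    while (jp < length(hom) &&
           count_in(cmiss, i, hom[jp + 1L]) <= params$max_missing_per_run &&
           count_in(chet, i, hom[jp + 1L]) <= params$max_het_per_run) {
      jp <- jp + 1L
    }
    j <- hom[jp]
    if (length(runs_j) == 0L || j > runs_j[length(runs_j)]) {
      runs_i <- c(runs_i, i); runs_j <- c(runs_j, j)
    }
  }

  n_snps <- runs_j - runs_i + 1L
  len <- pos[runs_j] - pos[runs_i] + 1
  ok <- n_snps >= params$min_snps | len > params$min_length_bp
  if (!any(ok)) return(empty)
  iv <- merge_intervals(data.frame(chrom = chrom, start = pos[runs_i[ok]],
                                   end = pos[runs_j[ok]],
                                   stringsAsFactors = FALSE))
  iv$n_snps <- vapply(seq_len(nrow(iv)), function(k) {
    sum(pos >= iv$start[k] & pos <= iv$end[k])
  }, integer(1))
  iv$length_bp <- iv$end - iv$start + 1
  iv
}

#' Detect qualifying ROH for one sample across all chromosomes
#'
#' @param x A [genotype_matrix()].
#' @param sample_id Sample to scan.
#' @param params A [roh_params()].
#' @return Data frame as in [detect_roh()], all chromosomes combined.
#' @export
detect_roh_sample <- function(x, sample_id, params = roh_params()) {
  out <- lapply(unique(x$map$chrom), function(ch) {
    idx <- which(x$map$chrom == ch)
    detect_roh(x$calls[sample_id, idx], x$map$pos[idx], chrom = ch,
               params = params)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Intersection of two non-overlapping sorted closed-interval sets.
intersect_intervals <- function(a, b) {
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(ai))) {
      s <- pmax(ai$start[i], bi$start)
      e <- pmin(ai$end[i], bi$end)
      keep <- s <= e
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = s[keep],
                                              end = e[keep],
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Shared identical-homozygous regions across affected cases
#'
#' Intersects all cases' qualifying ROH intervals and, within each
#' intersection, trims to maximal sub-intervals where every case carries the
#' identical homozygous genotype at every SNP. A SNP at which some cases
#' have a missing call is compatible as long as no called case is
#' heterozygous or conflicts; the shared haplotype is `NA` where no case has
#' a call. Sub-intervals are kept only if they themselves meet `params`.
#'
#' Regions separated by at most `max_bridge_snps` discordant markers are
#' merged, with the discordant markers excised from the reported haplotype:
#' at chip-scale error rates an isolated discordant call inside a long
#' shared block is overwhelmingly a genotyping artefact, whereas a genuine
#' identity-by-descent boundary shows several consecutive discordant
#' markers. Set `max_bridge_snps = 0` for strict splitting at every
#' discordance.
#'
#' @param roh_by_case Named list (one element per case) of ROH data frames
#'   from [detect_roh_sample()].
#' @param genotypes A [genotype_matrix()] containing at least the cases.
#' @param params A [roh_params()].
#' @param max_bridge_snps Maximum number of discordant markers bridged
#'   between two shared stretches (default 1).
#' @return Data frame of class `candidate_regions` with columns `chrom`,
#'   `start`, `end`, `n_snps` and a list-column `haplotype` (per region a
#'   data frame `snp_id`, `pos`, `call` giving the shared homozygous
#'   genotype).
#' @export
shared_case_regions <- function(roh_by_case, genotypes, params = roh_params(),
                                max_bridge_snps = 1) {
  if (length(roh_by_case) == 0L) stop_arg("at least one case required")
  cases <- names(roh_by_case)
  if (is.null(cases) || !all(cases %in% sample_ids(genotypes))) {
    stop_arg("roh_by_case must be named with case sample ids present in genotypes")
  }
  shared <- roh_by_case[[1]][, c("chrom", "start", "end")]
  for (k in seq_along(roh_by_case)[-1]) {
    shared <- intersect_intervals(shared, roh_by_case[[k]])
    if (nrow(shared) == 0L) break
  }
  out <- list()
  for (r in seq_len(nrow(shared))) {
    idx <- which(genotypes$map$chrom == shared$chrom[r] &
                 genotypes$map$pos >= shared$start[r] &
                 genotypes$map$pos <= shared$end[r])
    if (length(idx) == 0L) next
    g <- genotypes$calls[cases, idx, drop = FALSE]
    compatible <- logical(length(idx))
    hap <- rep(NA_integer_, length(idx))
    for (s in seq_along(idx)) {
      v <- g[, s]
      called <- v[!is.na(v)]
      if (length(called) == 0L) {
        compatible[s] <- TRUE
      } else if (all(called != 1L) && length(unique(called)) == 1L) {
        compatible[s] <- TRUE
        hap[s] <- called[1]
      }
    }
    # maximal stretches of compatible SNPs (qualification happens after the
    # bridging pass, so error-split fragments can still merge and qualify)
    rle_c <- rle(compatible)
    ends <- cumsum(rle_c$lengths)
    starts <- ends - rle_c$lengths + 1L
    for (b in which(rle_c$values)) {
      si <- idx[starts[b]]; ei <- idx[ends[b]]
      sel <- starts[b]:ends[b]
      out[[length(out) + 1L]] <- data.frame(
        chrom = shared$chrom[r],
        start = genotypes$map$pos[si], end = genotypes$map$pos[ei],
        n_snps = ends[b] - starts[b] + 1L,
        haplotype = I(list(data.frame(
          snp_id = genotypes$map$snp_id[idx[sel]],
          pos = genotypes$map$pos[idx[sel]],
          call = hap[sel], stringsAsFactors = FALSE))),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_snps = integer(0), haplotype = I(list()))
  res <- res[order(res$chrom, res$start), , drop = FALSE]

  # bridge isolated discordant markers between adjacent stretches
  if (nrow(res) > 1L && max_bridge_snps > 0L) {
    merged <- res[1, , drop = FALSE]
    for (k in 2:nrow(res)) {
      i <- nrow(merged)
      gap_snps <- sum(genotypes$map$chrom == res$chrom[k] &
                      genotypes$map$pos > merged$end[i] &
                      genotypes$map$pos < res$start[k])
      if (identical(merged$chrom[i], res$chrom[k]) &&
          gap_snps <= max_bridge_snps) {
        merged$end[i] <- res$end[k]
        merged$n_snps[i] <- merged$n_snps[i] + res$n_snps[k]
        merged$haplotype[[i]] <- rbind(merged$haplotype[[i]],
                                       res$haplotype[[k]])
      } else {
        merged <- rbind(merged, res[k, , drop = FALSE])
      }
    }
    res <- merged
  }

  ok <- res$n_snps >= params$min_snps |
        (res$end - res$start + 1) > params$min_length_bp
  res <- res[ok, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("candidate_regions", "data.frame")
  res
}

# TRUE when `sample` is homozygous-identical to the shared haplotype at the
# haplotype-defined SNPs of one region. Any observed heterozygous or
# conflicting homozygous call breaks the match (one genotyping error rescues
# a region from exclusion); missing calls are not observed discordances and
# do not break it, but at least half of the region's SNPs must be called for
# a match to count.
matches_case_haplotype <- function(genotypes, sample, hap) {
  def <- !is.na(hap$call)
  if (!any(def)) return(FALSE)
  snp_idx <- match(hap$snp_id[def], genotypes$map$snp_id)
  v <- genotypes$calls[sample, snp_idx]
  called <- !is.na(v)
  mean(called) >= 0.5 && all(v[called] == hap$call[def][called])
}

#' Filter candidate regions on pedigree consistency
#'
#' Under a full-penetrance recessive model, an obligate carrier (a parent of
#' an affected individual) must be heterozygous somewhere in the true
#' region, and no unaffected sibling may be homozygous for the case
#' haplotype across it. A region is therefore removed when (a) any genotyped
#' obligate-carrier parent (dam or sire of a case), or (b) any genotyped
#' unaffected sibling of a case, matches the shared case haplotype
#' homozygously at every SNP of the region. Ungenotyped relatives contribute
#' no exclusion.
#'
#' @param regions `candidate_regions` from [shared_case_regions()].
#' @param genotypes A [genotype_matrix()] containing the relatives.
#' @param ped A [pedigree()].
#' @return Surviving `candidate_regions`, with columns `n_carriers_checked`,
#'   `n_sibs_checked` appended. With `pool = TRUE` (default), surviving
#'   regions are pooled via [pool_candidate_regions()] before being
#'   returned, so fragments of one descending haplotype complex are
#'   reported as a single candidate locus.
#' @param pool Pool nearby surviving regions into single candidate loci.
#' @export
pedigree_filter <- function(regions, genotypes, ped, pool = TRUE) {
  parents_of_cases <- unique(c(ped$sire[ped$affected], ped$dam[ped$affected]))
  obligate <- intersect(parents_of_cases, sample_ids(genotypes))
  sibs <- ped$id[!ped$affected & ped$genotyped &
                 !(is.na(ped$sire) & is.na(ped$dam)) &
                 !(ped$id %in% parents_of_cases)]
  sibs <- intersect(sibs, sample_ids(genotypes))

  keep <- logical(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    hap <- regions$haplotype[[r]]
    excluded <-
      any(vapply(obligate, matches_case_haplotype,
                 logical(1), genotypes = genotypes, hap = hap)) ||
      any(vapply(sibs, matches_case_haplotype,
                 logical(1), genotypes = genotypes, hap = hap))
    keep[r] <- !excluded
  }
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_regions", "data.frame")
  if (pool) out <- pool_candidate_regions(out)
  out[["n_carriers_checked"]] <- rep(length(obligate), nrow(out))
  out[["n_sibs_checked"]] <- rep(length(sibs), nrow(out))
  out
}

#' Pool nearby candidate regions into single candidate loci
#'
#' A single identity-by-descent complex descending through few meioses is
#' often reported as several shared fragments: at its edges individual
#' cases lose identity over multi-marker stretches while the remaining
#' cases still share it. Mirroring the ROH-grouping step of chip-based
#' homozygosity mapping, two regions on the same chromosome are pooled
#' (interval hull, haplotype signatures concatenated) when the gap between
#' them is smaller than the span of the larger of the two — genuinely
#' independent candidate loci are farther apart than their own size. The
#' rule is scale-free and is applied transitively.
#'
#' @param regions `candidate_regions`.
#' @return Pooled `candidate_regions`.
#' @export
pool_candidate_regions <- function(regions) {
  if (nrow(regions) <= 1L) return(regions)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  repeat {
    if (nrow(regions) == 1L) {
      out <- regions
      break
    }
    out <- regions[1, , drop = FALSE]
    for (k in 2:nrow(regions)) {
      i <- nrow(out)
      gap <- regions$start[k] - out$end[i] - 1
      span <- max(out$end[i] - out$start[i] + 1,
                  regions$end[k] - regions$start[k] + 1)
      if (identical(out$chrom[i], regions$chrom[k]) && gap < span) {
        out$end[i] <- max(out$end[i], regions$end[k])
        out$n_snps[i] <- out$n_snps[i] + regions$n_snps[k]
        out$haplotype[[i]] <- rbind(out$haplotype[[i]], regions$haplotype[[k]])
      } else {
        out <- rbind(out, regions[k, , drop = FALSE])
      }
    }
    if (nrow(out) == nrow(regions)) break  # pooling reached a fixpoint
    regions <- out
  }
  rownames(out) <- NULL
  class(out) <- c("candidate_regions", "data.frame")
  out
}
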