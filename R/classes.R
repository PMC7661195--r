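# Core S3 containers used throughout the pipeline. These are lightweight
# list/data.frame-based classes in the style of population-genetics packages:
# plain data underneath, validated constructors on top.

#' Construct a genotype matrix
#'
#' A genotype matrix holds biallelic SNP calls for a set of samples as an
#' integer matrix coded by B-allele dose: `0` = AA, `1` = AB, `2` = BB,
#' `NA` = missing. Rows are samples, columns are SNPs. The SNP map carries
#' chromosome, 1-based position and the two allele labels per SNP.
#'
#' @param calls Integer matrix (samples x SNPs) with values in `c(0, 1, 2, NA)`
#'   and rownames giving sample ids.
#' @param map Data frame with columns `snp_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`; one row per column of `calls`, positions strictly increasing
#'   within each chromosome.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, map) {
  if (!is.matrix(calls)) stop_arg("'calls' must be a matrix")
  if (nrow(calls) > 0L && is.null(rownames(calls))) {
    stop_arg("'calls' must have sample ids as rownames")
  }
  if (ncol(calls) != nrow(map)) {
    stop_arg("map rows (%d) must match call columns (%d)", nrow(map), ncol(calls))
  }
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(map))) {
    stop_arg("map must have columns: %s", paste(need, collapse = ", "))
  }
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop_arg("calls must be 0, 1, 2 or NA")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) stop_arg("positions must be strictly increasing on %s", ch)
  }
  storage.mode(calls) <- "integer"
  structure(list(calls = calls, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Sample ids of a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x$calls)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param x A `genotype_matrix`.
#' @param samples Sample ids or indices (default all).
#' @param snps SNP indices or a logical mask over SNPs (default all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(x, samples = NULL, snps = NULL) {
  calls <- x$calls
  map <- x$map
  if (!is.null(samples)) {
    if (is.character(samples) && !all(samples %in% rownames(calls))) {
      stop_arg("unknown sample id(s): %s",
               paste(setdiff(samples, rownames(calls)), collapse = ", "))
    }
    calls <- calls[samples, , drop = FALSE]
  }
  if (!is.null(snps)) {
    calls <- calls[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
    rownames(map) <- NULL
  }
  genotype_matrix(calls, map)
}

#' Construct a pedigree
#'
#' A pedigree is a data frame of individuals with parent links, sex,
#' affection status and genotyping availability. Parents must be listed
#' before their offspring and every affected individual must have both
#' parents in the table (a full-penetrance recessive model needs its
#' obligate carriers identifiable).
#'
#' @param df Data frame with columns `id`, `sire`, `dam` (parent ids or `NA`),
#'   `sex` (`"M"`, `"F"` or `"U"`), `affected` (logical), `genotyped`
#'   (logical; available for genotyping).
#' @return An object of class `pedigree` (a validated data frame).
#' @export
pedigree <- function(df) {
  need <- c("id", "sire", "dam", "sex", "affected", "genotyped")
  if (!all(need %in% names(df))) {
    stop_arg("pedigree needs columns: %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$id)) stop_arg("duplicate individual ids in pedigree")
  seen <- character(0)
  for (i in seq_len(nrow(df))) {
    for (p in c(df$sire[i], df$dam[i])) {
      if (!is.na(p) && !(p %in% seen)) {
        stop_arg("parent '%s' of '%s' must precede it in the pedigree", p, df$id[i])
      }
    }
    seen <- c(seen, df$id[i])
  }
  aff <- df$affected
  if (any(aff & (is.na(df$sire) | is.na(df$dam)))) {
    stop_arg("affected individuals must have both parents in the pedigree")
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals (%d affected, %d genotyped)\n",
              nrow(x), sum(x$affected), sum(x$genotyped)))
  NextMethod()
}

#' Obligate-carrier dams of a pedigree
#'
#' Under a full-penetrance autosomal-recessive model, the dam of any affected
#' individual must carry one copy of the causal allele.
#'
#' @param ped A `pedigree`.
#' @return Character vector of dam ids with at least one affected offspring.
#' @export
obligate_carrier_dams <- function(ped) {
  unique(ped$dam[ped$affected & !is.na(ped$dam)])
}

#' Construct a depth profile
#'
#' Windowed read counts over one chromosomal segment, optionally with
#' per-base counts over focal sub-intervals (used for breakpoint refinement).
#' Windows tile the segment without overlap.
#'
#' @param chrom Chromosome name.
#' @param window_size Window width in bp.
#' @param window_start Integer vector of 1-based window start positions,
#'   spaced exactly `window_size` apart.
#' @param count Non-negative numeric vector, one value per window.
#' @param per_base Optional data frame with columns `pos`, `count` for
#'   focal per-base coverage.
#' @return An object of class `depth_profile`.
#' @export
depth_profile <- function(chrom, window_size, window_start, count, per_base = NULL) {
  if (window_size <= 0) stop_arg("window_size must be positive")
  if (length(window_start) != length(count)) stop_arg("window/count length mismatch")
  if (length(window_start) > 1L && any(diff(window_start) != window_size)) {
    stop_arg("windows must tile the segment without gaps or overlap")
  }
  if (any(count < 0)) stop_arg("counts must be non-negative")
  if (!is.null(per_base)) {
    stopifnot(all(c("pos", "count") %in% names(per_base)))
  }
  structure(list(chrom = chrom, window_size = window_size,
                 window_start = as.integer(window_start),
                 count = as.numeric(count), per_base = per_base),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile: %s, %d windows of %d bp [%d..%d], mean %.2fx%s\n",
              x$chrom, length(x$count), x$window_size,
              min(x$window_start), max(x$window_start) + x$window_size - 1L,
              mean(x$count),
              if (is.null(x$per_base)) "" else
                sprintf("; per-base focal coverage at %d positions", nrow(x$per_base))))
  invisible(x)
}
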