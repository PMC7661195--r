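# Readers and writers for the plain-text interchange formats at the module
# boundaries. Internal coordinates are 1-based fully closed; BED/bedGraph
# conversion to 0-based half-open happens here and only here.

#' Write a genotype matrix as PLINK PED/MAP text files
#'
#' @param x A [genotype_matrix()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @param ped Optional [pedigree()] supplying parent/sex/phenotype columns;
#'   without it those columns are written as unknown.
#' @return The two file paths, invisibly.
#' @export
write_ped_map <- function(x, prefix, ped = NULL) {
  map <- data.frame(chrom = x$map$chrom, snp_id = x$map$snp_id, cm = 0,
                    pos = x$map$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ids <- rownames(x$calls)
  lookup <- function(col, default) {
    if (is.null(ped)) return(rep(default, length(ids)))
    v <- stats::setNames(ped[[col]], ped$id)[ids]
    ifelse(is.na(v), default, v)
  }
  sex <- lookup("sex", "U")
  aff <- if (is.null(ped)) rep(NA, length(ids)) else
    stats::setNames(ped$affected, ped$id)[ids]
  lines <- vapply(seq_along(ids), function(i) {
    g <- x$calls[i, ]
    a <- x$map$allele_a; b <- x$map$allele_b
    al1 <- ifelse(is.na(g), "0", ifelse(g == 2L, b, a))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 0L, a, b))
    paste(c("FAM", ids[i], lookup("sire", "0")[i], lookup("dam", "0")[i],
            c(M = "1", F = "2", U = "0")[sex[i]],
            if (is.na(aff[i])) "0" else if (aff[i]) "2" else "1",
            as.vector(rbind(al1, al2))), collapse = "\t")
  }, character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(paste0(prefix, c(".ped", ".map")))
}

#' Read PLINK PED/MAP text files into a genotype matrix
#'
#' Allele labels are assigned per SNP in lexicographic order (`allele_a` is
#' the smaller label), so the B-allele dose coding may be swapped relative
#' to the writer's; every downstream statistic used here (call rate, MAF,
#' homozygosity, allele identity) is invariant under that swap.
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(prefix) {
  map_raw <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                               colClasses = c("character", "character",
                                              "numeric", "numeric"))
  ped_raw <- utils::read.table(paste0(prefix, ".ped"), sep = "\t",
                               colClasses = "character")
  n_snp <- nrow(map_raw)
  stopifnot(ncol(ped_raw) == 6 + 2 * n_snp)
  ids <- ped_raw[[2]]
  al1 <- as.matrix(ped_raw[, 6 + 2 * seq_len(n_snp) - 1, drop = FALSE])
  al2 <- as.matrix(ped_raw[, 6 + 2 * seq_len(n_snp), drop = FALSE])
  calls <- matrix(NA_integer_, nrow = length(ids), ncol = n_snp,
                  dimnames = list(ids, NULL))
  allele_a <- character(n_snp); allele_b <- character(n_snp)
  for (s in seq_len(n_snp)) {
    obs <- c(al1[, s], al2[, s])
    lev <- sort(setdiff(unique(obs), "0"))
    if (length(lev) == 0L) lev <- c("A", "B")
    if (length(lev) == 1L) lev <- c(lev, lev)  # monomorphic
    allele_a[s] <- lev[1]; allele_b[s] <- lev[2]
    dose <- (al1[, s] == lev[2]) + (al2[, s] == lev[2])
    dose[al1[, s] == "0" | al2[, s] == "0"] <- NA
    calls[, s] <- as.integer(dose)
  }
  genotype_matrix(calls, data.frame(
    snp_id = map_raw[[2]], chrom = map_raw[[1]], pos = map_raw[[4]],
    allele_a = allele_a, allele_b = allele_b, stringsAsFactors = FALSE))
}

#' Write a depth profile's windowed counts as bedGraph
#'
#' @param profile A [depth_profile()].
#' @param path Output path; per-base focal counts, when present, go to
#'   `<path>.perbase` in the same format.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  df <- data.frame(chrom = profile$chrom,
                   start0 = profile$window_start - 1L,
                   end = profile$window_start + profile$window_size - 1L,
                   value = profile$count)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(profile$per_base)) {
    pb <- data.frame(chrom = profile$chrom, start0 = profile$per_base$pos - 1L,
                     end = profile$per_base$pos, value = profile$per_base$count)
    utils::write.table(pb, paste0(path, ".perbase"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a bedGraph of tiling windows into a depth profile
#'
#' @param path bedGraph path as written by [write_bedgraph()].
#' @param per_base_path Optional per-base bedGraph path.
#' @return A [depth_profile()].
#' @export
read_bedgraph <- function(path, per_base_path = NULL) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start0", "end", "value"))
  pb <- NULL
  if (!is.null(per_base_path)) {
    raw <- utils::read.table(per_base_path, sep = "\t",
                             col.names = c("chrom", "start0", "end", "value"))
    pb <- data.frame(pos = raw$start0 + 1L, count = raw$value)
  }
  depth_profile(df$chrom[1], window_size = df$end[1] - df$start0[1],
                window_start = df$start0 + 1L, count = df$value,
                per_base = pb)
}

#' Write candidate regions as BED plus a haplotype-signature TSV
#'
#' BED output is 0-based half-open; the TSV keeps 1-based SNP positions and
#' the shared homozygous call per SNP.
#'
#' @param regions `candidate_regions` from [shared_case_regions()] or
#'   [pedigree_filter()].
#' @param prefix Writes `<prefix>.bed` and `<prefix>_haplotypes.tsv`.
#' @return The file paths, invisibly.
#' @export
write_candidate_regions <- function(regions, prefix) {
  bed <- data.frame(chrom = regions$chrom, start0 = regions$start - 1,
                    end = regions$end,
                    name = sprintf("region_%d", seq_len(nrow(regions))))
  utils::write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  hap <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    h <- regions$haplotype[[i]]
    data.frame(region = sprintf("region_%d", i), h)
  }))
  if (is.null(hap)) {
    hap <- data.frame(region = character(0), snp_id = character(0),
                      pos = numeric(0), call = integer(0))
  }
  utils::write.table(hap, paste0(prefix, "_haplotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paste0(prefix, c(".bed", "_haplotypes.tsv")))
}

#' Write / read a pedigree as TSV
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return `path` invisibly (writer); a [pedigree()] (reader).
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(id = "character", sire = "character",
                                         dam = "character", sex = "character",
                                         affected = "logical",
                                         genotyped = "logical"))
  pedigree(df)
}

#' Write / read family ground truth as JSON
#' @param truth A `family_truth`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `family_truth` (reader).
#' @export
write_family_truth <- function(truth, path) {
  jsonlite::write_json(list(
    deletion = truth$deletion, inserted_seq = truth$inserted_seq,
    carrier_status = as.list(truth$carrier_status)), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_family_truth
#' @export
read_family_truth <- function(path) {
  raw <- jsonlite::read_json(path)
  structure(list(
    deletion = list(chrom = raw$deletion$chrom,
                    start = as.numeric(raw$deletion$start),
                    end = as.numeric(raw$deletion$end)),
    inserted_seq = raw$inserted_seq,
    carrier_status = vapply(raw$carrier_status, as.integer, integer(1))),
    class = "family_truth")
}

#' Write a deletion call as a symbolic-ALT VCF record
#'
#' Emits a minimal VCF 4.2 file with one `<DEL>` record carrying `END`,
#' `SVLEN` and, when present, the junction insertion in `INSSEQ`.
#'
#' @param call A `deletion_call`.
#' @param path Output path.
#' @param sample_id Sample column name.
#' @return `path`, invisibly.
#' @export
write_deletion_vcf <- function(call, path, sample_id = "sample") {
  gt <- c("+/+" = "0/0", "+/-" = "0/1", "-/-" = "1/1")[call$genotype]
  info <- sprintf("SVTYPE=DEL;END=%s;SVLEN=-%s%s",
                  format(call$end, scientific = FALSE),
                  format(call$end - call$start + 1, scientific = FALSE),
                  if (nzchar(call$inserted_seq))
                    paste0(";INSSEQ=", call$inserted_seq) else "")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=INSSEQ,Number=1,Type=String,Description=\"Junction insertion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id),
    paste(call$chrom, format(call$start, scientific = FALSE), ".", "N",
          "<DEL>", ".", "PASS", info, "GT", gt, sep = "\t")), path)
  invisible(path)
}

#' Read a variant table from TSV
#'
#' Expects a header line with at least `chrom`, `pos`, `ref`, `alt` and
#' optionally `genotype`.
#'
#' @param path Input TSV.
#' @return Validated variant data frame.
#' @export
read_variant_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_variants(df)
}

#' @rdname read_variant_tsv
#' @param variants Variant data frame.
#' @export
write_variant_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
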