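# Independent oracles and fixture builders used across the suite.

# Quadratic brute-force enumeration of qualifying runs of homozygosity.
# Independent of the scanner: enumerates every candidate stretch with
# homozygous ends, checks the het/missing budgets by direct counting, keeps
# stretches that cannot be extended to the neighbouring homozygous call on
# either side, applies the SNP-count / length qualification, and merges
# overlapping or touching qualifying stretches into reported intervals.
brute_force_roh <- function(calls, pos, chrom = "chr", params = roh_params()) {
  hom <- which(!is.na(calls) & calls != 1L)
  nmiss <- cumsum(is.na(calls))
  nhet <- cumsum(!is.na(calls) & calls == 1L)
  valid <- function(i, j) {
    m <- nmiss[j] - if (i > 1L) nmiss[i - 1L] else 0L
    h <- nhet[j] - if (i > 1L) nhet[i - 1L] else 0L
    m <= params$max_missing_per_run && h <= params$max_het_per_run
  }
  runs <- list()
  for (a in seq_along(hom)) {
    for (b in a:length(hom)) {
      i <- hom[a]; j <- hom[b]
      if (!valid(i, j)) next
      ext_left <- a > 1L && valid(hom[a - 1L], j)
      ext_right <- b < length(hom) && valid(i, hom[b + 1L])
      if (ext_left || ext_right) next
      n_snps <- j - i + 1L
      len <- pos[j] - pos[i] + 1
      if (n_snps >= params$min_snps || len > params$min_length_bp) {
        runs[[length(runs) + 1L]] <- c(pos[i], pos[j])
      }
    }
  }
  if (length(runs) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0),
                      length_bp = numeric(0)))
  }
  m <- do.call(rbind, runs)
  m <- m[order(m[, 1]), , drop = FALSE]
  starts <- m[1, 1]; ends <- m[1, 2]
  for (r in seq_len(nrow(m))[-1]) {
    i <- length(starts)
    if (m[r, 1] <= ends[i] + 1) {
      ends[i] <- max(ends[i], m[r, 2])
    } else {
      starts <- c(starts, m[r, 1]); ends <- c(ends, m[r, 2])
    }
  }
  data.frame(chrom = chrom, start = starts, end = ends,
             n_snps = vapply(seq_along(starts), function(k) {
               sum(pos >= starts[k] & pos <= ends[k])
             }, integer(1)),
             length_bp = ends - starts + 1,
             stringsAsFactors = FALSE)
}

# Welch two-sample t reference: plain transcription of the statistic and the
# Satterthwaite degrees of freedom.
welch_reference <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  c(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Build a genotype matrix from an integer matrix of calls (rows = samples).
toy_genotypes <- function(calls, pos = NULL, chrom = "chr1") {
  if (is.null(pos)) pos <- seq_len(ncol(calls)) * 1000L
  if (is.null(rownames(calls))) {
    dimnames(calls) <- list(sprintf("s%d", seq_len(nrow(calls))), NULL)
  }
  genotype_matrix(calls, data.frame(
    snp_id = sprintf("snp%03d", seq_len(ncol(calls))), chrom = chrom,
    pos = pos, allele_a = "A", allele_b = "C", stringsAsFactors = FALSE))
}

# Six-exon fixture gene: 729-bp CDS (243 aa); exons 2-4 carry 522 coding bp
# (174 aa), so a deletion spanning them removes 71.6% of the protein.
fixture_gene <- function(offset = 0) {
  gene_model("fixture", "chr14", "+",
             exons = data.frame(
               start = offset + c(1000, 8000, 28000, 48000, 60000, 62000),
               end = offset + c(1200, 8146, 28179, 48194, 60089, 62300)),
             cds = data.frame(
               start = offset + c(1100, 8000, 28000, 48000, 60000, 62000),
               end = offset + c(1159, 8146, 28179, 48194, 60089, 62056)))
}

# The study-layout deletion and the two-assay primer set used in PCR tests.
assay_deletion <- list(chrom = "chr14", start = 56451029, end = 56501201)
assay_primers <- function() {
  list(fw = primer("Del_F", "TCCCTGAGCCAGTGAATTCC", "forward", 56450454),
       rv_wt = primer("DelWt_R", "GTGTCCGACTCTGTGTGACC", "reverse", 56451423),
       rv_mt = primer("DelMt_R", "GCATCAGCGCTAAGAACTGC", "reverse", 56501362))
}
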