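# Synthetic backcross-family generator.
#
# Emulates the study design the pipeline is built for: a proven sire mated to
# several of its own daughters, a medium-density SNP chip on the resulting
# family, an implanted heterozygous deletion in the sire, ~30x depth profiles
# with half-depth over heterozygous deletions, and discordant read pairs
# spanning the breakpoints. Ground truth is returned alongside the data so
# every downstream stage can be tested without external data.

#' Simulate a SNP-panel population model
#'
#' Draws a marker panel emulating a medium-density (50k-class) genotyping
#' chip: per chromosome, `n_snps_per_chrom` strictly increasing 1-based
#' positions and per-SNP reference (A) allele frequencies drawn uniformly
#' from `freq_range`.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp (recycled across chromosomes).
#' @param n_snps_per_chrom Markers per chromosome (>= 2).
#' @param seed Integer seed; the model is bit-reproducible for a fixed seed.
#' @param freq_range Range of the uniform A-allele frequency distribution.
#' @param recomb_rate Expected crossovers per bp per meiosis
#'   (default `1e-8`, i.e. 1 cM/Mb).
#' @param chrom_names Optional chromosome names (default `chr1`, `chr2`, ...).
#' @return An object of class `population_model` with elements `chromosomes`
#'   (data frame `name`, `length`), `snps` (data frame `snp_id`, `chrom`,
#'   `pos`, `freq_a`, `allele_a`, `allele_b`) and `recomb_rate`.
#' @export
simulate_population <- function(n_chroms = 1, chrom_length = 80e6,
                                n_snps_per_chrom = 1500, seed = NULL,
                                freq_range = c(0.05, 0.5),
                                recomb_rate = 1e-8, chrom_names = NULL) {
  if (n_chroms < 1 || chrom_length <= 0) stop_arg("sizes must be positive")
  if (n_snps_per_chrom < 2) stop_arg("need at least 2 SNPs per chromosome")
  if (n_snps_per_chrom > chrom_length) stop_arg("more SNPs than bases")
  if (is.null(chrom_names)) chrom_names <- paste0("chr", seq_len(n_chroms))
  chrom_length <- rep_len(chrom_length, n_chroms)
  with_seed(seed, {
    snps <- do.call(rbind, lapply(seq_len(n_chroms), function(i) {
      pos <- sort(sample.int(chrom_length[i], n_snps_per_chrom))
      bases <- c("A", "C", "G", "T")
      a <- sample(bases, n_snps_per_chrom, replace = TRUE)
      b <- vapply(a, function(x) sample(setdiff(bases, x), 1L), character(1))
      data.frame(
        snp_id = sprintf("%s_snp%05d", chrom_names[i], seq_len(n_snps_per_chrom)),
        chrom = chrom_names[i], pos = pos,
        freq_a = stats::runif(n_snps_per_chrom, freq_range[1], freq_range[2]),
        allele_a = a, allele_b = unname(b), stringsAsFactors = FALSE)
    }))
    rownames(snps) <- NULL
    structure(list(
      chromosomes = data.frame(name = chrom_names, length = chrom_length,
                               stringsAsFactors = FALSE),
      snps = snps, recomb_rate = recomb_rate),
      class = "population_model")
  })
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("population_model: %d chromosome(s), %d SNPs, recomb %.1e/bp\n",
              nrow(x$chromosomes), nrow(x$snps), x$recomb_rate))
  invisible(x)
}

# Draw a founder haplotype: B-allele indicator per SNP (P(B) = 1 - freq_a),
# plus a deletion flag (founders never carry the implanted deletion).
founder_haplotype <- function(model) {
  list(alleles = stats::rbinom(nrow(model$snps), 1L, 1 - model$snps$freq_a),
       del = 0L)
}

# One meiosis over all chromosomes: Poisson crossover count per chromosome,
# uniform crossover positions, no interference. `force_del` conditions the
# transmission of the deletion pseudo-locus (0/1) without altering the
# crossover process; NA transmits it unconditionally. `mandatory_xo` adds
# fixed crossover positions on the deletion chromosome (used to bound the
# transmitted deletion haplotype when implanting a shared IBD block of a
# defined scale; a short one-chromosome genome would otherwise often share
# the deletion haplotype chromosome-wide, which has no analogue in a full
# multi-chromosome genome).
gamete <- function(hap1, hap2, model, del_locus, force_del = NA,
                   mandatory_xo = NULL) {
  snps <- model$snps
  out <- integer(nrow(snps))
  del <- 0L
  for (i in seq_len(nrow(model$chromosomes))) {
    ch <- model$chromosomes$name[i]
    len <- model$chromosomes$length[i]
    idx <- which(snps$chrom == ch)
    k <- stats::rpois(1L, len * model$recomb_rate)
    xo <- sort(stats::runif(k, 1, len))
    on_chrom <- !is.na(del_locus$pos) && identical(del_locus$chrom, ch)
    if (on_chrom && !is.null(mandatory_xo)) {
      xo <- sort(c(xo, mandatory_xo[mandatory_xo > 1 & mandatory_xo < len]))
    }
    start <- sample(0:1, 1L)
    if (on_chrom && !is.na(force_del)) {
      cross_before <- sum(xo < del_locus$pos)
      flags <- c(hap1$del, hap2$del)
      ok <- which(vapply(0:1, function(s) {
        flags[(s + cross_before) %% 2L + 1L] == force_del
      }, logical(1))) - 1L
      if (length(ok) == 0L) {
        stop_arg("cannot force deletion transmission: parent lacks required allele")
      }
      start <- if (length(ok) == 1L) ok else sample(ok, 1L)
    }
    src <- (start + findInterval(snps$pos[idx], xo)) %% 2L
    out[idx] <- ifelse(src == 0L, hap1$alleles[idx], hap2$alleles[idx])
    if (on_chrom) {
      s <- (start + sum(xo < del_locus$pos)) %% 2L
      del <- if (s == 0L) hap1$del else hap2$del
    }
  }
  list(alleles = out, del = del)
}

# Apply symmetric genotyping error (call replaced by one of the other two
# classes with probability `error`) and independent Bernoulli missingness.
corrupt_calls <- function(calls, error, missing) {
  n <- length(calls)
  flip <- stats::runif(n) < error
  if (any(flip)) {
    calls[flip] <- vapply(calls[flip], function(g) {
      sample(setdiff(0:2, g), 1L)
    }, integer(1))
  }
  calls[stats::runif(n) < missing] <- NA_integer_
  calls
}

#' Simulate a sire-by-daughter backcross family with an implanted deletion
#'
#' Builds the full family: founder dams, a sire heterozygous for the
#' deletion, daughters (sire x founder dam), and offspring
#' (daughter x sire), with Poisson-crossover recombination at each meiosis.
#' An offspring is affected if and only if it inherits two copies of the
#' deletion allele. SNP calls carry configurable genotyping error and
#' missingness.
#'
#' The optional layout arguments condition the transmission of the deletion
#' locus (not the flanking markers) so a fixed family structure — e.g. the
#' default study layout of 3 carrier dams and 2 affected offspring each —
#' can be reproduced at any seed. With both set to `NULL` transmission is
#' fully stochastic (used for segregation-ratio checks).
#'
#' @param model A `population_model`.
#' @param deletion_interval List or vector `(chrom, start, end)`; 1-based
#'   inclusive breakpoints on a model chromosome.
#' @param inserted_seq Replacement sequence at the deletion junction
#'   (possibly empty).
#' @param n_dams Number of daughters mated back to the sire.
#' @param n_offspring_per_dam Offspring per daughter; scalar or vector of
#'   length `n_dams`.
#' @param seed Integer seed.
#' @param geno_error Per-call symmetric flip probability (default 0.002).
#' @param missing_rate Per-call missingness probability (default 0.01).
#' @param carrier_daughters `NULL` for stochastic transmission, or an integer:
#'   exactly this many daughters receive the deletion-bearing sire gamete.
#' @param affected_per_carrier_dam `NULL` for stochastic transmission, or an
#'   integer: exactly this many offspring of each carrier daughter are made
#'   homozygous for the deletion (the remainder are conditioned against it).
#' @param n_genotyped_cases,n_genotyped_unaffected Number of affected /
#'   unaffected offspring flagged as available for genotyping (`NULL` = all).
#' @return List with elements `pedigree` (a [pedigree()]), `genotypes`
#'   (a [genotype_matrix()] restricted to genotyped individuals) and `truth`
#'   (class `family_truth`: `deletion`, `inserted_seq`, `carrier_status`).
#' @export
simulate_backcross <- function(model, deletion_interval,
                               inserted_seq = "", n_dams = 5,
                               n_offspring_per_dam = 5, seed = NULL,
                               geno_error = 0.002, missing_rate = 0.01,
                               carrier_daughters = NULL,
                               affected_per_carrier_dam = NULL,
                               n_genotyped_cases = NULL,
                               n_genotyped_unaffected = NULL,
                               ibd_flank_mb = c(4, 12)) {
  del <- as.list(deletion_interval)
  names(del) <- c("chrom", "start", "end")
  del$start <- as.numeric(del$start); del$end <- as.numeric(del$end)
  ci <- match(del$chrom, model$chromosomes$name)
  if (is.na(ci)) stop_arg("deletion chromosome '%s' not in model", del$chrom)
  if (del$start < 1 || del$end > model$chromosomes$length[ci] ||
      del$start > del$end) {
    stop_arg("deletion interval off chromosome")
  }
  n_off <- rep_len(n_offspring_per_dam, n_dams)
  del_locus <- list(chrom = del$chrom, pos = del$start, end = del$end)

  with_seed(seed, {
    # sire: heterozygous for the deletion by construction
    sire_h1 <- founder_haplotype(model); sire_h1$del <- 1L
    sire_h2 <- founder_haplotype(model)

    founder_dam_haps <- lapply(seq_len(n_dams), function(i) {
      list(founder_haplotype(model), founder_haplotype(model))
    })

    force_dtr <- rep(NA_integer_, n_dams)
    if (!is.null(carrier_daughters)) {
      if (carrier_daughters > n_dams) stop_arg("more carrier daughters than daughters")
      force_dtr <- rep(0L, n_dams)
      force_dtr[sample.int(n_dams, carrier_daughters)] <- 1L
    }
    # draw the IBD-block bound distances (Mb) for one forced meiosis; the
    # optional caps keep a daughter-to-offspring bound strictly inside the
    # bound of the deletion haplotype the daughter herself received, so the
    # maternal lineage always exits to founder-dam content before it could
    # expose the sire's other haplotype near the block
    draw_bounds <- function(cap = NULL) {
      if (is.null(ibd_flank_mb)) return(NULL)
      hi <- rep_len(ibd_flank_mb[2], 2L)
      if (!is.null(cap)) hi <- pmin(hi, cap * 0.99)
      lo <- pmin(ibd_flank_mb[1], hi)
      b <- stats::runif(2, lo, hi) * 1e6
      c(del$start - b[1], del$end + b[2])
    }
    dtr_bounds <- vector("list", n_dams)
    daughters <- lapply(seq_len(n_dams), function(i) {
      mxo <- if (!is.na(force_dtr[i]) && force_dtr[i] == 1L) draw_bounds()
      sg <- gamete(sire_h1, sire_h2, model, del_locus,
                   force_del = force_dtr[i], mandatory_xo = mxo)
      dg <- gamete(founder_dam_haps[[i]][[1]], founder_dam_haps[[i]][[2]],
                   model, del_locus)
      dtr_bounds[[i]] <<- mxo
      list(h1 = sg, h2 = dg)
    })

    offspring <- list()
    off_dam <- integer(0)
    for (i in seq_len(n_dams)) {
      dtr <- daughters[[i]]
      is_carrier <- (dtr$h1$del + dtr$h2$del) >= 1L
      force_off <- rep(NA_integer_, n_off[i])
      if (!is.null(affected_per_carrier_dam) && is_carrier) {
        if (affected_per_carrier_dam > n_off[i]) {
          stop_arg("affected_per_carrier_dam exceeds offspring per dam")
        }
        force_off <- rep(0L, n_off[i])
        force_off[sample.int(n_off[i], affected_per_carrier_dam)] <- 1L
      }
      for (j in seq_len(n_off[i])) {
        # conditioning: force the maternal gamete; the paternal one is forced
        # only when the offspring must be (or must not be) homozygous
        if (is.na(force_off[j])) {
          mg <- gamete(dtr$h1, dtr$h2, model, del_locus)
          pg <- gamete(sire_h1, sire_h2, model, del_locus)
        } else if (force_off[j] == 1L) {
          cap <- if (is.null(dtr_bounds[[i]])) NULL else
            c((del$start - dtr_bounds[[i]][1]) / 1e6,
              (dtr_bounds[[i]][2] - del$end) / 1e6)
          mg <- gamete(dtr$h1, dtr$h2, model, del_locus, force_del = 1L,
                       mandatory_xo = draw_bounds(cap))
          pg <- gamete(sire_h1, sire_h2, model, del_locus, force_del = 1L,
                       mandatory_xo = draw_bounds())
        } else {
          mg <- gamete(dtr$h1, dtr$h2, model, del_locus)
          pg <- gamete(sire_h1, sire_h2, model, del_locus,
                       force_del = if (mg$del == 1L) 0L else NA_integer_)
        }
        offspring[[length(offspring) + 1L]] <- list(h1 = pg, h2 = mg)
        off_dam <- c(off_dam, i)
      }
    }

    ids <- list(
      sire = "sire",
      fdam = sprintf("founder_dam_%d", seq_len(n_dams)),
      dam = sprintf("dam_%d", seq_len(n_dams)),
      off = sprintf("offspring_%02d", seq_along(offspring)))

    copies <- c(
      stats::setNames(1L, ids$sire),
      stats::setNames(rep(0L, n_dams), ids$fdam),
      stats::setNames(vapply(daughters, function(d) d$h1$del + d$h2$del,
                             integer(1)), ids$dam),
      stats::setNames(vapply(offspring, function(o) o$h1$del + o$h2$del,
                             integer(1)), ids$off))
    affected <- stats::setNames(copies == 2L, names(copies))

    aff_off <- ids$off[affected[ids$off]]
    unaff_off <- setdiff(ids$off, aff_off)
    geno_cases <- if (is.null(n_genotyped_cases)) aff_off else {
      if (n_genotyped_cases > length(aff_off)) {
        stop_arg("requested %d genotyped cases but only %d affected offspring",
                 n_genotyped_cases, length(aff_off))
      }
      sort(sample(aff_off, n_genotyped_cases))
    }
    geno_unaff <- if (is.null(n_genotyped_unaffected)) unaff_off else {
      sort(sample(unaff_off, min(n_genotyped_unaffected, length(unaff_off))))
    }
    genotyped_ids <- c(ids$sire, ids$dam, geno_cases, geno_unaff)

    ped <- pedigree(data.frame(
      id = c(ids$sire, ids$fdam, ids$dam, ids$off),
      sire = c(NA, rep(NA, n_dams), rep(ids$sire, n_dams), rep(ids$sire, length(offspring))),
      dam = c(NA, rep(NA, n_dams), ids$fdam, ids$dam[off_dam]),
      sex = c("M", rep("F", 2 * n_dams),
              sample(c("M", "F"), length(offspring), replace = TRUE)),
      affected = c(FALSE, rep(FALSE, 2 * n_dams), unname(affected[ids$off])),
      genotyped = c(ids$sire, ids$fdam, ids$dam, ids$off) %in% genotyped_ids,
      stringsAsFactors = FALSE))

    haps <- c(
      stats::setNames(list(list(h1 = sire_h1, h2 = sire_h2)), ids$sire),
      stats::setNames(daughters, ids$dam),
      stats::setNames(offspring, ids$off))
    calls <- t(vapply(genotyped_ids, function(id) {
      h <- haps[[id]]
      corrupt_calls(h$h1$alleles + h$h2$alleles, geno_error, missing_rate)
    }, integer(nrow(model$snps))))
    rownames(calls) <- genotyped_ids
    map <- data.frame(snp_id = model$snps$snp_id, chrom = model$snps$chrom,
                      pos = model$snps$pos, allele_a = model$snps$allele_a,
                      allele_b = model$snps$allele_b, stringsAsFactors = FALSE)

    truth <- structure(list(deletion = del, inserted_seq = inserted_seq,
                            carrier_status = copies),
                       class = "family_truth")
    stopifnot(all(copies[names(affected)[affected]] == 2L))
    list(pedigree = ped, genotypes = genotype_matrix(calls, map), truth = truth)
  })
}

#' @export
print.family_truth <- function(x, ...) {
  cat(sprintf("family_truth: %s:%s-%s delins'%s'; carriers het=%d hom=%d of %d\n",
              x$deletion$chrom, format(x$deletion$start, scientific = FALSE),
              format(x$deletion$end, scientific = FALSE), x$inserted_seq,
              sum(x$carrier_status == 1L), sum(x$carrier_status == 2L),
              length(x$carrier_status)))
  invisible(x)
}

#' Simulate the default study-layout family
#'
#' Convenience wrapper reproducing the study design at chip-like marker
#' density: one 80-Mb chromosome with 1500 SNPs, a heterozygous
#' 50,173-bp deletion (replaced by `TGACAA`) in the sire at
#' chr14:56,451,029-56,501,201, 5 daughter-dams of which 3 carry the
#' deletion, 24 offspring of which 6 (2 per carrier dam) are affected,
#' and a genotyped subset of 3 cases, 9 unaffected siblings, all 5 dams
#' and the sire.
#'
#' @param seed Integer seed.
#' @param n_snps Markers on the simulated chromosome.
#' @param ... Passed on to [simulate_backcross()] (e.g. error rates).
#' @return As [simulate_backcross()], plus element `model`.
#' @export
simulate_default_family <- function(seed = NULL, n_snps = 1500, ...) {
  model <- simulate_population(n_chroms = 1, chrom_length = 80e6,
                               n_snps_per_chrom = n_snps,
                               seed = derive_seed(seed, 1L),
                               chrom_names = "chr14")
  fam <- simulate_backcross(
    model,
    deletion_interval = list(chrom = "chr14", start = 56451029, end = 56501201),
    inserted_seq = "TGACAA",
    n_dams = 5, n_offspring_per_dam = c(5, 5, 5, 5, 4),
    seed = derive_seed(seed, 2L),
    carrier_daughters = 3, affected_per_carrier_dam = 2,
    n_genotyped_cases = 3, n_genotyped_unaffected = 9, ...)
  fam$model <- model
  fam
}

#' Simulate a windowed + per-base depth profile over a deletion region
#'
#' Window counts are negative binomial with mean
#' `mean_depth * copy_number / 2` inside the deletion (with a floor of 2% of
#' `mean_depth`, emulating reads mismapped into the deleted interval) and
#' `mean_depth` outside; windows partially overlapping the deletion get the
#' overlap-weighted mixture mean. Per-base counts are Poisson with the same
#' means over a focal window around each breakpoint.
#'
#' @param truth A `family_truth`.
#' @param sample_id Individual whose copy number is read from
#'   `truth$carrier_status`.
#' @param region `(start, end)` in bp; must cover the deletion plus flanks.
#'   Default: deletion start - 100 kb to deletion end + 50 kb.
#' @param mean_depth Diploid mean depth (x-fold).
#' @param window_size Window width in bp (default 1000).
#' @param dispersion Negative-binomial dispersion `phi`
#'   (variance `mu + phi * mu^2`; default 0.1).
#' @param seed Integer seed.
#' @param per_base_flank Half-width in bp of the per-base focal window around
#'   each breakpoint (default 2000).
#' @param mismap_floor Floor on the in-deletion mean, as a fraction of
#'   `mean_depth` (default 0.02).
#' @return A [depth_profile()].
#' @export
simulate_depth <- function(truth, sample_id, region = NULL, mean_depth = 30,
                           window_size = 1000, dispersion = 0.1, seed = NULL,
                           per_base_flank = 2000, mismap_floor = 0.02) {
  if (window_size <= 0) stop_arg("window_size must be positive")
  d <- truth$deletion
  if (is.null(region)) region <- c(d$start - 100000, d$end + 50000)
  if (region[1] > d$start || region[2] < d$end) {
    stop_arg("region must cover the deletion plus flanks")
  }
  copies <- truth$carrier_status[sample_id]
  if (is.na(copies)) stop_arg("unknown sample '%s'", sample_id)
  copies <- unname(copies)
  cn <- 2L - copies
  mu_in <- max(mean_depth * cn / 2, mismap_floor * mean_depth)
  mu_out <- mean_depth

  starts <- seq(region[1], region[2] - window_size + 1, by = window_size)
  ends <- starts + window_size - 1
  frac_del <- interval_overlap(starts, ends, d$start, d$end) / window_size
  mu_w <- mu_out * (1 - frac_del) + mu_in * frac_del

  with_seed(seed, {
    counts <- stats::rnbinom(length(mu_w), mu = mu_w, size = 1 / dispersion)
    pos <- sort(unique(c(
      seq(max(region[1], d$start - per_base_flank),
          min(region[2], d$start + per_base_flank)),
      seq(max(region[1], d$end - per_base_flank),
          min(region[2], d$end + per_base_flank)))))
    inside <- pos >= d$start & pos <= d$end
    pb <- data.frame(pos = pos,
                     count = stats::rpois(length(pos),
                                          ifelse(inside, mu_in, mu_out)))
    depth_profile(d$chrom, window_size, starts, counts, per_base = pb)
  })
}

#' Simulate discordant read pairs across a deletion
#'
#' Each pair is drawn from a fragment of length `Normal(nominal_insert_mean,
#' insert_sd)` on the deletion allele, placed so that the two reads straddle
#' the deletion junction. On the reference the apparent insert therefore
#' equals the fragment length plus the deleted length minus the length of
#' the replacement insertion.
#'
#' @param truth A `family_truth`.
#' @param carrier_status Deletion-allele copies of the sample (0, 1 or 2);
#'   samples with 0 copies produce no pairs.
#' @param n_pairs Number of pairs to draw (>= 0).
#' @param nominal_insert_mean,insert_sd Fragment-length distribution (bp).
#' @param seed Integer seed.
#' @param read_len Read length in bp (default 100).
#' @return Data frame with columns `left_end` (rightmost base of the left
#'   read), `right_start` (leftmost base of the right read) and
#'   `nominal_insert` (the drawn fragment length); zero rows for non-carriers.
#' @export
simulate_discordant_pairs <- function(truth, carrier_status, n_pairs,
                                      nominal_insert_mean = 400,
                                      insert_sd = 30, seed = NULL,
                                      read_len = 100) {
  if (n_pairs < 0) stop_arg("n_pairs must be non-negative")
  empty <- data.frame(left_end = integer(0), right_start = integer(0),
                      nominal_insert = integer(0))
  if (carrier_status < 1L || n_pairs == 0L) return(empty)
  d <- truth$deletion
  ins <- nchar(truth$inserted_seq)
  del_len <- interval_length(d$start, d$end)
  with_seed(seed, {
    frag <- round(stats::rnorm(n_pairs, nominal_insert_mean, insert_sd))
    gap <- frag - 2L * read_len
    ok <- gap > ins
    while (!all(ok)) {  # resample unusable short fragments
      frag[!ok] <- round(stats::rnorm(sum(!ok), nominal_insert_mean, insert_sd))
      gap <- frag - 2L * read_len
      ok <- gap > ins
    }
    u <- vapply(gap, function(g) sample.int(g - ins + 1L, 1L) - 1L, integer(1))
    left_end <- d$start - 1L - u
    right_start <- d$end + (gap - u - ins) + 1L
    data.frame(left_end = as.integer(left_end),
               right_start = as.integer(right_start),
               nominal_insert = as.integer(frag))
  })
}

#' Simulate a control-cohort site table
#'
#' Draws a table of biallelic sites observed in a control cohort, emulating a
#' large sequenced reference population at reduced sample size. Sites listed
#' in `exclude_sites` (e.g. variants configured as private to the sire) are
#' guaranteed absent from the output.
#'
#' @param model A `population_model`.
#' @param n_samples Cohort size (>= 1); reported as metadata and used for the
#'   simulated allele counts.
#' @param site_density Expected segregating sites per bp (default 1/2000).
#' @param seed Integer seed.
#' @param exclude_sites Optional data frame with `chrom`, `pos`, `ref`, `alt`
#'   of sites that must not appear in the cohort.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `ac`
#'   (alternate-allele count among `2 * n_samples` chromosomes).
#' @export
simulate_control_cohort <- function(model, n_samples, site_density = 1 / 2000,
                                    seed = NULL, exclude_sites = NULL) {
  if (n_samples < 1) stop_arg("n_samples must be >= 1")
  if (site_density < 0) stop_arg("site_density must be non-negative")
  with_seed(seed, {
    tabs <- lapply(seq_len(nrow(model$chromosomes)), function(i) {
      n_sites <- round(model$chromosomes$length[i] * site_density)
      if (n_sites == 0L) return(NULL)
      pos <- sort(sample.int(model$chromosomes$length[i], n_sites))
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, n_sites, replace = TRUE)
      alt <- vapply(ref, function(x) sample(setdiff(bases, x), 1L), character(1))
      data.frame(chrom = model$chromosomes$name[i], pos = pos, ref = ref,
                 alt = unname(alt),
                 ac = 1L + stats::rbinom(n_sites, 2L * n_samples - 1L, 0.1),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, tabs)
    if (is.null(out)) {
      out <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0), ac = integer(0))
    }
    if (!is.null(exclude_sites) && nrow(out) > 0L) {
      out <- out[!(site_key(out) %in% site_key(exclude_sites)), , drop = FALSE]
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate the sequenced carrier parent's small-variant table
#'
#' Produces a variant table for the sire as a variant caller would emit it:
#' a sample of cohort-shared sites (mixed het / hom genotypes) plus
#' `n_private` heterozygous sites absent from the cohort. Private sites are
#' placed outside `exclude` so that a run on the default family reproduces
#' the configuration in which no private small variant falls inside the
#' mapped candidate region and the analysis escalates to structural
#' variants.
#'
#' @param model A `population_model`.
#' @param cohort Cohort site table from [simulate_control_cohort()].
#' @param n_shared Number of cohort sites also called in the sire.
#' @param n_private Number of sire-private heterozygous sites.
#' @param exclude Optional data frame `chrom`, `start`, `end`: intervals in
#'   which no private site is placed.
#' @param seed Integer seed.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `genotype`.
#' @export
simulate_sire_variants <- function(model, cohort, n_shared = 200,
                                   n_private = 25, exclude = NULL,
                                   seed = NULL) {
  with_seed(seed, {
    shared <- cohort[sample.int(nrow(cohort), min(n_shared, nrow(cohort))), ,
                     drop = FALSE]
    shared$genotype <- sample(c("het", "hom_alt"), nrow(shared),
                              replace = TRUE, prob = c(0.7, 0.3))
    shared$ac <- NULL
    priv <- NULL
    if (n_private > 0L) {
      bases <- c("A", "C", "G", "T")
      rows <- list()
      while (length(rows) < n_private) {
        i <- sample.int(nrow(model$chromosomes), 1L)
        p <- sample.int(model$chromosomes$length[i], 1L)
        ch <- model$chromosomes$name[i]
        if (!is.null(exclude)) {
          hit <- exclude$chrom == ch & exclude$start <= p & p <= exclude$end
          if (any(hit)) next
        }
        r <- sample(bases, 1L)
        a <- sample(setdiff(bases, r), 1L)
        if (paste(ch, p, r, a) %in% site_key(cohort)) next
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, pos = p, ref = r, alt = a, genotype = "het",
          stringsAsFactors = FALSE)
      }
      priv <- do.call(rbind, rows)
    }
    out <- rbind(shared, priv)
    out <- out[order(match(out$chrom, model$chromosomes$name), out$pos), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
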