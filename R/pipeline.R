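# End-to-end orchestration: QC -> ROH mapping -> pedigree filter -> small-
# variant triage -> (on an empty candidate-region variant set) read-depth SV
# calling -> PCR co-segregation -> consequence annotation.

#' Synthetic gene model overlapping a deletion
#'
#' Builds a deterministic six-exon fixture gene positioned relative to a
#' deletion so that exons 2-4 (522 coding bp, 174 aa) fall inside it and the
#' full CDS is 729 bp (243 aa); the deletion therefore removes 71.6% of the
#' protein. This is a synthetic stand-in with the same arithmetic structure
#' as the disrupted R-spondin gene, not its real coordinates.
#'
#' @param deletion List `(chrom, start, end)`.
#' @param name Gene name (default `"synthetic_rspo_like"`).
#' @return A [gene_model()].
#' @export
synthetic_gene_model <- function(deletion, name = "synthetic_rspo_like") {
  d <- normalize_interval(deletion)
  s <- d$start; e <- d$end
  stopifnot(e - s + 1 >= 40195 + 2000)
  exons <- data.frame(
    start = c(s - 6000, s + 1000, s + 20000, s + 40000, e + 2000, e + 4000),
    end = c(s - 5800, s + 1146, s + 20179, s + 40194, e + 2089, e + 4300))
  cds <- data.frame(
    start = c(s - 5900, s + 1000, s + 20000, s + 40000, e + 2000, e + 4000),
    end = c(s - 5841, s + 1146, s + 20179, s + 40194, e + 2089, e + 4056))
  gene_model(name, d$chrom, "+", exons, cds)
}

#' Default pipeline configuration for the simulated study family
#'
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 42) {
  list(
    simulation = list(seed = seed, n_snps = 1500),
    qc = list(min_call_rate = 0.90, min_maf = 0.01),
    roh = list(min_snps = 30, min_length_bp = 100000,
               max_missing_per_run = 2, max_het_per_run = 0),
    variants = list(cohort_n = 100, site_density = 1 / 2000,
                    n_shared = 200, n_private = 30),
    sv = list(mean_depth = 30, window_size = 1000, dispersion = 0.1,
              n_pairs = 20, nominal_insert_mean = 400, insert_sd = 30),
    pcr = list(max_product = 5000, n_population_controls = 182),
    stages = c("qc", "roh", "variants", "sv", "pcr", "annotation"))
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full mapping workflow on a simulated family
#'
#' Stages run in order: genotype QC, per-case ROH detection with
#' shared-allele intersection, pedigree-consistency filtering, small-variant
#' triage (heterozygous selection, cohort subtraction, candidate-region
#' restriction), and — only when the candidate region contains no surviving
#' small variant — read-depth structural-variant calling, followed by PCR
#' co-segregation testing and consequence annotation. The escalation branch
#' is explicit: a non-empty candidate-region variant set skips the SV stage
#' and the report records why.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or the
#'   path of a JSON file holding one.
#' @param verbose Emit one structured message per stage.
#' @return Object of class `mapping_report`; a nested list of plain values
#'   (counts, intervals, test statistics, calls, parameters and seeds) that
#'   serializes losslessly to JSON via [write_mapping_report()].
#' @export
run_pipeline <- function(config = default_pipeline_config(), verbose = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  has_seed <- !is.null(config$simulation$seed)
  defaults <- default_pipeline_config()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]])) {
      miss <- setdiff(names(defaults[[nm]]), names(config[[nm]]))
      config[[nm]][miss] <- defaults[[nm]][miss]
    }
  }
  if (!has_seed) {
    stop_arg("configuration error: simulation block must name a seed")
  }
  stages <- config$stages
  needs <- list(roh = "qc", variants = "roh", sv = "variants",
                pcr = "sv", annotation = "sv")
  for (st in stages) {
    if (!is.null(needs[[st]]) && !(needs[[st]] %in% stages)) {
      stop_arg("configuration error: stage '%s' requires stage '%s'",
               st, needs[[st]])
    }
  }
  seed <- config$simulation$seed
  report <- list(config = config, seed = seed)

  fam <- simulate_default_family(seed = seed, n_snps = config$simulation$n_snps)
  ped <- fam$pedigree
  truth <- fam$truth
  cases <- ped$id[ped$affected & ped$genotyped]
  report$simulation <- list(
    n_individuals = nrow(ped), n_genotyped = sum(ped$genotyped),
    n_cases_genotyped = length(cases),
    true_deletion = truth$deletion, inserted_seq = truth$inserted_seq)

  # --- QC ---------------------------------------------------------------
  qc <- qc_filter(fam$genotypes, config$qc$min_call_rate, config$qc$min_maf)
  report$qc <- list(n_input_snps = qc$report$n_input_snps,
                    n_removed_callrate = qc$report$n_removed_callrate,
                    n_removed_maf = qc$report$n_removed_maf,
                    n_retained = qc$report$n_retained)
  pipeline_log(verbose, "qc: %d SNPs in, %d retained",
               qc$report$n_input_snps, qc$report$n_retained)
  if (!("roh" %in% stages)) {
    return(structure(report, class = "mapping_report"))
  }

  # --- ROH mapping + pedigree filter -------------------------------------
  params <- do.call(roh_params, config$roh)
  roh_by_case <- lapply(stats::setNames(cases, cases), function(id) {
    detect_roh_sample(qc$genotypes, id, params)
  })
  shared <- shared_case_regions(roh_by_case, qc$genotypes, params)
  surviving <- pedigree_filter(shared, qc$genotypes, ped)
  region_df <- function(r) {
    lapply(seq_len(nrow(r)), function(i) {
      list(chrom = r$chrom[i], start = r$start[i], end = r$end[i],
           n_snps = r$n_snps[i])
    })
  }
  report$roh <- list(
    n_roh_per_case = vapply(roh_by_case, nrow, integer(1)),
    n_shared_regions = nrow(shared),
    n_surviving_regions = nrow(surviving),
    shared_regions = region_df(shared),
    candidate_regions = region_df(surviving))
  pipeline_log(verbose, "roh: %d shared regions, %d survive the pedigree filter",
               nrow(shared), nrow(surviving))
  if (!("variants" %in% stages)) {
    return(structure(report, class = "mapping_report"))
  }

  # --- small-variant triage ----------------------------------------------
  vcfg <- config$variants
  cohort <- simulate_control_cohort(fam$model, vcfg$cohort_n,
                                    vcfg$site_density,
                                    seed = derive_seed(seed, 11L))
  dd <- truth$deletion
  sire_vars <- simulate_sire_variants(
    fam$model, cohort, n_shared = vcfg$n_shared, n_private = vcfg$n_private,
    exclude = data.frame(chrom = dd$chrom, start = dd$start - 2e7,
                         end = dd$end + 2e7),
    seed = derive_seed(seed, 12L))
  het <- select_heterozygous(sire_vars)
  priv <- subtract_cohort(het, cohort)
  in_region <- if (nrow(surviving)) {
    restrict_to_intervals(priv, surviving[, c("chrom", "start", "end")])
  } else priv[0, , drop = FALSE]
  report$variants <- list(
    n_sire = nrow(sire_vars), n_het = nrow(het), n_private = nrow(priv),
    n_in_candidate_region = nrow(in_region))
  escalate <- nrow(in_region) == 0L
  report$variants$escalate_to_sv <- escalate
  report$variants$note <- if (escalate) {
    "no small variant in the candidate region; escalating to structural-variant analysis"
  } else {
    "candidate-region small variants found; structural-variant stage not triggered"
  }
  pipeline_log(verbose, "variants: %d het, %d private, %d in candidate region",
               nrow(het), nrow(priv), nrow(in_region))
  if (!("sv" %in% stages) || !escalate) {
    return(structure(report, class = "mapping_report"))
  }

  # --- read-depth SV calling ---------------------------------------------
  scfg <- config$sv
  profile <- simulate_depth(truth, "sire", mean_depth = scfg$mean_depth,
                            window_size = scfg$window_size,
                            dispersion = scfg$dispersion,
                            seed = derive_seed(seed, 21L))
  pairs <- simulate_discordant_pairs(truth, truth$carrier_status[["sire"]],
                                     scfg$n_pairs, scfg$nominal_insert_mean,
                                     scfg$insert_sd,
                                     seed = derive_seed(seed, 22L))
  call <- call_deletion(profile, pairs, scfg$nominal_insert_mean,
                        scfg$insert_sd, inserted_seq = truth$inserted_seq)
  report$sv <- list(
    chrom = call$chrom, start = call$start, end = call$end,
    length_bp = call$end - call$start + 1,
    genotype = call$genotype, depth_ratio = call$depth_ratio,
    mean_upstream = call$report$mean_upstream,
    mean_inside = call$report$mean_inside,
    mean_downstream = call$report$mean_downstream,
    p_up_vs_in = unname(call$report$up_vs_in["p"]),
    p_in_vs_down = unname(call$report$in_vs_down["p"]),
    p_up_vs_down = unname(call$report$up_vs_down["p"]),
    pair_support = call$pair_support,
    pair_implied_span = call$pair_implied_span,
    hgvs = hgvs_name(call))
  pipeline_log(verbose, "sv: %s %s (ratio %.3f, pair support %d)",
               report$sv$hgvs, call$genotype, call$depth_ratio,
               call$pair_support)
  if (!("pcr" %in% stages)) {
    return(structure(report, class = "mapping_report"))
  }

  # --- PCR co-segregation -------------------------------------------------
  pcfg <- config$pcr
  fw <- primer("Del_F", "ACGTACGTACGTACGTACGT", "forward", call$start - 575)
  rv_wt <- primer("DelWt_R", "ACGTACGTACGTACGTACGT", "reverse", call$start + 394)
  rv_mt <- primer("DelMt_R", "ACGTACGTACGTACGTACGT", "reverse", call$end + 161)
  del_iv <- list(chrom = call$chrom, start = call$start, end = call$end)
  truth_gt <- c("+/+", "+/-", "-/-")[truth$carrier_status + 1L]
  names(truth_gt) <- names(truth$carrier_status)
  assayed <- ped$id[ped$genotyped | (ped$affected & ped$id %in% names(truth_gt))]
  pcr_calls <- vapply(assayed, function(id) {
    pcr_genotype(truth_gt[[id]], fw, rv_wt, rv_mt, del_iv,
                 truth$inserted_seq, pcfg$max_product)$genotype
  }, character(1))
  coseg <- cosegregation_check(pcr_calls, ped)
  carrier_dams <- intersect(names(pcr_calls)[pcr_calls == "+/-"],
                            ped$id[ped$id %in% ped$dam])
  ratio <- segregation_ratio_test(ped, carrier_dams)
  screen <- population_screen(rep("+/+", pcfg$n_population_controls))
  report$pcr <- list(
    product_wt = amplicon_length(fw, rv_wt, allele_model(), pcfg$max_product),
    product_del = amplicon_length(fw, rv_mt, alleles_for_genotype(
      del_iv, truth$inserted_seq, "-/-")[[1]], pcfg$max_product),
    n_assayed = length(pcr_calls),
    genotype_counts = as.list(table(pcr_calls)),
    cosegregation_perfect = coseg$perfect,
    n_violations = nrow(coseg$violations),
    segregation = list(n_offspring = ratio$n_offspring,
                       n_affected = ratio$n_affected,
                       p_value = ratio$p_value),
    population_screen_carriers = screen,
    population_screen_n = pcfg$n_population_controls)
  pipeline_log(verbose, "pcr: co-segregation %s, ratio p = %.3f",
               if (coseg$perfect) "perfect" else "violated", ratio$p_value)
  if (!("annotation" %in% stages)) {
    return(structure(report, class = "mapping_report"))
  }

  # --- consequence annotation ---------------------------------------------
  gm <- synthetic_gene_model(del_iv)
  impact <- coding_impact(del_iv, gm)
  report$annotation <- list(
    gene = impact$gene, n_exons_deleted = impact$n_exons_deleted,
    cds_bp_deleted = impact$cds_bp_deleted, aa_deleted = impact$aa_deleted,
    total_aa = impact$total_aa, protein_pct = impact$protein_pct,
    in_frame = impact$in_frame)
  pipeline_log(verbose, "annotation: %d exons, %d aa (%.1f%% of protein)",
               impact$n_exons_deleted, impact$aa_deleted, impact$protein_pct)
  structure(report, class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("mapping_report\n")
  cat(sprintf("  qc: %d SNPs -> %d retained\n", x$qc$n_input_snps,
              x$qc$n_retained))
  if (!is.null(x$roh)) {
    cat(sprintf("  roh: %d shared -> %d candidate region(s)\n",
                x$roh$n_shared_regions, x$roh$n_surviving_regions))
    for (r in x$roh$candidate_regions) {
      cat(sprintf("    %s:%s-%s (%d SNPs)\n", r$chrom,
                  format(r$start, scientific = FALSE),
                  format(r$end, scientific = FALSE), r$n_snps))
    }
  }
  if (!is.null(x$variants)) {
    cat(sprintf("  variants: %d private het; %d in candidate region — %s\n",
                x$variants$n_private, x$variants$n_in_candidate_region,
                x$variants$note))
  }
  if (!is.null(x$sv)) {
    cat(sprintf("  sv: %s %s %s, depth ratio %.3f, pair support %d\n",
                x$sv$chrom, x$sv$hgvs, x$sv$genotype, x$sv$depth_ratio,
                x$sv$pair_support))
  }
  if (!is.null(x$pcr)) {
    cat(sprintf("  pcr: wt %d bp / del %d bp; co-segregation %s; ratio %d/%d, p = %.3f\n",
                x$pcr$product_wt, x$pcr$product_del,
                if (x$pcr$cosegregation_perfect) "perfect" else "VIOLATED",
                x$pcr$segregation$n_affected, x$pcr$segregation$n_offspring,
                x$pcr$segregation$p_value))
  }
  if (!is.null(x$annotation)) {
    cat(sprintf("  annotation: %s, %d exons deleted, %d/%d aa (%.1f%%)\n",
                x$annotation$gene, x$annotation$n_exons_deleted,
                x$annotation$aa_deleted, x$annotation$total_aa,
                x$annotation$protein_pct))
  }
  invisible(x)
}

#' Write / read a mapping report as JSON
#'
#' The report is a nested list of plain values, so the JSON round trip is
#' lossless.
#'
#' @param report A `mapping_report`.
#' @param path Output path.
#' @return `path` invisibly (writer); a `mapping_report` (reader).
#' @export
write_mapping_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_mapping_report
#' @export
read_mapping_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "mapping_report")
}
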