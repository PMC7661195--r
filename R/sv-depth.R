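# Read-depth deletion detection: windowed step scan, Welch flank tests,
# per-base breakpoint refinement, depth-ratio genotyping and discordant
# read-pair corroboration.

#' Scan a depth profile for low-coverage segments
#'
#' Finds contiguous maximal runs of at least `min_len_windows` windows whose
#' running-median-smoothed count falls below `max_ratio` times the global
#' median window count — the step-shaped coverage drop a (hemi)zygous
#' deletion leaves in windowed depth. Smoothing makes the run detection
#' robust to single overdispersed windows inside a deletion; each run's
#' edges are then refined at window resolution by a least-squares step fit
#' on the raw counts around the coarse edge.
#'
#' @param profile A [depth_profile()].
#' @param min_len_windows Minimum run length in windows (default 10).
#' @param max_ratio Fraction of the median below which a (smoothed) window
#'   counts as low (default 0.75).
#' @param smooth_windows Width of the running median, in windows; an odd
#'   number (default 9).
#' @return Data frame with columns `chrom`, `start`, `end` (bp, 1-based
#'   inclusive over the windows of the run), `n_windows`, `mean_count`;
#'   sorted and non-overlapping.
#' @export
segment_scan <- function(profile, min_len_windows = 10, max_ratio = 0.75,
                         smooth_windows = 9) {
  n <- length(profile$count)
  if (n < 3 * min_len_windows) {
    stop_arg("profile too short: need at least 3 x min_len_windows windows")
  }
  med <- stats::median(profile$count)
  if (med == 0) stop_arg("no baseline coverage")
  k <- min(smooth_windows, n - (1 - n %% 2))
  smoothed <- stats::runmed(profile$count, k, endrule = "median")
  # two-pass baseline: windows flagged low by the provisional threshold are
  # excluded from the diploid baseline, so a deletion occupying a sizeable
  # fraction of the profiled region does not drag the threshold down with it
  base <- stats::median(profile$count[smoothed >= max_ratio * med])
  if (!is.na(base) && base > 0) med <- base
  low <- smoothed < max_ratio * med
  # close single/double-window interruptions inside a low run
  r0 <- rle(as.vector(low))
  if (length(r0$lengths) > 2L) {
    inner <- 2:(length(r0$lengths) - 1L)
    r0$values[inner][!r0$values[inner] & r0$lengths[inner] <= 2L] <- TRUE
  }
  r <- rle(inverse.rle(r0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len_windows)

  # window-resolution edge refinement on the raw counts: each edge is the
  # least-squares two-segment step split fitted over the stretch from the
  # neighbouring run (or profile end) to the middle of the current run, so
  # the fit always brackets the true step with a long baseline on both sides
  refine <- function(lo, hi, left_edge) {
    x <- profile$count[lo:hi]
    if (length(x) < 2L || length(unique(x)) == 1L) {
      return(if (left_edge) lo else hi)
    }
    split <- best_step_split(lo:hi, x, tol = 0)
    if (is.null(split)) {
      if (left_edge) lo else hi
    } else if (left_edge) split else split - 1L
  }
  mid <- floor((starts[keep] + ends[keep]) / 2)
  prev_end <- c(1L, ends[keep][-length(keep)] + 1L)
  next_start <- c(starts[keep][-1L] - 1L, n)
  seg_start <- vapply(seq_along(keep), function(b) {
    refine(prev_end[b], mid[b], TRUE)
  }, numeric(1))
  seg_end <- vapply(seq_along(keep), function(b) {
    refine(mid[b], next_start[b], FALSE)
  }, numeric(1))

  out <- data.frame(
    chrom = rep(profile$chrom, length(keep)),
    start = profile$window_start[seg_start],
    end = profile$window_start[seg_end] + profile$window_size - 1,
    n_windows = seg_end - seg_start + 1,
    mean_count = vapply(seq_along(keep), function(b) {
      mean(profile$count[seg_start[b]:seg_end[b]])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

window_counts_in <- function(profile, interval) {
  w_end <- profile$window_start + profile$window_size - 1
  profile$count[profile$window_start >= interval[1] & w_end <= interval[2]]
}

#' Welch flank tests of a candidate deletion segment
#'
#' Compares windowed counts inside the segment against an upstream and a
#' downstream flank with three two-sided Welch (unequal-variance) two-sample
#' t-tests: upstream vs inside, inside vs downstream, upstream vs
#' downstream. The third is the negative control: for a genuine deletion the
#' two flanks should not differ.
#'
#' @param profile A [depth_profile()].
#' @param segment `(start, end)` of the candidate segment in bp.
#' @param flank_up,flank_down `(start, end)` of the flank intervals in bp.
#'   Defaults: 100 kb immediately upstream and 50 kb immediately downstream
#'   of the segment.
#' @return Object of class `coverage_test_report`: per-stratum means and
#'   window counts, and `t`/`p` for the three comparisons. Raw p-values are
#'   reported; the three tests are planned comparisons and no multiplicity
#'   adjustment is applied.
#' @export
flank_tests <- function(profile, segment, flank_up = NULL, flank_down = NULL) {
  if (is.null(flank_up)) flank_up <- c(segment[1] - 100000, segment[1] - 1)
  if (is.null(flank_down)) flank_down <- c(segment[2] + 1, segment[2] + 50000)
  strata <- list(upstream = window_counts_in(profile, flank_up),
                 inside = window_counts_in(profile, segment),
                 downstream = window_counts_in(profile, flank_down))
  for (nm in names(strata)) {
    x <- strata[[nm]]
    if (length(x) < 2) stop_arg("stratum '%s' has fewer than 2 windows", nm)
    if (stats::var(x) == 0) stop_arg("stratum '%s' has zero variance", nm)
  }
  welch <- function(x, y) {
    tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
    c(t = unname(tt$statistic), p = tt$p.value)
  }
  structure(list(
    mean_upstream = mean(strata$upstream),
    mean_inside = mean(strata$inside),
    mean_downstream = mean(strata$downstream),
    n_windows = vapply(strata, length, integer(1)),
    up_vs_in = welch(strata$upstream, strata$inside),
    in_vs_down = welch(strata$inside, strata$downstream),
    up_vs_down = welch(strata$upstream, strata$downstream)),
    class = "coverage_test_report")
}

#' @export
print.coverage_test_report <- function(x, ...) {
  cat(sprintf("coverage_test_report: means %.2fx | %.2fx | %.2fx (up|in|down)\n",
              x$mean_upstream, x$mean_inside, x$mean_downstream))
  cat(sprintf("  up vs in:   t = %8.2f, p = %.3g\n", x$up_vs_in["t"], x$up_vs_in["p"]))
  cat(sprintf("  in vs down: t = %8.2f, p = %.3g\n", x$in_vs_down["t"], x$in_vs_down["p"]))
  cat(sprintf("  up vs down: t = %8.2f, p = %.3g%s\n", x$up_vs_down["t"],
              x$up_vs_down["p"],
              if (x$up_vs_down["p"] > 0.05) " (n.s.)" else ""))
  invisible(x)
}

# Least-squares two-segment step fit: returns the split position minimizing
# the residual sum of squares, with `x[pos < split]` forming the left segment.
# Ties break to the leftmost split.
best_step_split <- function(pos, x, tol) {
  n <- length(x)
  cs <- cumsum(x); css <- cumsum(x^2)
  k <- seq_len(n - 1L)               # left segment = 1..k
  ss_left <- css[k] - cs[k]^2 / k
  ss_right <- (css[n] - css[k]) - (cs[n] - cs[k])^2 / (n - k)
  ss <- ss_left + ss_right
  ss0 <- css[n] - cs[n]^2 / n
  best <- which.min(ss)              # which.min takes the first (leftmost) tie
  if (ss0 <= 0 || (ss0 - ss[best]) / ss0 < tol) {
    return(NULL)
  }
  pos[best + 1L]                     # first position of the right segment
}

#' Refine deletion breakpoints from per-base depth
#'
#' For each edge independently, fits a two-segment step to the per-base
#' counts within `search_radius` of the approximate breakpoint and returns
#' the change point minimizing the least-squares step fit (ties to the
#' leftmost position). The left breakpoint is the first deleted base, the
#' right breakpoint the last deleted base.
#'
#' @param per_base Data frame `pos`, `count` (from a [depth_profile()]'s
#'   `per_base` element).
#' @param approx_left,approx_right Approximate breakpoints in bp (e.g. the
#'   segment bounds from [segment_scan()]).
#' @param search_radius Half-width of the search window in bp (default 2000).
#' @param tol Minimum relative reduction in residual sum of squares for a
#'   step to count as detected (default 0.05); below it the breakpoint is
#'   declared not resolvable.
#' @return Named numeric vector `c(left, right)`.
#' @export
refine_breakpoints <- function(per_base, approx_left, approx_right,
                               search_radius = 2000, tol = 0.05) {
  fit_edge <- function(center) {
    sel <- per_base$pos >= center - search_radius &
           per_base$pos <= center + search_radius
    if (sum(sel) < 4) stop_arg("per-base depth missing around position %s",
                               format(center, scientific = FALSE))
    ord <- order(per_base$pos[sel])
    best_step_split(per_base$pos[sel][ord], per_base$count[sel][ord], tol)
  }
  left <- fit_edge(approx_left)          # first low base
  right_split <- fit_edge(approx_right)  # first high base after the deletion
  if (is.null(left) || is.null(right_split)) {
    stop_arg("breakpoint not resolvable: no step exceeds the fit tolerance")
  }
  c(left = left, right = right_split - 1)
}

#' Genotype a deletion from the depth ratio
#'
#' The ratio `r = inside_mean / flank_mean` is compared against thresholds
#' midway between the copy-number expectations 0, 0.5 and 1:
#' `r < 0.25` is homozygous deleted (`-/-`), `0.25 <= r <= 0.75` heterozygous
#' (`+/-`), `r > 0.75` homozygous reference (`+/+`).
#'
#' @param inside_mean,flank_mean Mean window counts inside the deletion and
#'   over the flanks; `flank_mean` must be positive.
#' @param thresholds Lower/upper ratio cut points (default `c(0.25, 0.75)`).
#' @return List with `genotype` (`"-/-"`, `"+/-"`, `"+/+"`) and
#'   `depth_ratio`.
#' @export
genotype_from_depth <- function(inside_mean, flank_mean,
                                thresholds = c(0.25, 0.75)) {
  if (flank_mean <= 0) stop_arg("flank_mean must be positive")
  r <- inside_mean / flank_mean
  gt <- if (r < thresholds[1]) "-/-" else if (r <= thresholds[2]) "+/-" else "+/+"
  list(genotype = gt, depth_ratio = r)
}

#' Cluster discordant read pairs and estimate the implied deletion span
#'
#' Pairs whose apparent insert (reference span between the outer read ends)
#' exceeds the nominal fragment length by more than `4 * insert_sd` are
#' discordant. Discordant pairs are clustered by overlap of their
#' `[left_end, right_start]` spans; the largest cluster's member count and
#' median implied deletion length (apparent insert minus nominal) are
#' returned.
#'
#' @param pairs Data frame `left_end`, `right_start` (and optionally
#'   `nominal_insert`, ignored) as from [simulate_discordant_pairs()].
#' @param nominal_insert_mean Nominal fragment length in bp.
#' @param insert_sd Fragment-length SD defining the discordance cut
#'   (default 30).
#' @param read_len Read length in bp used to reconstruct the apparent insert
#'   (default 100).
#' @param verbose If `TRUE`, all clusters are returned in `clusters`.
#' @return List with `pair_support` (largest cluster size), `implied_span`
#'   (its median implied deletion length in bp, `NA` when no support) and,
#'   when `verbose`, `clusters` (data frame `n`, `implied_span`, `left`,
#'   `right`).
#' @export
cluster_discordant_pairs <- function(pairs, nominal_insert_mean,
                                     insert_sd = 30, read_len = 100,
                                     verbose = FALSE) {
  res <- list(pair_support = 0L, implied_span = NA_real_)
  if (nrow(pairs) == 0L) return(res)
  apparent <- pairs$right_start - pairs$left_end - 1 + 2 * read_len
  disc <- apparent > nominal_insert_mean + 4 * insert_sd
  if (!any(disc)) return(res)
  p <- pairs[disc, , drop = FALSE]
  app <- apparent[disc]
  ord <- order(p$left_end)
  p <- p[ord, , drop = FALSE]; app <- app[ord]
  # single-linkage by span overlap: a new cluster starts when a pair's span
  # no longer overlaps the running cluster span
  cl <- integer(nrow(p)); cl[1] <- 1L
  right_max <- p$right_start[1]
  for (i in seq_len(nrow(p))[-1]) {
    if (p$left_end[i] <= right_max) {
      cl[i] <- cl[i - 1L]
      right_max <- max(right_max, p$right_start[i])
    } else {
      cl[i] <- cl[i - 1L] + 1L
      right_max <- p$right_start[i]
    }
  }
  spans <- vapply(split(app, cl), function(a) {
    stats::median(a) - nominal_insert_mean
  }, numeric(1))
  sizes <- tabulate(cl)
  big <- which.max(sizes)
  res$pair_support <- sizes[big]
  res$implied_span <- unname(spans[big])
  if (verbose) {
    res$clusters <- data.frame(
      n = sizes, implied_span = unname(spans),
      left = vapply(split(p$left_end, cl), min, numeric(1)),
      right = vapply(split(p$right_start, cl), max, numeric(1)))
  }
  res
}

#' Call and characterize a deletion from a depth profile
#'
#' Convenience wrapper running the full depth workflow on one profile:
#' segment scan, Welch flank tests, per-base breakpoint refinement,
#' depth-ratio genotyping and (optionally) discordant-pair corroboration.
#' The largest detected segment is characterized.
#'
#' @param profile A [depth_profile()] with per-base focal counts.
#' @param pairs Optional discordant-pair data frame.
#' @param nominal_insert_mean,insert_sd Passed to
#'   [cluster_discordant_pairs()] when `pairs` is given.
#' @param inserted_seq Junction replacement sequence, if known from sequence
#'   evidence (depth alone cannot discover it); stored on the call.
#' @param ... Passed to [segment_scan()].
#' @return Object of class `deletion_call`: `chrom`, `start`, `end`,
#'   `inserted_seq`, `genotype`, `depth_ratio`, `report`
#'   (a `coverage_test_report`), `pair_support`, `pair_implied_span`.
#' @export
call_deletion <- function(profile, pairs = NULL, nominal_insert_mean = 400,
                          insert_sd = 30, inserted_seq = "", ...) {
  segs <- segment_scan(profile, ...)
  if (nrow(segs) == 0L) stop_arg("no low-coverage segment detected")
  seg <- segs[which.max(segs$end - segs$start), , drop = FALSE]
  report <- flank_tests(profile, c(seg$start, seg$end))
  if (is.null(profile$per_base)) stop_arg("profile lacks per-base focal counts")
  # per-base counts come in contiguous focal chunks; each edge is refined
  # within the chunk nearest the corresponding window-resolution edge
  pb <- profile$per_base[order(profile$per_base$pos), , drop = FALSE]
  chunk_id <- cumsum(c(1L, diff(pb$pos) > 1L))
  chunks <- lapply(split(pb$pos, chunk_id), range)
  nearest <- function(target) {
    d <- vapply(chunks, function(rg) {
      if (target < rg[1]) rg[1] - target else if (target > rg[2]) target - rg[2] else 0
    }, numeric(1))
    chunks[[which.min(d)]]
  }
  lc <- nearest(seg$start); rc <- nearest(seg$end)
  bp <- refine_breakpoints(pb, mean(lc), mean(rc),
                           search_radius = max(diff(lc), diff(rc)) / 2 + 1)
  gt <- genotype_from_depth(report$mean_inside,
                            mean(c(report$mean_upstream, report$mean_downstream)))
  support <- list(pair_support = 0L, implied_span = NA_real_)
  if (!is.null(pairs)) {
    support <- cluster_discordant_pairs(pairs, nominal_insert_mean, insert_sd)
  }
  structure(list(chrom = profile$chrom, start = unname(bp["left"]),
                 end = unname(bp["right"]), inserted_seq = inserted_seq,
                 genotype = gt$genotype, depth_ratio = gt$depth_ratio,
                 report = report, pair_support = support$pair_support,
                 pair_implied_span = support$implied_span),
            class = "deletion_call")
}

#' @export
print.deletion_call <- function(x, ...) {
  cat(sprintf("deletion_call: %s:%s-%s (%s bp) %s, depth ratio %.3f, pair support %d\n",
              x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(x$end - x$start + 1, scientific = FALSE),
              x$genotype, x$depth_ratio, x$pair_support))
  invisible(x)
}
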