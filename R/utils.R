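# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so seeded generators never perturb the session stream.
#' A `NULL` seed evaluates `expr` under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a master seed. Sub-seeds stay inside
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1009 + offset) %% .Machine$integer.max)
}

stop_arg <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# 1-based fully closed interval length.
interval_length <- function(start, end) {
  end - start + 1
}

# Overlap length of two closed intervals (0 when disjoint).
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

# Merge sorted-or-unsorted closed intervals (data.frame chrom/start/end) into
# a non-overlapping sorted set. Touching intervals (end + 1 == start) merge.
merge_intervals <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) return(intervals)
  out <- lapply(split(intervals, intervals$chrom), function(iv) {
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    starts <- iv$start[1]
    ends <- iv$end[1]
    if (nrow(iv) > 1L) {
      for (k in 2:nrow(iv)) {
        i <- length(starts)
        if (iv$start[k] <= ends[i] + 1) {
          ends[i] <- max(ends[i], iv$end[k])
        } else {
          starts <- c(starts, iv$start[k])
          ends <- c(ends, iv$end[k])
        }
      }
    }
    data.frame(chrom = iv$chrom[1], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
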