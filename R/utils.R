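# Internal helpers shared across modules.

# Abort unless `x` is a single finite numeric inside [lo, hi].
check_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min))
  }
  invisible(as.integer(x))
}

# Validate a tibble of 1-based, inclusive-start / exclusive-end intervals
# against a backbone of length `L`. Intervals must be pairwise non-overlapping.
check_intervals <- function(iv, L, what) {
  if (is.null(iv) || nrow(iv) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  iv <- as_tibble(iv)
  if (!all(c("start", "end") %in% names(iv))) {
    abort(sprintf("%s intervals need `start` and `end` columns", what))
  }
  if (any(iv$start < 1 | iv$end > L + 1 | iv$start >= iv$end)) {
    abort(sprintf("%s intervals must satisfy 1 <= start < end <= L + 1", what))
  }
  iv <- arrange(iv, .data$start)
  if (nrow(iv) > 1L && any(iv$start[-1] < iv$end[-nrow(iv)])) {
    bad <- which(iv$start[-1] < iv$end[-nrow(iv)])[1]
    abort(sprintf(
      "%s intervals overlap: [%d,%d) and [%d,%d)", what,
      iv$start[bad], iv$end[bad], iv$start[bad + 1], iv$end[bad + 1]
    ))
  }
  iv
}

# Greedy run merger used by both depth segmentation and sweep detection.
# `member` is a logical vector; runs of TRUE may absorb up to `max_gap`
# FALSE interruptions in total. Runs with fewer than `min_members` TRUE
# entries are dropped. Returns a list of integer vectors of member indices.
merge_runs <- function(member, min_members, max_gap) {
  idx <- which(member)
  if (length(idx) == 0L) return(list())
  runs <- list()
  cur <- idx[1]
  gaps_used <- 0L
  if (length(idx) > 1L) {
    for (j in idx[-1]) {
      gap <- j - cur[length(cur)] - 1L
      if (gaps_used + gap <= max_gap) {
        gaps_used <- gaps_used + gap
        cur <- c(cur, j)
      } else {
        runs[[length(runs) + 1L]] <- cur
        cur <- j
        gaps_used <- 0L
      }
    }
  }
  runs[[length(runs) + 1L]] <- cur
  runs[lengths(runs) >= min_members]
}

# Reciprocal overlap of two 1-based inclusive-start/exclusive-end intervals.
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}
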