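#' Expected normalized depth under the copy-number model
#'
#' Under uniform coverage, a locus present in `copies_sample` copies in the
#' sequenced sample but assembled as `copies_reference` copies in the
#' reference receives `copies_sample / copies_reference` of the single-copy
#' normalized depth at each reference copy: a 2 -> 1 copy-number change gives
#' two paired reference regions each at 0.5, and 3 -> 2 gives three regions
#' near 0.67.
#'
#' @param copies_sample,copies_reference Non-negative copy counts;
#'   `copies_reference` must be positive.
#' @return Expected normalized depth (ratio).
#' @examples
#' cnv_expected_depth(1, 2) # 0.5
#' @export
cnv_expected_depth <- function(copies_sample, copies_reference) {
  if (any(copies_reference <= 0)) abort("`copies_reference` must be > 0")
  if (any(copies_sample < 0)) abort("`copies_sample` must be >= 0")
  copies_sample / copies_reference
}

#' Expected normalized depth of strain-private regions under the titer model
#'
#' In a double infection, regions present only in the strain making up a
#' fraction `titer` of all symbiont cells are covered at `titer` times the
#' depth of the shared backbone: at 70% titer, private regions sit at 0.7
#' normalized depth.
#'
#' @param titer Titer fraction in `[0, 1]` of the strain carrying the regions.
#' @return Expected normalized depth relative to the shared backbone.
#' @examples
#' private_expected_depth(0.7) # 0.7
#' @export
private_expected_depth <- function(titer) {
  if (any(titer < 0 | titer > 1)) abort("`titer` must be in [0, 1]")
  titer
}

#' Normalized depth in sliding windows
#'
#' Computes mean depth in sliding windows (default 1,000 bp stepped by
#' 500 bp) divided by the mean depth over the entire genome. Windows start at
#' 1, 1 + step, 1 + 2*step, ... and only full windows are emitted; trailing
#' bases contribute to the genome mean but form no window. A display cap
#' (default 5) is stored alongside the raw ratio.
#'
#' @param track Data frame with columns `pos` (1..L, complete) and `depth`,
#'   or a bare numeric depth vector.
#' @param window_size,step Window size and step in bp.
#' @param cap Cap applied to the stored `capped_norm_depth`.
#' @return A tibble of class `window_track` with columns `start`, `end`
#'   (inclusive), `raw_norm_depth`, `capped_norm_depth`, and attributes
#'   `window_size`, `step`, `cap`, `genome_mean_depth`, `genome_length`.
#' @examples
#' wt <- windowed_normalized_depth(rep(50, 10000))
#' nrow(wt) # 19 windows
#' @export
windowed_normalized_depth <- function(track, window_size = 1000L,
                                      step = 500L, cap = 5) {
  depth <- if (is.data.frame(track)) {
    if (!all(c("pos", "depth") %in% names(track))) {
      abort("`track` needs `pos` and `depth` columns")
    }
    if (is.unsorted(track$pos)) track <- arrange(track, .data$pos)
    if (!identical(as.integer(track$pos), seq_len(nrow(track)))) {
      abort("`track` must cover every base 1..L exactly once")
    }
    as.numeric(track$depth)
  } else {
    as.numeric(track)
  }
  L <- length(depth)
  window_size <- check_count(window_size, "window_size", 1)
  step <- check_count(step, "step", 1)
  if (L < window_size) abort("genome shorter than window")
  if (any(depth < 0)) abort("depth must be non-negative")
  genome_mean <- mean(depth)
  starts <- seq.int(1L, L - window_size + 1L, by = step)
  cs <- cumsum(c(0, depth))
  wmean <- (cs[starts + window_size] - cs[starts]) / window_size
  raw <- wmean / genome_mean
  out <- tibble(
    start = starts,
    end = starts + window_size - 1L,
    raw_norm_depth = raw,
    capped_norm_depth = pmin(raw, cap)
  )
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  attr(out, "cap") <- cap
  attr(out, "genome_mean_depth") <- genome_mean
  attr(out, "genome_length") <- L
  class(out) <- c("window_track", class(out))
  out
}

#' Segment depressed and elevated depth regions
#'
#' Finds maximal runs of consecutive windows whose capped normalized depth
#' falls in a low or high band, tolerating a limited number of out-of-band
#' interrupting windows per run, and merges each qualifying run into a region
#' call. Regions span the first member window's start to the last member
#' window's end; `mean_norm_depth` is the mean of the member windows' raw
#' (uncapped) values.
#'
#' @param wt A `window_track` from [windowed_normalized_depth()].
#' @param low_band,high_band Numeric length-2 open bands for depressed and
#'   elevated windows.
#' @param min_windows Minimum in-band member windows per region.
#' @param max_gap_windows Maximum out-of-band interruptions tolerated within
#'   one region.
#' @return A tibble of class `region_calls`: `start`, `end`, `mean_norm_depth`,
#'   `n_windows`, `direction` (`low`/`high`), `label` (`NA` until
#'   [classify_regions()]), `rationale`, and a `window_idx` list-column of
#'   member window indices.
#' @export
segment_regions <- function(wt, low_band = c(0.35, 0.90),
                            high_band = c(1.15, Inf),
                            min_windows = 10L, max_gap_windows = 2L) {
  stopifnot(inherits(wt, "window_track"))
  if (nrow(wt) == 0L) abort("empty window track")
  min_windows <- check_count(min_windows, "min_windows", 1)
  max_gap_windows <- check_count(max_gap_windows, "max_gap_windows", 0)
  d <- wt$capped_norm_depth
  bands <- list(low = low_band, high = high_band)
  out <- purrr::imap(bands, function(band, dir) {
    member <- d > band[1] & d < band[2]
    runs <- merge_runs(member, min_windows, max_gap_windows)
    if (length(runs) == 0L) return(NULL)
    tibble(
      start = map_dbl(runs, ~ wt$start[min(.x)]),
      end = map_dbl(runs, ~ wt$end[max(.x)]),
      mean_norm_depth = map_dbl(runs, ~ mean(wt$raw_norm_depth[.x])),
      n_windows = lengths(runs),
      direction = dir,
      label = NA_character_,
      rationale = NA_character_,
      window_idx = runs
    )
  }) |> bind_rows()
  if (nrow(out) == 0L) {
    out <- tibble(
      start = double(), end = double(), mean_norm_depth = double(),
      n_windows = integer(), direction = character(), label = character(),
      rationale = character(), window_idx = list()
    )
  }
  out <- arrange(out, .data$start)
  class(out) <- c("region_calls", class(out))
  attr(out, "window_track") <- wt
  out
}

#' Classify segmented regions as CNV or strain-private
#'
#' Applies ordered decision rules to low-depth regions: (a) a region whose
#' mean depth is within `tol` of a small-integer copy-ratio (1/2, 2/3, 3/4
#' for 2->1, 3->2, 4->3 losses) is labelled `cnv_loss` only if the number of
#' regions sharing that depth level is a positive multiple of the `k` paired
#' reference copies each loss event leaves behind (a 2->1 loss depresses 2
#' paired regions, 3->2 depresses 3); (b) otherwise, regions sharing a common depth
#' level inside the low band are labelled `strain_private` (the level
#' estimates the carrying strain's titer), strengthened when independent
#' duplicated single-copy gene evidence is supplied; (c) anything else is
#' `ambiguous`. High regions are labelled `cnv_gain`. The rationale string
#' records which clause fired.
#'
#' @param regions A `region_calls` tibble from [segment_regions()].
#' @param duplication_evidence Count of duplicated single-copy genes found in
#'   the mixed assembly (e.g. by a completeness screen); `> 0` corroborates
#'   the two-strain interpretation.
#' @param tol Depth tolerance for ratio matching and level sharing.
#' @param low_band Band within which strain-private levels are credible.
#' @return The input tibble with `label` and `rationale` filled in.
#' @export
classify_regions <- function(regions, duplication_evidence = 0L, tol = 0.06,
                             low_band = c(0.35, 0.90)) {
  stopifnot(inherits(regions, "region_calls"))
  if (tol <= 0) abort("`tol` must be > 0")
  if (nrow(regions) == 0L) return(regions)
  ratios <- c(2L, 3L, 4L)
  names(ratios) <- c("1/2", "2/3", "3/4")
  low <- which(regions$direction == "low")
  d <- regions$mean_norm_depth
  for (i in which(regions$direction == "high")) {
    regions$label[i] <- "cnv_gain"
    regions$rationale[i] <- "elevated depth; gain or repeat collapse in reference"
  }
  for (i in low) {
    partners <- sum(abs(d[low] - d[i]) <= tol)
    dev <- abs(d[i] - (ratios - 1) / ratios)
    k <- ratios[which.min(dev)]
    if (min(dev) <= tol && partners >= k && partners %% k == 0L) {
      regions$label[i] <- "cnv_loss"
      regions$rationale[i] <- sprintf(
        "depth %.2f within %.2f of %d->%d ratio %.2f with %d regions at this level (needs a multiple of %d)",
        d[i], tol, k, k - 1L, (k - 1) / k, partners, k
      )
    } else if (d[i] > low_band[1] && d[i] < low_band[2]) {
      extra <- if (min(dev) <= tol) {
        sprintf(
          "; %d->%d loss rejected (%d region(s) at this level, needs a multiple of %d)",
          k, k - 1L, partners, k
        )
      } else ""
      dup <- if (duplication_evidence > 0) {
        sprintf("; corroborated by %d duplicated single-copy genes",
                as.integer(duplication_evidence))
      } else ""
      regions$label[i] <- "strain_private"
      regions$rationale[i] <- sprintf(
        "%d region(s) share depth level %.2f consistent with a strain titer fraction%s%s",
        partners, d[i], extra, dup
      )
    } else {
      regions$label[i] <- "ambiguous"
      regions$rationale[i] <- sprintf(
        "depth %.2f matches neither a supported copy-ratio nor the private band",
        d[i]
      )
    }
  }
  regions
}

#' Estimate the relative titer of the strain carrying private regions
#'
#' The normalized depth of strain-private regions estimates the titer
#' fraction of the strain that carries them. Because the private regions
#' themselves depress the genome-wide mean, the estimator divides the mean
#' raw normalized depth over private member windows by the mean over
#' background windows (windows belonging to no segmented region), i.e. the
#' private regions' depth relative to the rest of the genome. A percentile
#' bootstrap over windows gives the confidence interval. `1 - f_hat` is the
#' co-infecting strain's fraction.
#'
#' @param regions A labelled `region_calls` tibble ([classify_regions()]).
#' @param wt The `window_track` the regions were segmented from (defaults to
#'   the one attached to `regions`).
#' @param n_boot Bootstrap replicates.
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `titer_estimate`: list with `f_hat`, `ci_low`,
#'   `ci_high`, `n_windows_used`, `n_boot`, `conf`.
#' @export
estimate_titer <- function(regions, wt = attr(regions, "window_track"),
                           n_boot = 1000L, conf = 0.95, seed = 42L) {
  stopifnot(inherits(regions, "region_calls"))
  if (is.null(wt)) abort("supply the window track the regions came from")
  priv <- regions[!is.na(regions$label) & regions$label == "strain_private", ]
  if (nrow(priv) == 0L) abort("nothing to estimate: no strain_private regions")
  member <- sort(unique(unlist(priv$window_idx)))
  in_any_region <- sort(unique(unlist(regions$window_idx)))
  background <- setdiff(seq_len(nrow(wt)), in_any_region)
  if (length(background) == 0L) abort("no background windows left")
  dp <- wt$raw_norm_depth[member]
  db <- wt$raw_norm_depth[background]
  f_hat <- mean(dp) / mean(db)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(dp, replace = TRUE)) / mean(sample(db, replace = TRUE))
  }, double(1))
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  structure(
    list(
      f_hat = min(max(f_hat, 0), 1),
      ci_low = min(max(qs[1], 0), 1),
      ci_high = min(max(qs[2], 0), 1),
      n_windows_used = length(member),
      n_boot = as.integer(n_boot),
      conf = conf
    ),
    class = "titer_estimate"
  )
}

#' @export
print.titer_estimate <- function(x, ...) {
  cat(sprintf(
    "Strain titer estimate: f_hat = %.3f (%.0f%% CI %.3f-%.3f) from %d windows\n",
    x$f_hat, 100 * x$conf, x$ci_low, x$ci_high, x$n_windows_used
  ))
  cat(sprintf("Co-infecting strain fraction: %.3f\n", 1 - x$f_hat))
  invisible(x)
}
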