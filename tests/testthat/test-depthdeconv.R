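test_that("copy-number and titer depth closed forms", {
  expect_equal(cnv_expected_depth(1, 2), 0.5)
  expect_equal(cnv_expected_depth(2, 3), 2 / 3)
  expect_equal(private_expected_depth(0.7), 0.7)
  expect_error(cnv_expected_depth(1, 0), "copies_reference")
  expect_error(private_expected_depth(1.3), "titer")
})

test_that("uniform coverage gives unit normalized depth in every full window", {
  wt <- windowed_normalized_depth(rep(50, 10000))
  expect_equal(nrow(wt), 19L)
  expect_true(all(wt$raw_norm_depth == 1))
  expect_equal(wt$start, seq(1, 9001, by = 500))
  expect_equal(wt$end[1], 1000)
})

test_that("two-level track matches direct arithmetic", {
  depth <- c(rep(10, 5000), rep(30, 5000))
  wt <- windowed_normalized_depth(depth)
  expect_equal(attr(wt, "genome_mean_depth"), 20)
  first_half <- wt$end <= 5000
  second_half <- wt$start >= 5001
  expect_true(all(abs(wt$raw_norm_depth[first_half] - 0.5) < 1e-12))
  expect_true(all(abs(wt$raw_norm_depth[second_half] - 1.5) < 1e-12))
})

test_that("capping stores the display value without touching the raw ratio", {
  depth <- rep(10, 20000)
  depth[10001:11000] <- 200 # one window region far above the cap
  wt <- windowed_normalized_depth(depth, cap = 5)
  expect_gt(max(wt$raw_norm_depth), 5)
  expect_equal(max(wt$capped_norm_depth), 5)
})

test_that("window computation agrees with a naive loop to 1e-12", {
  set.seed(77)
  depth <- rpois(50000, 40)
  wt <- windowed_normalized_depth(depth)
  gm <- mean(depth)
  naive <- vapply(wt$start, function(s) {
    mean(depth[s:(s + 999)]) / gm
  }, double(1))
  expect_lt(max(abs(wt$raw_norm_depth - naive)), 1e-12)
})

test_that("tracks shorter than a window are rejected", {
  expect_error(windowed_normalized_depth(rep(5, 500)), "shorter than window")
})

test_that("segmentation finds constructed runs and ignores flat tracks", {
  flat <- fake_window_track(rep(1, 200))
  expect_equal(nrow(segment_regions(flat)), 0L)

  raw <- c(rep(1, 30), rep(0.7, 140), rep(1, 30))
  wt <- fake_window_track(raw)
  rg <- segment_regions(wt)
  expect_equal(nrow(rg), 1L)
  expect_equal(rg$n_windows, 140L)
  expect_equal(rg$direction, "low")
  expect_equal(rg$mean_norm_depth, 0.7)
  expect_equal(rg$start, wt$start[31])
  expect_equal(rg$end, wt$end[170])
})

test_that("short runs and isolated noisy windows are not called", {
  raw <- rep(1, 100)
  raw[c(10, 40, 41, 42, 80)] <- 0.6 # longest run is 3 < min_windows
  expect_equal(nrow(segment_regions(fake_window_track(raw))), 0L)
})

test_that("runs absorb at most the allowed interruptions", {
  raw <- rep(1, 100)
  raw[20:60] <- 0.7
  raw[c(30, 45)] <- 1.0 # two interruptions: still one region
  rg <- segment_regions(fake_window_track(raw))
  expect_equal(nrow(rg), 1L)
  expect_equal(rg$n_windows, 39L)
})

test_that("classification follows the ordered copy-ratio and private-level rules", {
  wt <- fake_window_track(rep(1, 50))
  mk_regions <- function(depths) {
    rg <- tibble::tibble(
      start = seq_along(depths) * 10000, end = seq_along(depths) * 10000 + 5000,
      mean_norm_depth = depths, n_windows = 20L, direction = "low",
      label = NA_character_, rationale = NA_character_,
      window_idx = lapply(seq_along(depths), function(i) integer())
    )
    class(rg) <- c("region_calls", class(rg))
    attr(rg, "window_track") <- wt
    rg
  }
  # paired 0.5 regions: a 2->1 copy loss
  two_half <- classify_regions(mk_regions(c(0.50, 0.50)))
  expect_equal(two_half$label, c("cnv_loss", "cnv_loss"))

  # two regions near 0.7: a 3->2 loss would need three, so strain-private
  fig <- classify_regions(mk_regions(c(0.70, 0.69)), duplication_evidence = 17)
  expect_equal(fig$label, c("strain_private", "strain_private"))
  expect_match(fig$rationale[1], "duplicated single-copy genes")

  # single 0.66 region: 3->2 rejected for missing partners
  lone <- classify_regions(mk_regions(0.66))
  expect_equal(lone$label, "strain_private")
  expect_match(lone$rationale, "rejected")

  # below the credible private band
  deep <- classify_regions(mk_regions(0.2))
  expect_equal(deep$label, "ambiguous")

  expect_error(classify_regions(mk_regions(0.5), tol = 0), "tol")
})

test_that("degenerate titer bootstrap collapses to a point", {
  raw <- c(rep(1, 40), rep(0.7, 20), rep(1, 40))
  wt <- fake_window_track(raw)
  rg <- classify_regions(segment_regions(wt))
  expect_equal(rg$label, "strain_private")
  ti <- estimate_titer(rg, wt, n_boot = 200, seed = 1)
  expect_equal(ti$f_hat, 0.7)
  expect_equal(ti$ci_low, 0.7)
  expect_equal(ti$ci_high, 0.7)
  expect_equal(ti$n_windows_used, 20L)
})

test_that("estimate_titer refuses when nothing is labelled strain-private", {
  wt <- fake_window_track(rep(1, 60))
  rg <- segment_regions(wt)
  expect_error(estimate_titer(rg, wt), "nothing to estimate")
})

test_that("titer recovery is accurate at 0.5 and monotone in the true titer", {
  # five private regions: no k -> k-1 copy-number loss can explain five
  # same-level regions (5 is no multiple of 2, 3 or 4), so classification
  # resolves to strain-private at every titer in the band
  f_hat_at <- function(titer, seed) {
    starts <- c(50001, 150001, 250001, 350001, 450001)
    pair <- make_strain_pair(
      strain_pair_spec(
        backbone_length = 6e5,
        private_regions_a = data.frame(start = starts, end = starts + 24000),
        titer_a = titer, seed = seed
      ),
      sequences = FALSE
    )
    dt <- simulate_mixture_depth(pair, cov = coverage_sim_spec(50, seed = seed))
    wt <- windowed_normalized_depth(dt)
    rg <- classify_regions(segment_regions(wt))
    estimate_titer(rg, wt, n_boot = 200, seed = seed)$f_hat
  }
  f5 <- f_hat_at(0.5, 101)
  expect_lt(abs(f5 - 0.5), 0.02)
  fs <- vapply(c(0.4, 0.6, 0.8), f_hat_at, double(1), seed = 102)
  expect_true(all(diff(c(fs)) > 0))
})

test_that("a single-strain track yields no strain-private calls", {
  hits <- vapply(1:10, function(s) {
    pair <- make_strain_pair(
      strain_pair_spec(
        backbone_length = 1e5,
        private_regions_a = data.frame(start = 40001, end = 60001),
        titer_a = 1.0, seed = s
      ),
      sequences = FALSE
    )
    dt <- simulate_mixture_depth(pair, titer_a = 1,
                                 cov = coverage_sim_spec(50, seed = s))
    rg <- classify_regions(segment_regions(windowed_normalized_depth(dt)))
    sum(!is.na(rg$label) & rg$label == "strain_private")
  }, double(1))
  expect_gte(mean(hits == 0), 0.95)
})
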