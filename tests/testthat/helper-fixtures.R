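# Shared fixture builders; everything is generated in code.

# The two-strain layout matching the published coverage figure, scaled to a
# 1 Mb backbone: private regions at 600-700 kb and 900-950 kb.
fig_style_pair <- function(titer_a = 0.7, seed = 42L) {
  make_strain_pair(
    strain_pair_spec(
      backbone_length = 1e6,
      private_regions_a = data.frame(start = c(600001, 900001),
                                     end = c(700001, 950001)),
      titer_a = titer_a, seed = seed
    ),
    sequences = FALSE
  )
}

# Hand-built window track (bypasses depth simulation) for segmentation and
# titer unit tests.
fake_window_track <- function(raw, window_size = 1000L, step = 500L,
                              cap = 5) {
  starts <- 1L + step * (seq_along(raw) - 1L)
  out <- tibble::tibble(
    start = starts,
    end = starts + window_size - 1L,
    raw_norm_depth = raw,
    capped_norm_depth = pmin(raw, cap)
  )
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  attr(out, "cap") <- cap
  attr(out, "genome_mean_depth") <- 1
  attr(out, "genome_length") <- max(out$end)
  class(out) <- c("window_track", class(out))
  out
}

# Small genotype matrix from an explicit genotype matrix (samples x sites).
toy_genotype_matrix <- function(geno, contig = "c1", phenotype = NULL) {
  n_sites <- ncol(geno)
  sites <- tibble::tibble(
    contig = if (length(contig) == 1L) rep(contig, n_sites) else contig,
    pos = seq_len(n_sites) * 100L,
    ref = "A", alt = "T"
  )
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(nrow(geno))),
    line = "toy",
    phenotype = phenotype %||% rep("MK", nrow(geno))
  )
  genotype_matrix(geno, sites, samples)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
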