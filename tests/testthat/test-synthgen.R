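test_that("strain pair with no private or CNV regions gives identical genomes", {
  sp <- strain_pair_spec(backbone_length = 5000)
  pair <- make_strain_pair(sp)
  expect_identical(pair$genome_a, pair$genome_b)
  expect_equal(nrow(pair$truth), 0L)
})

test_that("private regions shorten strain B and are recorded in the truth table", {
  pair <- make_strain_pair(
    strain_pair_spec(
      backbone_length = 1e6,
      private_regions_a = data.frame(start = c(600001, 900001),
                                     end = c(700001, 950001)),
      titer_a = 0.7
    )
  )
  expect_equal(nchar(pair$genome_a), 1e6)
  expect_equal(nchar(pair$genome_b), 850000)
  expect_equal(nrow(pair$truth), 2L)
  expect_true(all(pair$truth$class == "a_private"))
})

test_that("CNV truth rows carry the pure copy-number depth ratio", {
  pair <- make_strain_pair(
    strain_pair_spec(
      backbone_length = 1e4,
      cnv_regions = data.frame(start = 2001, end = 3001,
                               copies_a = 2L, copies_b = 1L)
    ),
    sequences = FALSE
  )
  expect_equal(pair$truth$class, "cnv")
  expect_equal(pair$truth$depth_ratio_cnv, 0.5)
})

test_that("overlapping intervals are rejected with an informative error", {
  expect_error(
    strain_pair_spec(
      backbone_length = 1e4,
      private_regions_a = data.frame(start = c(1000, 1500),
                                     end = c(2000, 2500))
    ),
    "overlap"
  )
  expect_error(strain_pair_spec(1e4, titer_a = 1.2), "titer_a")
})

test_that("mixture depth has the titer-weighted means and is seed-reproducible", {
  pair <- make_strain_pair(
    strain_pair_spec(
      backbone_length = 60000,
      private_regions_a = data.frame(start = 20001, end = 40001),
      titer_a = 0.7
    ),
    sequences = FALSE
  )
  cov <- coverage_sim_spec(mean_depth = 50, seed = 11)
  dt <- simulate_mixture_depth(pair, cov = cov)
  dt2 <- simulate_mixture_depth(pair, cov = cov)
  expect_identical(dt$depth, dt2$depth)

  priv <- dt$depth[20001:40000]
  shared <- dt$depth[c(1:20000, 40001:60000)]
  # Poisson closed form: sample mean within 3 standard errors
  expect_lt(abs(mean(priv) - 35), 3 * sqrt(35 / length(priv)))
  expect_lt(abs(mean(shared) - 50), 3 * sqrt(50 / length(shared)))

  # single infection: private regions indistinguishable from backbone
  dt1 <- simulate_mixture_depth(pair, titer_a = 1, cov = cov)
  expect_lt(abs(mean(dt1$depth[20001:40000]) - 50), 3 * sqrt(50 / 20000))

  # second truth value
  dt5 <- simulate_mixture_depth(pair, titer_a = 0.5,
                                cov = coverage_sim_spec(50, seed = 12))
  expect_lt(abs(mean(dt5$depth[20001:30000]) - 25), 3 * sqrt(25 / 10000))
})

test_that("genome-wide mean of normalized depth is 1 by construction", {
  pair <- fig_style_pair(seed = 3)
  dt <- simulate_mixture_depth(pair, cov = coverage_sim_spec(50, seed = 3))
  wt <- windowed_normalized_depth(dt)
  expect_lt(abs(mean(dt$depth) / attr(wt, "genome_mean_depth") - 1), 1e-12)
  expect_lt(abs(mean(wt$raw_norm_depth) - 1), 0.01)
})

test_that("zero recombination with one backcross leaves whole contigs donor or recurrent", {
  gm <- simulate_backcross_genotypes(backcross_sim_spec(
    n_contigs = 2, sites_per_contig = 50, recomb_rate = 0,
    n_lines_mk = 5, n_lines_mks = 5, n_backcrosses = 1,
    missing_rate = 0, seed = 5
  ))
  for (ct in unique(gm$sites$contig)) {
    sub <- gm$geno[, gm$sites$contig == ct, drop = FALSE]
    per_line <- apply(sub, 1, function(x) length(unique(x)))
    expect_true(all(per_line == 1L))
  }
})

test_that("phenotype groups are defined by the suppressor genotype at the truth locus", {
  gm <- simulate_backcross_genotypes(backcross_sim_spec(
    sites_per_contig = 120, n_lines_mk = 10, n_lines_mks = 10,
    missing_rate = 0, seed = 9
  ))
  tr <- attr(gm, "truth")
  expect_equal(sum(gm$samples$phenotype == "MK"), 10L)
  expect_equal(sum(gm$samples$phenotype == "MKS"), 10L)
  # nearest genotyped site to the suppressor should be heterozygous in most
  # MKS lines and recurrent-homozygous in most MK lines (tight linkage)
  on_ct <- which(gm$sites$contig == tr$contig)
  near <- on_ct[which.min(abs(gm$sites$pos[on_ct] - tr$pos))]
  mks <- gm$geno[gm$samples$phenotype == "MKS", near]
  mk <- gm$geno[gm$samples$phenotype == "MK", near]
  expect_gte(mean(mks == 1L), 0.8)
  expect_gte(mean(mk == 0L), 0.8)
})

test_that("donor allele frequency at unlinked sites matches the pedigree expectation", {
  # gametes of BC2 mothers carry donor ancestry with probability (1/2)^3;
  # sampled BC2 individuals are heterozygous with probability (1/2)^2, i.e.
  # allele frequency 0.125
  gm <- simulate_backcross_genotypes(backcross_sim_spec(
    sites_per_contig = 200, n_lines_mk = 30, n_lines_mks = 30,
    n_backcrosses = 2, missing_rate = 0, seed = 21
  ))
  bg <- gm$sites$contig != attr(gm, "truth")$contig
  # sites within a line are linked, but line means are independent: compare
  # the mean per-line donor ancestry against (1/2)^2 on the line-mean scale
  line_anc <- rowMeans(gm$geno[, bg])
  se <- sd(line_anc) / sqrt(length(line_anc))
  expect_lt(abs(mean(line_anc) - 0.25), 3 * se)
  # and the allele frequency is half the ancestry fraction
  expect_lt(abs(mean(gm$geno[, bg]) / 2 - 0.125), 3 * se / 2)
})

test_that("requesting no lines errors", {
  expect_error(
    simulate_backcross_genotypes(backcross_sim_spec(n_lines_mk = 0,
                                                    n_lines_mks = 0)),
    "at least one line"
  )
})
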