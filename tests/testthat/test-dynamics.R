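test_that("model parameters are validated", {
  expect_error(model_params(tau_mk = 1.2), "tau_mk")
  expect_error(model_params(mu = 0.8, leak = 0.3), "mu \\+ leak")
  expect_error(individual("female", cytotype = "XX"), "cytotype")
})

test_that("an incompatible cross hatches at h_ci and a null cross at baseline", {
  p <- model_params()
  ci_cross <- expected_cross_outcome(
    individual("female", "ss"), individual("male", "ss", "CI"), p
  )
  expect_equal(ci_cross$expected_hatch, 0.0617)

  null_cross <- expected_cross_outcome(
    individual("female", "ss"), individual("male", "ss"), p
  )
  expect_equal(null_cross$expected_hatch, p$h_0)
  expect_equal(null_cross$expected_prop_female, 0.5)
  expect_equal(null_cross$expected_egg_to_adult, p$v_0)

  # an MK-line female carries the CI strain, so CI males are compatible
  mk_mother <- expected_cross_outcome(
    individual("female", "ss", c("CI", "MK")),
    individual("male", "ss", "CI"), p
  )
  expect_equal(mk_mother$expected_hatch, p$h_0)

  expect_error(
    expected_cross_outcome(individual("male"), individual("male"), p),
    "female"
  )
})

test_that("full male killing halves viability and leaves only daughters", {
  p <- model_params(tau_mk = 1, mu = 1, leak = 0, v_0 = 0.8)
  out <- expected_cross_outcome(
    individual("female", "ss", c("CI", "MK")),
    individual("male", "ss", "CI"), p
  )
  expect_equal(out$expected_prop_female, 1)
  expect_equal(out$expected_egg_to_adult, 0.40)
})

test_that("offspring distributions are proper and viability follows its closed form", {
  set.seed(14)
  for (i in 1:20) {
    p <- model_params(
      tau_ci = runif(1), tau_mk = runif(1), h_ci = runif(1, 0, 0.5),
      h_0 = runif(1, 0.5, 1), v_0 = runif(1, 0.3, 1),
      mu = runif(1, 0, 0.7), leak = runif(1, 0, 0.3)
    )
    mother <- individual("female", sample(c("ss", "Ss", "SS"), 1),
                         c("CI", "MK"))
    father <- individual("male", sample(c("ss", "Ss", "SS"), 1),
                         if (runif(1) < 0.5) "CI" else character())
    out <- expected_cross_outcome(mother, father, p)
    expect_equal(sum(out$offspring$p_birth), 1, tolerance = 1e-12)
    expect_equal(sum(out$offspring$p_adult), 1, tolerance = 1e-12)
    expect_true(out$expected_prop_female >= 0 &&
                  out$expected_prop_female <= 1)
    # MK-mother x ss father with ss mother: exact viability identity
    if (mother$nuclear == "ss" && father$nuclear == "ss" &&
        out$expected_hatch == p$h_0) {
      expect_equal(out$expected_egg_to_adult,
                   p$v_0 * (1 - (1 - p$leak) * p$mu / 2),
                   tolerance = 1e-12)
    }
  }
})

test_that("incompatible crosses never out-hatch compatible ones", {
  set.seed(3)
  for (i in 1:10) {
    p <- model_params(h_ci = runif(1, 0, 0.3), h_0 = runif(1, 0.5, 1))
    inc <- expected_cross_outcome(
      individual("female", "ss"), individual("male", "ss", "CI"), p
    )
    comp <- expected_cross_outcome(
      individual("female", "ss", "CI"), individual("male", "ss", "CI"), p
    )
    expect_lte(inc$expected_hatch, comp$expected_hatch)
  }
})

test_that("with complete transmission and killing, adult sons of MK mothers carry S", {
  p <- model_params(tau_mk = 1, mu = 1, leak = 0)
  for (mn in c("ss", "Ss", "SS")) {
    for (fn in c("ss", "Ss", "SS")) {
      out <- expected_cross_outcome(
        individual("female", mn, c("CI", "MK")),
        individual("male", fn, "CI"), p
      )
      males_alive <- out$offspring[out$offspring$sex == "male" &
                                     out$offspring$p_adult > 0, ]
      expect_true(all(males_alive$nuclear %in% c("Ss", "SS")))
    }
  }
})

test_that("line phenotype classification applies the exclusion rules", {
  expect_equal(
    classify_line_phenotype(c(30, 12, 18, 40), c(0, 2, 14, 5)),
    c("MK", "excluded", "MKS", "excluded")
  )
  # 40F/5M: 88.9% female exceeds the 70% ambiguity bound -> excluded
  expect_equal(classify_line_phenotype(14, 0), "excluded") # under min_total
  expect_error(classify_line_phenotype(-1, 5), ">= 0")
})

test_that("the backcross panel reproduces the segregation structure", {
  pan <- simulate_backcross_panel(n_lines = 29, generations = 3, seed = 42)
  expect_equal(pan$percent_mk[pan$generation == "F1"], 0)
  expect_equal(pan$expected_percent_mk[pan$generation == "F1"], 0)
  # Mendelian expectation from backcross 2 on: half the mothers are ss
  bc2_expected <- pan$expected_percent_mk[pan$generation == "BC2"]
  expect_equal(bc2_expected, 100 * 0.5 * (71 / 73)^2, tolerance = 1e-12)
  band <- 100 * qbinom(c(0.025, 0.975), 29, 0.5) / 29
  bc2 <- pan$percent_mk[pan$generation == "BC2"]
  expect_gte(bc2, band[1])
  expect_lte(bc2, band[2])
})

test_that("a recurrent-line control panel never reverts to male killing", {
  pan <- simulate_backcross_panel(
    n_lines = 10, generations = 3,
    donor = individual("female", "ss", character()), seed = 7
  )
  expect_true(all(pan$percent_mk == 0))
})

test_that("S allele frequency is non-decreasing under MK mortality", {
  # deterministic one-generation recursion over a random-mating population of
  # MK-carrying mothers, using the cross calculator as the oracle
  next_s_freq <- function(q, p) {
    geno_freq <- c(SS = q^2, Ss = 2 * q * (1 - q), ss = (1 - q)^2)
    alleles <- c(SS = 2, Ss = 1, ss = 0)
    num <- 0
    den <- 0
    for (mn in names(geno_freq)) {
      for (fn in names(geno_freq)) {
        w <- geno_freq[[mn]] * geno_freq[[fn]]
        out <- expected_cross_outcome(
          individual("female", mn, c("CI", "MK")),
          individual("male", fn, "CI"), p
        )
        surv <- out$offspring$p_birth * out$offspring$p_survive
        num <- num + w * sum(surv * alleles[out$offspring$nuclear] / 2)
        den <- den + w * sum(surv)
      }
    }
    num / den
  }
  for (mu in c(0.3, 1)) {
    p <- model_params(mu = mu)
    for (q in seq(0.1, 0.9, by = 0.2)) {
      expect_gte(next_s_freq(q, p) + 1e-12, q)
    }
  }
  # and exactly stable when MK is inert
  p0 <- model_params(mu = 0)
  expect_equal(next_s_freq(0.3, p0), 0.3, tolerance = 1e-12)
})

test_that("neutral parameters give unbiased 50:50 vial sex ratios", {
  p <- model_params(mu = 0, h_ci = 0.76, h_0 = 0.76)
  v <- simulate_mixed_population(0.9, generations = 3, n_replicates = 30,
                                 p = p, seed = 8)
  expect_lt(abs(mean(v$percent_female) - 50), 2)
  # per-generation means also stay near 50
  bygen <- tapply(v$percent_female, v$generation, mean)
  expect_true(all(abs(bygen - 50) < 3))
})

test_that("G statistic matches an independent log-linear oracle", {
  tab <- rbind(c(10, 90), c(20, 80))
  ours <- g_test(tab)
  oracle <- MASS::loglm(~ rows + cols, data = as.table(structure(
    tab, dimnames = list(rows = c("a", "b"), cols = c("x", "y"))
  )))
  expect_equal(unname(ours$statistic),
               unname(oracle$lrt), tolerance = 1e-8)
  expect_equal(unname(ours$parameter), 1)

  # equal proportions in every row -> G = 0
  expect_equal(unname(g_test(rbind(c(5, 45), c(20, 180)))$statistic), 0,
               tolerance = 1e-12)
  expect_error(g_test(rbind(c(0, 5), c(0, 7))), "all zeros")
})

test_that("field incidence counts give the published-style G and df", {
  # six collection-site categories
  tab <- cbind(c(1, 0, 3, 0, 3, 0), c(33, 3, 71, 10, 41, 23))
  res <- g_test(tab)
  expect_equal(unname(res$parameter), 5)
  oracle <- MASS::loglm(~ rows + cols, data = as.table(structure(
    tab, dimnames = list(rows = paste0("s", 1:6), cols = c("y", "n"))
  )))
  expect_equal(unname(res$statistic), unname(oracle$lrt), tolerance = 1e-8)
})

test_that("sex-ratio chi-square follows its closed form", {
  expect_equal(unname(sex_ratio_chisq(50, 50)$statistic), 0)
  r <- sex_ratio_chisq(90, 10)
  expect_equal(unname(r$statistic), 64)
  expect_lt(r$p.value, 0.001)
  expect_equal(unname(sex_ratio_chisq(143, 0)$statistic), 143)
  expect_error(sex_ratio_chisq(0, 0), "at least one")
})

test_that("relative density doubles per cycle difference and flags noisy runs", {
  expect_equal(relative_density(c(25, 25), c(25, 25))$density, 1)
  expect_equal(relative_density(20, 23.3219)$density, 10, tolerance = 1e-3)
  noisy <- relative_density(c(20.0, 25.5), c(21, 21.2))
  expect_true(noisy$qc_flag)
  expect_equal(noisy$sd_target, sd(c(20, 25.5)))
  clean <- relative_density(c(21.0, 21.4), c(20.0, 20.2))
  expect_false(clean$qc_flag)
  expect_error(relative_density(numeric(), 20), "replicate")
})
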