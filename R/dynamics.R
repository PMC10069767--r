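#' Inheritance-model parameters for the CI + MK double infection
#'
#' Parameters of the generative model of cytoplasmic incompatibility (CI),
#' late-acting male killing (MK), imperfect maternal transmission and a
#' dominant nuclear suppressor `S`:
#' \describe{
#'   \item{tau_ci, tau_mk}{Maternal transmission probabilities of the CI and
#'     MK strains (paternal transmission is zero for both). The MK default
#'     71/73 reflects occasional transmission failure.}
#'   \item{h_ci}{Egg-hatch proportion of an incompatible cross (CI-carrying
#'     male x female lacking the CI strain); default 0.0617.}
#'   \item{h_0}{Baseline egg-hatch proportion of compatible crosses.}
#'   \item{v_0}{Baseline egg-to-adult viability (hatch included).}
#'   \item{mu}{Probability that an unsuppressed (`ss`) son of an MK-carrying
#'     mother dies at the larval stage. MK acts late: it reduces egg-to-adult
#'     viability, not hatch.}
#'   \item{leak}{Probability the MK effect fails to act on a susceptible son
#'     (partial-expression lines); effective larval death is `mu * (1 - leak)`.}
#'   \item{penetrance}{Penetrance of dominant suppression in `Ss`/`SS` sons
#'     (1 = fully protective).}
#'   \item{male_ci_loss}{Probability a CI-carrying male fails to induce CI
#'     (hook for titer loss in males; default 0 — CI stays strong).}
#'   \item{sex_ratio_0}{Primary sex ratio (proportion female at egg).}
#' }
#'
#' @param tau_ci,tau_mk,h_ci,h_0,v_0,mu,leak,penetrance,male_ci_loss,sex_ratio_0
#'   See description.
#' @return A `model_params` list.
#' @export
model_params <- function(tau_ci = 1.0, tau_mk = 71 / 73, h_ci = 0.0617,
                         h_0 = 0.76, v_0 = 0.7, mu = 1.0, leak = 0,
                         penetrance = 1.0, male_ci_loss = 0,
                         sex_ratio_0 = 0.5) {
  p <- list(
    tau_ci = tau_ci, tau_mk = tau_mk, h_ci = h_ci, h_0 = h_0, v_0 = v_0,
    mu = mu, leak = leak, penetrance = penetrance,
    male_ci_loss = male_ci_loss, sex_ratio_0 = sex_ratio_0
  )
  for (nm in names(p)) check_prob(p[[nm]], nm)
  if (mu + leak > 1) abort("`mu + leak` must be <= 1")
  structure(p, class = "model_params")
}

#' Construct an individual genotype
#'
#' @param sex `"female"` or `"male"`.
#' @param nuclear Suppressor genotype: `"ss"`, `"Ss"` or `"SS"`.
#' @param cytotype Character vector of strains carried, a subset of
#'   `c("CI", "MK")`. Both strains are strictly maternally acquired.
#' @return An `individual` list.
#' @export
individual <- function(sex = c("female", "male"),
                       nuclear = c("ss", "Ss", "SS"),
                       cytotype = character()) {
  sex <- match.arg(sex)
  nuclear <- match.arg(nuclear)
  if (!all(cytotype %in% c("CI", "MK"))) {
    abort("cytotype must be a subset of c('CI', 'MK')")
  }
  structure(list(sex = sex, nuclear = nuclear, cytotype = unique(cytotype)),
            class = "individual")
}

n_s_alleles <- function(nuclear) c(ss = 0L, Ss = 1L, SS = 2L)[[nuclear]]

mendelian_nuclear <- function(mother, father) {
  pm <- n_s_alleles(mother) / 2
  pf <- n_s_alleles(father) / 2
  c(
    SS = pm * pf,
    Ss = pm * (1 - pf) + (1 - pm) * pf,
    ss = (1 - pm) * (1 - pf)
  )
}

# Expected hatch of a cross given parental cytotypes.
expected_hatch <- function(mother_ci, father_ci, p) {
  if (father_ci && !mother_ci) {
    p$male_ci_loss * p$h_0 + (1 - p$male_ci_loss) * p$h_ci
  } else {
    p$h_0
  }
}

# Larval death probability of one offspring class. MK lethality acts through
# the mother's infection (maternally loaded, larval-stage): an unsuppressed
# son of an MK-carrying mother dies with probability mu * (1 - leak);
# suppressor carriers are protected with probability `penetrance`; daughters
# are unaffected.
mk_death_prob <- function(sex, nuclear, mother_mk, p) {
  if (!mother_mk || sex == "female") return(0)
  protect <- if (nuclear == "ss") 0 else p$penetrance
  p$mu * (1 - p$leak) * (1 - protect)
}

#' Deterministic expectations for a single cross
#'
#' Computes the expected hatch proportion, egg-to-adult viability, proportion
#' of females among emerging adults, and the full offspring genotype
#' distribution for one mother x father cross under [model_params()].
#' Offspring cytotype is sampled per strain from the mother only
#' (`tau_ci`/`tau_mk`); nuclear genotype segregates Mendelianly; CI applies
#' only when the father carries the CI strain and the mother does not (an
#' MK-line female carries CI, so she is fully compatible with CI males);
#' MK removes unsuppressed sons at the larval stage.
#'
#' @param mother,father [individual()]s (female and male respectively).
#' @param p A [model_params()].
#' @return An object of class `cross_outcome`: list with `expected_hatch`,
#'   `expected_egg_to_adult`, `expected_prop_female` and `offspring`, a
#'   tibble of genotype classes with birth probabilities (`p_birth`, sums to
#'   1), survival (`p_survive`) and adult composition (`p_adult`).
#' @examples
#' p <- model_params()
#' out <- expected_cross_outcome(
#'   mother = individual("female", "ss", character()),
#'   father = individual("male", "ss", "CI"), p
#' )
#' out$expected_hatch # 0.0617
#' @export
expected_cross_outcome <- function(mother, father, p = model_params()) {
  stopifnot(inherits(mother, "individual"), inherits(father, "individual"))
  if (mother$sex != "female" || father$sex != "male") {
    abort("`mother` must be female and `father` male")
  }
  mother_ci <- "CI" %in% mother$cytotype
  mother_mk <- "MK" %in% mother$cytotype
  father_ci <- "CI" %in% father$cytotype
  hatch <- expected_hatch(mother_ci, father_ci, p)
  nuc <- mendelian_nuclear(mother$nuclear, father$nuclear)
  p_ci <- if (mother_ci) p$tau_ci else 0
  p_mk <- if (mother_mk) p$tau_mk else 0
  grid <- tidyr::expand_grid(
    sex = c("female", "male"),
    nuclear = names(nuc),
    has_ci = c(TRUE, FALSE),
    has_mk = c(TRUE, FALSE)
  )
  offspring <- grid |>
    mutate(
      p_birth = ifelse(.data$sex == "female", p$sex_ratio_0,
                       1 - p$sex_ratio_0) *
        nuc[.data$nuclear] *
        ifelse(.data$has_ci, p_ci, 1 - p_ci) *
        ifelse(.data$has_mk, p_mk, 1 - p_mk),
      p_survive = 1 - map_dbl(
        seq_len(dplyr::n()),
        function(i) mk_death_prob(.data$sex[i], .data$nuclear[i], mother_mk, p)
      )
    ) |>
    mutate(p_adult = .data$p_birth * .data$p_survive / sum(.data$p_birth * .data$p_survive))
  mean_survive <- sum(offspring$p_birth * offspring$p_survive)
  p_female_adult <- sum(offspring$p_birth * offspring$p_survive *
                          (offspring$sex == "female"))
  structure(
    list(
      expected_hatch = hatch,
      expected_egg_to_adult = p$v_0 * (hatch / p$h_0) * mean_survive,
      expected_prop_female = p_female_adult / mean_survive,
      offspring = offspring,
      mother = mother, father = father, params = p
    ),
    class = "cross_outcome"
  )
}

#' @export
print.cross_outcome <- function(x, ...) {
  cat(sprintf(
    "cross: %%hatch %.1f, %%egg-to-adult %.1f, %%female among adults %.1f\n",
    100 * x$expected_hatch, 100 * x$expected_egg_to_adult,
    100 * x$expected_prop_female
  ))
  invisible(x)
}

#' Classify a line's MK phenotype from offspring sex counts
#'
#' A line is scored `MK` (male killing expressed) when it produces no male
#' offspring, `MKS` (suppressed) when its proportion of females does not
#' exceed `mixed_max_prop_female`, and `excluded` when the brood is too small
#' or the sex ratio is ambiguously female-biased (MK may be leaky).
#'
#' @param n_female,n_male Offspring counts (vectorised).
#' @param min_total Minimum total offspring for a confident call.
#' @param female_only_max_males Maximum males compatible with an `MK` call.
#' @param mixed_max_prop_female Maximum proportion female for an `MKS` call.
#' @return Character vector: `"MK"`, `"MKS"` or `"excluded"`.
#' @examples
#' classify_line_phenotype(c(30, 12, 18), c(0, 2, 14))
#' @export
classify_line_phenotype <- function(n_female, n_male, min_total = 15L,
                                    female_only_max_males = 0L,
                                    mixed_max_prop_female = 0.70) {
  if (any(n_female < 0 | n_male < 0)) abort("counts must be >= 0")
  total <- n_female + n_male
  prop_f <- ifelse(total > 0, n_female / total, NA_real_)
  dplyr::case_when(
    total < min_total ~ "excluded",
    n_male <= female_only_max_males ~ "MK",
    prop_f <= mixed_max_prop_female ~ "MKS",
    TRUE ~ "excluded"
  )
}

# Stochastically realise the adult offspring of a set of mated mothers.
# `mothers` is a tibble with columns nuclear, has_ci, has_mk and mate_nuclear,
# mate_has_ci. Returns a tibble of adults (sex, nuclear, has_ci, has_mk,
# mother_id) — one row per surviving offspring.
realize_broods <- function(mothers, p, eggs_per_female) {
  n_eggs <- rpois(nrow(mothers), eggs_per_female)
  if (sum(n_eggs) == 0L) {
    return(tibble(mother_id = integer(), sex = character(),
                  nuclear = character(), has_ci = logical(),
                  has_mk = logical()))
  }
  mid <- rep.int(seq_len(nrow(mothers)), n_eggs)
  m <- mothers[mid, ]
  n <- length(mid)
  sex <- ifelse(runif(n) < p$sex_ratio_0, "female", "male")
  allele_m <- runif(n) < c(ss = 0, Ss = 0.5, SS = 1)[m$nuclear]
  allele_f <- runif(n) < c(ss = 0, Ss = 0.5, SS = 1)[m$mate_nuclear]
  nuclear <- dplyr::case_when(
    allele_m & allele_f ~ "SS",
    allele_m | allele_f ~ "Ss",
    TRUE ~ "ss"
  )
  has_ci <- m$has_ci & runif(n) < p$tau_ci
  has_mk <- m$has_mk & runif(n) < p$tau_mk
  hatch <- ifelse(m$mate_has_ci & !m$has_ci,
                  p$male_ci_loss * p$h_0 + (1 - p$male_ci_loss) * p$h_ci,
                  p$h_0)
  death <- ifelse(
    m$has_mk & sex == "male",
    p$mu * (1 - p$leak) * ifelse(nuclear == "ss", 1, 1 - p$penetrance),
    0
  )
  p_adult <- p$v_0 * (hatch / p$h_0) * (1 - death)
  keep <- runif(n) < p_adult
  tibble(mother_id = mid, sex = sex, nuclear = nuclear,
         has_ci = has_ci, has_mk = has_mk)[keep, ]
}

#' Simulate the segregation of MK suppression through backcrossing
#'
#' Simulates the introgression design used to expose a dominant suppressor:
#' suppressed donor females (`SS`, carrying both strains) are crossed to
#' recurrent uninfected `ss` males; each following generation, offspring
#' females are pooled across lines and re-crossed individually to
#' recurrent-line males. Each line (female parent) is scored from her adult
#' offspring with [classify_line_phenotype()]. The deterministic expectation
#' under full penetrance is 0% MK lines at F1 (every offspring carries `S`)
#' and, from backcross 2 on, 50% of mothers are `ss` so about half the lines
#' revert to female-only broods (times the MK strain's cumulative maternal
#' transmission).
#'
#' @param n_lines Female parents tested per generation.
#' @param generations Number of scored generations: F1, then backcrosses.
#' @param p A [model_params()].
#' @param donor,recurrent [individual()] templates for the founding females
#'   and the recurrent-line males.
#' @param eggs_per_female Poisson mean of eggs scored per line (vial-level
#'   scoring over several days of oviposition).
#' @param seed Integer seed.
#' @return A tibble per generation: `generation` (`F1`, `BC1`, ...),
#'   `n_lines`, `percent_mk` (lines classified MK), `percent_excluded`, and
#'   the deterministic `expected_percent_mk`.
#' @export
simulate_backcross_panel <- function(n_lines = 20L, generations = 3L,
                                     p = model_params(),
                                     donor = individual("female", "SS",
                                                        c("CI", "MK")),
                                     recurrent = individual("male", "ss",
                                                            character()),
                                     eggs_per_female = 60, seed = 42L) {
  set.seed(seed)
  gen_labels <- c("F1", paste0("BC", seq_len(max(0L, generations - 1L))))
  gen_labels <- gen_labels[seq_len(generations)]
  mothers <- tibble(
    nuclear = rep(donor$nuclear, n_lines),
    has_ci = "CI" %in% donor$cytotype,
    has_mk = "MK" %in% donor$cytotype,
    mate_nuclear = recurrent$nuclear,
    mate_has_ci = "CI" %in% recurrent$cytotype
  )
  # expected fraction of ss mothers per scored generation under S fixed in
  # the donor: 0 (donor SS), 0 (F1 Ss), then 1/2 from BC2 onwards
  exp_ss <- c(0, 0, rep(0.5, max(0L, generations - 2L)))[seq_len(generations)]
  out <- vector("list", generations)
  for (g in seq_len(generations)) {
    adults <- realize_broods(mothers, p, eggs_per_female)
    per_line <- adults |>
      group_by(.data$mother_id) |>
      summarise(n_female = sum(.data$sex == "female"),
                n_male = sum(.data$sex == "male"), .groups = "drop")
    # lines whose brood died out entirely count as excluded
    n_f <- n_m <- rep(0L, nrow(mothers))
    n_f[per_line$mother_id] <- per_line$n_female
    n_m[per_line$mother_id] <- per_line$n_male
    cls <- classify_line_phenotype(n_f, n_m)
    out[[g]] <- tibble(
      generation = gen_labels[g],
      n_lines = nrow(mothers),
      percent_mk = 100 * mean(cls == "MK"),
      percent_mks = 100 * mean(cls == "MKS"),
      percent_excluded = 100 * mean(cls == "excluded"),
      expected_percent_mk = 100 * exp_ss[g] * p$tau_mk^(g - 1L)
    )
    if (g < generations) {
      daughters <- filter(adults, .data$sex == "female")
      if (nrow(daughters) == 0L) {
        abort("no daughters left to continue the backcross design")
      }
      pick <- daughters[sample.int(nrow(daughters), n_lines, replace = nrow(daughters) < n_lines), ]
      mothers <- tibble(
        nuclear = pick$nuclear, has_ci = pick$has_ci, has_mk = pick$has_mk,
        mate_nuclear = recurrent$nuclear,
        mate_has_ci = "CI" %in% recurrent$cytotype
      )
    }
  }
  bind_rows(out)
}

#' Simulate the spread of MK suppression in mixed vial populations
#'
#' Discrete-generation, individual-based simulation of laboratory vials
#' founded with a mixture of unsuppressed `MK` females (`ss`, carrying CI and
#' MK, pre-mated to uninfected `ss` males) and suppressed `MKS` females
#' (`SS`, carrying CI and MK, pre-mated to `SS` males). Each generation,
#' every female mates once with a male drawn uniformly from the vial's males
#' (uninfected `ss` rescue males are supplied when the vial has none — the
#' maintenance scheme for female-only vials), broods are realised
#' stochastically, and up to `vial_size` adults are sampled to found the next
#' generation. The percent of females among emerging adults is recorded each
#' generation; rescue males are not counted.
#'
#' @param init_mk_fraction Starting fraction of MK (unsuppressed) females.
#' @param vial_size Adults kept per generation.
#' @param generations Number of offspring generations tracked.
#' @param rescue_males Uninfected `ss` males added when a vial has no males.
#' @param p A [model_params()].
#' @param n_replicates Replicate vials.
#' @param eggs_per_female Poisson mean eggs per female.
#' @param seed Integer seed.
#' @return A tibble of class `vial_trajectories`: `replicate`, `generation`,
#'   `percent_female`, `n_adults`, `extinct`.
#' @export
simulate_mixed_population <- function(init_mk_fraction = 0.9, vial_size = 40L,
                                      generations = 5L, rescue_males = 5L,
                                      p = model_params(), n_replicates = 10L,
                                      eggs_per_female = 60, seed = 42L) {
  check_prob(init_mk_fraction, "init_mk_fraction")
  set.seed(seed)
  one_rep <- function(rep_id) {
    n_mk <- round(init_mk_fraction * vial_size)
    n_mks <- vial_size - n_mk
    mothers <- bind_rows(
      tibble(nuclear = rep("ss", n_mk), has_ci = TRUE, has_mk = TRUE,
             mate_nuclear = "ss", mate_has_ci = FALSE),
      tibble(nuclear = rep("SS", n_mks), has_ci = TRUE, has_mk = TRUE,
             mate_nuclear = "SS", mate_has_ci = TRUE)
    )
    rows <- vector("list", generations)
    for (g in seq_len(generations)) {
      adults <- realize_broods(mothers, p, eggs_per_female)
      if (nrow(adults) == 0L) {
        rows[[g]] <- tibble(replicate = rep_id, generation = g,
                            percent_female = NA_real_, n_adults = 0L,
                            extinct = TRUE)
        break
      }
      # sex ratio is scored on the full emergence; the vial then carries
      # forward at most `vial_size` adults
      rows[[g]] <- tibble(
        replicate = rep_id, generation = g,
        percent_female = 100 * mean(adults$sex == "female"),
        n_adults = nrow(adults), extinct = FALSE
      )
      if (nrow(adults) > vial_size) {
        adults <- adults[sample.int(nrow(adults), vial_size), ]
      }
      if (g < generations) {
        females <- filter(adults, .data$sex == "female")
        males <- filter(adults, .data$sex == "male")
        if (nrow(females) == 0L) {
          rows[[g]]$extinct <- TRUE
          break
        }
        if (nrow(males) == 0L) {
          males <- tibble(
            sex = rep("male", rescue_males), nuclear = "ss",
            has_ci = FALSE, has_mk = FALSE, mother_id = NA_integer_
          )
        }
        mate <- males[sample.int(nrow(males), nrow(females), replace = TRUE), ]
        mothers <- tibble(
          nuclear = females$nuclear, has_ci = females$has_ci,
          has_mk = females$has_mk,
          mate_nuclear = mate$nuclear, mate_has_ci = mate$has_ci
        )
      }
    }
    bind_rows(rows)
  }
  out <- bind_rows(purrr::map(seq_len(n_replicates), one_rep))
  class(out) <- c("vial_trajectories", class(out))
  out
}

#' Likelihood-ratio G-test on a k x 2 incidence table
#'
#' `G = 2 * sum(O * ln(O / E))` over cells with positive observed counts,
#' with expected counts from the row/column marginals, referred to a
#' chi-squared distribution on `k - 1` degrees of freedom.
#'
#' @param counts A k x 2 matrix or data frame of (affected, unaffected)
#'   counts per category.
#' @return An object of class `htest`.
#' @examples
#' g_test(rbind(c(10, 90), c(20, 80)))
#' @export
g_test <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) != 2L) abort("`counts` must have exactly 2 columns")
  if (any(m < 0)) abort("counts must be >= 0")
  if (any(rowSums(m) == 0)) abort("row totals must be > 0")
  if (any(colSums(m) == 0)) abort("a column of all zeros leaves G undefined")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  obs <- m[m > 0]
  g <- 2 * sum(obs * log(obs / expected[m > 0]))
  df <- nrow(m) - 1L
  structure(
    list(
      statistic = c(G = g), parameter = c(df = df),
      p.value = pchisq(g, df, lower.tail = FALSE),
      method = "Likelihood-ratio G-test of independence",
      data.name = deparse(substitute(counts))
    ),
    class = "htest"
  )
}

#' Chi-squared test of a sex ratio against 50:50
#'
#' `X^2 = (n_f - n_m)^2 / (n_f + n_m)` on 1 degree of freedom.
#'
#' @param n_female,n_male Offspring counts.
#' @return An object of class `htest`.
#' @examples
#' sex_ratio_chisq(90, 10)
#' @export
sex_ratio_chisq <- function(n_female, n_male) {
  if (n_female + n_male <= 0) abort("need at least one offspring")
  stat <- (n_female - n_male)^2 / (n_female + n_male)
  structure(
    list(
      statistic = c(`X-squared` = stat), parameter = c(df = 1),
      p.value = pchisq(stat, 1, lower.tail = FALSE),
      method = "Chi-squared test against a 50:50 sex ratio",
      data.name = sprintf("%d females, %d males", n_female, n_male)
    ),
    class = "htest"
  )
}

#' Relative symbiont density from qPCR crossing points
#'
#' Density of a target marker relative to a host reference marker,
#' `2^(mean(Cp_host) - mean(Cp_target))`, from replicate crossing-point (Cp)
#' runs. A quality flag is raised when the replicate standard deviation of
#' either marker exceeds `sd_threshold`.
#'
#' @param cp_target,cp_host Numeric vectors of replicate Cp values.
#' @param sd_threshold Replicate SD above which the measurement is flagged.
#' @return A one-row tibble: `density`, `qc_flag`, `sd_target`, `sd_host`.
#' @examples
#' relative_density(c(25.0, 25.2), c(21.6, 21.8))
#' @export
relative_density <- function(cp_target, cp_host, sd_threshold = 2.5) {
  if (length(cp_target) < 1L || length(cp_host) < 1L) {
    abort("each marker needs at least one replicate Cp value")
  }
  sd_t <- if (length(cp_target) > 1L) sd(cp_target) else 0
  sd_h <- if (length(cp_host) > 1L) sd(cp_host) else 0
  tibble(
    density = 2^(mean(cp_host) - mean(cp_target)),
    qc_flag = sd_t > sd_threshold | sd_h > sd_threshold,
    sd_target = sd_t,
    sd_host = sd_h
  )
}

#' Incidence of a binary line phenotype across collection sites
#'
#' Per-site and overall percentages of affected lines (e.g. female-biased
#' isofemale lines per field collection site), with the [g_test()] of
#' homogeneity across sites attached as attribute `g_test`.
#'
#' @param counts Data frame with columns `site`, `n_lines`, `n_affected`.
#' @return A tibble of per-site rows plus an `overall` row with
#'   `percent_affected` rounded to 0.01.
#' @export
incidence_summary <- function(counts) {
  counts <- as_tibble(counts)
  if (!all(c("site", "n_lines", "n_affected") %in% names(counts))) {
    abort("`counts` needs columns site, n_lines, n_affected")
  }
  if (any(counts$n_affected > counts$n_lines)) {
    abort("`n_affected` cannot exceed `n_lines`")
  }
  out <- bind_rows(
    counts,
    tibble(site = "overall", n_lines = sum(counts$n_lines),
           n_affected = sum(counts$n_affected))
  ) |>
    mutate(percent_affected = round(100 * .data$n_affected / .data$n_lines, 2))
  attr(out, "g_test") <- g_test(
    cbind(counts$n_affected, counts$n_lines - counts$n_affected)
  )
  out
}
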