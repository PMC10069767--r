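# broom-style tidiers for the package's fitted/result objects.

#' Tidy a titer estimate
#'
#' @param x A `titer_estimate` from [estimate_titer()].
#' @param ... Unused.
#' @return One row per strain (`private_carrier` and `co_infecting`) with
#'   `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.titer_estimate <- function(x, ...) {
  tibble(
    term = c("private_carrier", "co_infecting"),
    estimate = c(x$f_hat, 1 - x$f_hat),
    conf.low = c(x$ci_low, 1 - x$ci_high),
    conf.high = c(x$ci_high, 1 - x$ci_low)
  )
}

#' Glance at a titer estimate
#' @param x A `titer_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the estimate and bootstrap settings.
#' @export
glance.titer_estimate <- function(x, ...) {
  tibble(
    f_hat = x$f_hat, ci_low = x$ci_low, ci_high = x$ci_high,
    n_windows_used = x$n_windows_used, n_boot = x$n_boot, conf = x$conf
  )
}

#' Tidy a cross outcome into its offspring genotype distribution
#' @param x A `cross_outcome` from [expected_cross_outcome()].
#' @param ... Unused.
#' @return The offspring class tibble (`p_birth` sums to 1).
#' @export
tidy.cross_outcome <- function(x, ...) x$offspring

#' Glance at a cross outcome
#' @param x A `cross_outcome`.
#' @param ... Unused.
#' @return One row with expected hatch, egg-to-adult viability and percent
#'   female among adults.
#' @export
glance.cross_outcome <- function(x, ...) {
  tibble(
    expected_hatch = x$expected_hatch,
    expected_egg_to_adult = x$expected_egg_to_adult,
    expected_prop_female = x$expected_prop_female
  )
}

#' Tidy a genotype matrix into long format
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A long tibble: one row per sample x site with genotype code and
#'   sample/site metadata.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  long <- as_tibble(x$geno, .name_repair = "minimal")
  names(long) <- paste0("site", seq_len(ncol(long)))
  long$sample_id <- x$samples$sample_id
  long <- tidyr::pivot_longer(long, -"sample_id", names_to = "site_idx",
                              values_to = "genotype")
  long$site_idx <- as.integer(sub("site", "", long$site_idx))
  long |>
    left_join(mutate(x$sites, site_idx = row_number()), by = "site_idx") |>
    left_join(x$samples, by = "sample_id") |>
    select(-"site_idx")
}
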