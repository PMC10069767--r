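#' Construct a genotype matrix container
#'
#' Holds sample-by-site biallelic genotypes coded 0/1/2 (copies of the
#' alternate allele, `NA` = missing) with site metadata (contig, 1-based
#' position, ref/alt alleles) and sample metadata (line, phenotype group).
#' Sites are kept sorted by contig then position.
#'
#' @param geno Integer matrix, samples in rows, sites in columns.
#' @param sites Tibble with `contig`, `pos`, and optionally `ref`, `alt`.
#' @param samples Tibble with `sample_id` and grouping columns such as
#'   `line`, `phenotype`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, samples) {
  geno <- as.matrix(geno)
  sites <- as_tibble(sites)
  samples <- as_tibble(samples)
  if (nrow(geno) != nrow(samples)) abort("rows of `geno` must match `samples`")
  if (ncol(geno) != nrow(sites)) abort("columns of `geno` must match `sites`")
  if (!all(c("contig", "pos") %in% names(sites))) {
    abort("`sites` needs `contig` and `pos` columns")
  }
  if (!"sample_id" %in% names(samples)) abort("`samples` needs `sample_id`")
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) abort("genotype codes must be 0, 1, 2 or NA")
  ord <- order(sites$contig, sites$pos)
  structure(
    list(geno = geno[, ord, drop = FALSE], sites = sites[ord, ],
         samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d sites on %d contig(s)\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$sites$contig))
  ))
  if ("phenotype" %in% names(x$samples)) {
    print(table(x$samples$phenotype))
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# Per-site allele statistics across a sample subset.
site_allele_stats <- function(geno) {
  called <- colSums(!is.na(geno))
  alt <- colSums(geno, na.rm = TRUE)
  p_alt <- ifelse(called > 0, alt / (2 * called), NA_real_)
  mac <- pmin(alt, 2 * called - alt)
  tibble(
    n_called = called,
    call_rate = called / nrow(geno),
    mac = mac,
    maf = pmin(p_alt, 1 - p_alt),
    p_alt = p_alt,
    h_o = ifelse(called > 0, colSums(geno == 1L, na.rm = TRUE) / called,
                 NA_real_),
    h_e = 2 * p_alt * (1 - p_alt)
  )
}

#' Filter SNP sites on call rate and minor allele count
#'
#' Retains sites called in at least `min_call_rate` of all individuals and
#' with at least `min_mac` copies of the minor allele overall. The numbers
#' removed by each criterion are attached as attribute `removed` and printed.
#' The filter is idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param min_call_rate Minimum fraction of individuals with a called
#'   genotype.
#' @param min_mac Minimum overall minor allele count.
#' @param quiet Suppress the removal message.
#' @return The filtered `genotype_matrix`.
#' @export
filter_sites <- function(gm, min_call_rate = 0.95, min_mac = 3L,
                         quiet = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (min_call_rate < 0 || min_call_rate > 1) {
    abort("`min_call_rate` must be in [0, 1]")
  }
  if (min_mac < 0) abort("`min_mac` must be >= 0")
  st <- site_allele_stats(gm$geno)
  keep_cr <- st$call_rate >= min_call_rate
  keep_mac <- st$mac >= min_mac
  keep <- keep_cr & keep_mac
  out <- genotype_matrix(gm$geno[, keep, drop = FALSE], gm$sites[keep, ],
                         gm$samples)
  attr(out, "truth") <- attr(gm, "truth")
  attr(out, "removed") <- c(
    low_call_rate = sum(!keep_cr),
    low_mac = sum(!keep_mac),
    total_removed = sum(!keep)
  )
  if (!quiet) {
    message(sprintf(
      "filter_sites: kept %d/%d sites (%d below call rate %.2f, %d below MAC %d)",
      sum(keep), length(keep), sum(!keep_cr), min_call_rate, sum(!keep_mac),
      as.integer(min_mac)
    ))
  }
  out
}

#' Observed/expected heterozygosity and F_IS per group and contig
#'
#' For each sample group, sites with any missing genotype in that group are
#' omitted (complete-cases rule) and, per contig and genome-wide:
#' `H_O` = mean fraction of heterozygous genotypes, `H_E` = mean `2p(1-p)`,
#' and `F_IS = 1 - H_O / H_E` (reported as `NA` when `H_E = 0`).
#'
#' @param gm A [genotype_matrix()].
#' @param group_by Sample-metadata columns defining the groups (default
#'   `"phenotype"`).
#' @param include_monomorphic Keep monomorphic sites in the averages (they
#'   contribute 0 to both H_O and H_E), as when heterozygosity is computed
#'   over all callable sites rather than the SNP set.
#' @return A tibble with one row per group x contig plus a `genome` row per
#'   group: `n_sites`, `h_o`, `h_e`, `f_is`.
#' @export
heterozygosity_stats <- function(gm, group_by = "phenotype",
                                 include_monomorphic = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!all(group_by %in% names(gm$samples))) {
    abort("grouping columns missing from sample metadata")
  }
  key <- do.call(paste, c(gm$samples[group_by], sep = "/"))
  groups <- split(seq_len(nrow(gm$geno)), key)
  if (any(lengths(groups) < 2L)) abort("each group needs >= 2 samples")
  out <- purrr::imap(groups, function(rows, gname) {
    sub <- gm$geno[rows, , drop = FALSE]
    complete <- colSums(is.na(sub)) == 0L
    st <- site_allele_stats(sub)
    poly <- !is.na(st$maf) & st$maf > 0
    use <- complete & (include_monomorphic | poly)
    per_unit <- function(idx, label) {
      if (sum(idx) == 0L) {
        return(tibble(group = gname, contig = label, n_sites = 0L,
                      h_o = NA_real_, h_e = NA_real_, f_is = NA_real_))
      }
      h_o <- mean(st$h_o[idx])
      h_e <- mean(st$h_e[idx])
      tibble(
        group = gname, contig = label, n_sites = sum(idx),
        h_o = h_o, h_e = h_e,
        f_is = if (h_e > 0) 1 - h_o / h_e else NA_real_
      )
    }
    bind_rows(
      purrr::map(unique(gm$sites$contig), function(ct) {
        per_unit(use & gm$sites$contig == ct, ct)
      }),
      list(per_unit(use, "genome"))
    )
  }) |> bind_rows()
  out
}

#' Contrast each contig against the genome background per group
#'
#' For each group, computes the relative deviation of a contig's H_O and
#' F_IS from the mean of all other contigs,
#' `(value - mean(others)) / |mean(others)|`, and flags candidate
#' suppressor-linked contigs showing the directional signature of the
#' introgression design: observed heterozygosity depressed below the genome
#' background in the unsuppressed (swept) group while elevated above it in
#' the suppressed group, whose lines retain the donor haplotype.
#'
#' @param stats Output of [heterozygosity_stats()].
#' @param swept_group,retained_group Group labels of the unsuppressed (MK)
#'   and suppressed (MKS) lines in `stats`.
#' @param min_dev Minimum absolute relative deviation for flagging.
#' @return A tibble `group` x `contig` with `dev_h_o`, `dev_f_is` and a
#'   per-contig logical `flagged`.
#' @export
contig_contrast <- function(stats, swept_group = "MK",
                            retained_group = "MKS", min_dev = 0.10) {
  per_contig <- filter(stats, .data$contig != "genome")
  contigs <- unique(per_contig$contig)
  if (length(contigs) < 2L) abort("no background: need >= 2 contigs")
  if (!all(c(swept_group, retained_group) %in% per_contig$group)) {
    abort("swept/retained groups not found in `stats`")
  }
  dev <- per_contig |>
    group_by(.data$group) |>
    mutate(
      dev_h_o = deviation_vs_others(.data$h_o),
      dev_f_is = deviation_vs_others(.data$f_is)
    ) |>
    ungroup() |>
    select("group", "contig", "h_o", "f_is", "dev_h_o", "dev_f_is")
  flags <- dev |>
    group_by(.data$contig) |>
    summarise(
      flagged =
        any(.data$group == swept_group & .data$dev_h_o < -min_dev) &&
        any(.data$group == retained_group & .data$dev_h_o > min_dev),
      .groups = "drop"
    )
  left_join(dev, flags, by = "contig")
}

deviation_vs_others <- function(x) {
  vapply(seq_along(x), function(i) {
    m <- mean(x[-i], na.rm = TRUE)
    if (!is.finite(m) || m == 0) return(NA_real_)
    (x[i] - m) / abs(m)
  }, double(1))
}

#' Construct a sweep interval record
#'
#' @param contig Contig name.
#' @param start,end 1-based positions of the first and last SNP in the swept
#'   run. The interval length is the exclusive difference `end - start`.
#' @param n_snps Number of member SNPs.
#' @param max_group_maf Largest group MAF among member SNPs.
#' @return A one-row tibble with a computed `length` column.
#' @examples
#' sweep_interval("NW_1", 3321074, 4637826)$length # 1316752
#' @export
sweep_interval <- function(contig, start, end, n_snps = NA_integer_,
                           max_group_maf = NA_real_) {
  tibble(
    contig = contig, start = start, end = end,
    length = end - start,
    n_snps = n_snps, max_group_maf = max_group_maf
  )
}

#' Detect swept low-diversity intervals from group minor allele frequencies
#'
#' Per contig, finds maximal runs of consecutive SNPs whose minor allele
#' frequency in the chosen group is below `maf_threshold`, tolerating up to
#' `max_interrupt` violating SNPs inside a run. Runs of at least `min_snps`
#' member SNPs become intervals spanning the first to last member SNP.
#'
#' @param gm A filtered [genotype_matrix()].
#' @param group Phenotype group scanned for the sweep (default `"MK"`, the
#'   unsuppressed lines in which the suppressor region is swept).
#' @param group_col Sample-metadata column holding the group labels.
#' @param maf_threshold MAF below which a SNP is a sweep member.
#' @param min_snps Minimum member SNPs per interval.
#' @param max_interrupt Maximum violating SNPs tolerated inside a run.
#' @param contigs Optional contig subset to scan (e.g. the candidates
#'   flagged by [contig_contrast()]); default all.
#' @return A tibble of sweep intervals (possibly empty) as in
#'   [sweep_interval()].
#' @export
detect_sweep <- function(gm, group = "MK", group_col = "phenotype",
                         maf_threshold = 0.1, min_snps = 25L,
                         max_interrupt = 2L, contigs = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rows <- which(gm$samples[[group_col]] == group)
  if (length(rows) == 0L) abort(sprintf("group '%s' not present", group))
  st <- site_allele_stats(gm$geno[rows, , drop = FALSE])
  scan_contigs <- if (is.null(contigs)) unique(gm$sites$contig) else
    intersect(unique(gm$sites$contig), contigs)
  out <- purrr::map(scan_contigs, function(ct) {
    idx <- which(gm$sites$contig == ct)
    member <- !is.na(st$maf[idx]) & st$maf[idx] < maf_threshold
    runs <- merge_runs(member, min_snps, max_interrupt)
    if (length(runs) == 0L) return(NULL)
    bind_rows(purrr::map(runs, function(r) {
      sweep_interval(
        contig = ct,
        start = gm$sites$pos[idx[min(r)]],
        end = gm$sites$pos[idx[max(r)]],
        n_snps = length(r),
        max_group_maf = max(st$maf[idx[r]])
      )
    }))
  }) |> bind_rows()
  if (nrow(out) == 0L) {
    out <- sweep_interval(character(), double(), double())[0, ]
  }
  out
}

#' Map the suppressor region: the full sweep-scan pipeline
#'
#' Chains the module end to end: SNP filtering ([filter_sites()]),
#' group heterozygosity ([heterozygosity_stats()]), directional contig
#' contrast ([contig_contrast()]) to nominate candidate suppressor contigs,
#' and run-based sweep detection ([detect_sweep()]) restricted to those
#' candidates. Restricting the scan to contrast-nominated contigs supplies
#' the specificity that the single-group MAF-run statistic lacks on its own:
#' backcross ancestry is strongly autocorrelated along a contig, so low-MAF
#' runs arise by chance on unlinked contigs, but only the suppressor contig
#' shows variation depressed in the swept group yet elevated in the
#' suppressed group.
#'
#' @param gm A [genotype_matrix()] with a phenotype column.
#' @param swept_group,retained_group Phenotype labels of the unsuppressed
#'   and suppressed groups.
#' @param min_call_rate,min_mac Site filters.
#' @param min_dev Contrast flagging threshold.
#' @param ... Passed to [detect_sweep()].
#' @return A list of class `suppressor_scan`: `gm` (filtered), `stats`,
#'   `contrast`, `candidates` (flagged contigs) and `sweeps`.
#' @export
map_suppressor_region <- function(gm, swept_group = "MK",
                                  retained_group = "MKS",
                                  min_call_rate = 0.95, min_mac = 3L,
                                  min_dev = 0.10, ...) {
  gmf <- filter_sites(gm, min_call_rate, min_mac, quiet = TRUE)
  stats <- heterozygosity_stats(gmf)
  contrast <- contig_contrast(stats, swept_group, retained_group, min_dev)
  candidates <- unique(contrast$contig[contrast$flagged])
  sweeps <- detect_sweep(gmf, group = swept_group, contigs = candidates, ...)
  structure(
    list(gm = gmf, stats = stats, contrast = contrast,
         candidates = candidates, sweeps = sweeps),
    class = "suppressor_scan"
  )
}

#' @export
print.suppressor_scan <- function(x, ...) {
  cat(sprintf("suppressor scan: %d candidate contig(s): %s\n",
              length(x$candidates), paste(x$candidates, collapse = ", ")))
  print(x$sweeps)
  invisible(x)
}
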