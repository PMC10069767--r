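#' Specify a pair of closely related symbiont strains
#'
#' Describes the ground truth for a two-strain (superinfected) symbiont
#' system: a shared backbone, genomic regions private to each strain, copy
#' number variant (CNV) regions, and the relative titer of strain A.
#' Coordinates are 1-based with inclusive starts and exclusive ends, so the
#' interval `[600001, 700001)` covers 100 kb. Strain A is taken as the
#' reference/assembled strain; regions private to strain B are extra sequence
#' absent from the reference and therefore invisible to reference-based depth
#' analysis.
#'
#' @param backbone_length Backbone length in bp shared by the two strains.
#' @param private_regions_a,private_regions_b Data frames with `start`/`end`
#'   columns giving intervals present only in strain A (on backbone
#'   coordinates) or only in strain B (novel sequence, lengths only are used).
#' @param cnv_regions Data frame with `start`, `end`, `copies_a`, `copies_b`:
#'   intervals whose copy number differs between the strains.
#' @param titer_a Fraction of all symbiont cells belonging to strain A.
#' @param seed Integer seed used by generators consuming this spec.
#' @return A `strain_pair_spec` list.
#' @examples
#' strain_pair_spec(
#'   backbone_length = 1e6,
#'   private_regions_a = data.frame(start = c(600001, 900001),
#'                                  end   = c(700001, 950001)),
#'   titer_a = 0.7
#' )
#' @export
strain_pair_spec <- function(backbone_length,
                             private_regions_a = NULL,
                             private_regions_b = NULL,
                             cnv_regions = NULL,
                             titer_a = 0.7,
                             seed = 42L) {
  L <- check_count(backbone_length, "backbone_length", min = 1)
  check_prob(titer_a, "titer_a")
  priv_a <- check_intervals(private_regions_a, L, "private_regions_a")
  priv_b <- if (is.null(private_regions_b)) {
    tibble(start = integer(), end = integer())
  } else {
    as_tibble(private_regions_b)
  }
  cnv <- if (is.null(cnv_regions)) {
    tibble(start = integer(), end = integer(),
           copies_a = integer(), copies_b = integer())
  } else {
    cnv <- as_tibble(cnv_regions)
    stopifnot(all(c("start", "end", "copies_a", "copies_b") %in% names(cnv)))
    cnv
  }
  # private and CNV intervals live on the same backbone and must not collide
  all_iv <- bind_rows(
    select(priv_a, "start", "end"),
    select(cnv, "start", "end")
  )
  check_intervals(all_iv, L, "private/cnv")
  structure(
    list(
      backbone_length = L,
      private_regions_a = priv_a,
      private_regions_b = priv_b,
      cnv_regions = cnv,
      titer_a = titer_a,
      seed = as.integer(seed)
    ),
    class = "strain_pair_spec"
  )
}

#' Specify Poisson sequencing-coverage simulation
#'
#' @param mean_depth Expected per-base read depth (Poisson mean) for
#'   single-copy shared sequence.
#' @param window Window size in bp for downstream windowed analysis.
#' @param step Step between window starts in bp.
#' @param seed Integer seed.
#' @return A `coverage_sim_spec` list.
#' @export
coverage_sim_spec <- function(mean_depth = 50, window = 1000L, step = 500L,
                              seed = 42L) {
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    abort("`mean_depth` must be > 0")
  }
  window <- check_count(window, "window", min = 1)
  step <- check_count(step, "step", min = 1)
  if (step > window) abort("`step` must not exceed `window`")
  structure(
    list(mean_depth = mean_depth, window = window, step = step,
         seed = as.integer(seed)),
    class = "coverage_sim_spec"
  )
}

#' Generate a synthetic strain pair with truth annotations
#'
#' Materialises the two strain genomes described by a [strain_pair_spec()] and
#' a truth table of every interval whose expected read depth (in a mixture
#' mapped against the strain A reference) differs from the single-copy shared
#' baseline. The truth table records, for each interval, the copy number in
#' each strain and the pure copy-number depth ratio `copies_b / copies_a`
#' (the expected normalized depth if the sample were pure strain B).
#'
#' @param spec A [strain_pair_spec()].
#' @param sequences If `TRUE` (default) random nucleotide sequences are
#'   generated for both strains; set `FALSE` to return only the truth table
#'   (sufficient for depth simulation) when the backbone is large.
#' @return A list of class `strain_pair` with elements `genome_a`, `genome_b`
#'   (character scalars or `NULL`), `truth` (tibble: `start`, `end`, `class`,
#'   `copies_a`, `copies_b`, `depth_ratio_cnv`) and `spec`.
#' @examples
#' sp <- strain_pair_spec(1e4, data.frame(start = 2001, end = 4001))
#' pair <- make_strain_pair(sp)
#' pair$truth
#' @export
make_strain_pair <- function(spec, sequences = TRUE) {
  stopifnot(inherits(spec, "strain_pair_spec"))
  L <- spec$backbone_length
  truth <- bind_rows(
    mutate(spec$private_regions_a,
           class = "a_private", copies_a = 1L, copies_b = 0L),
    mutate(spec$cnv_regions, class = "cnv")
  )
  truth <- if (nrow(truth) == 0L) {
    tibble(start = integer(), end = integer(), class = character(),
           copies_a = integer(), copies_b = integer(),
           depth_ratio_cnv = double())
  } else {
    truth |>
      mutate(depth_ratio_cnv = .data$copies_b / .data$copies_a) |>
      select("start", "end", "class", "copies_a", "copies_b",
             "depth_ratio_cnv") |>
      arrange(.data$start)
  }
  genome_a <- genome_b <- NULL
  if (sequences) {
    set.seed(spec$seed)
    backbone <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    genome_a <- paste(backbone, collapse = "")
    keep <- rep(TRUE, L)
    for (i in seq_len(nrow(spec$private_regions_a))) {
      keep[spec$private_regions_a$start[i]:(spec$private_regions_a$end[i] - 1L)] <- FALSE
    }
    b_extra_len <- if (nrow(spec$private_regions_b) > 0L) {
      sum(spec$private_regions_b$end - spec$private_regions_b$start)
    } else 0L
    b_extra <- if (b_extra_len > 0L) {
      sample(c("A", "C", "G", "T"), b_extra_len, replace = TRUE)
    } else character()
    genome_b <- paste(c(backbone[keep], b_extra), collapse = "")
  }
  structure(
    list(genome_a = genome_a, genome_b = genome_b, truth = truth, spec = spec),
    class = "strain_pair"
  )
}

#' Simulate read depth for a two-strain mixture over the reference strain
#'
#' Draws independent per-base Poisson depths over strain A (reference)
#' coordinates for a mixture in which strain A makes up `titer_a` of all
#' symbiont cells. Shared single-copy bases have mean `mean_depth`; bases
#' private to strain A have mean `mean_depth * titer_a`; CNV bases have mean
#' `mean_depth * (titer_a * copies_a + (1 - titer_a) * copies_b) / copies_a`
#' (reads are split evenly across the `copies_a` reference copies).
#'
#' @param pair A `strain_pair` from [make_strain_pair()], or its truth tibble
#'   (in which case `backbone_length` must be supplied).
#' @param titer_a Mixture fraction of strain A; defaults to the spec's value.
#' @param cov A [coverage_sim_spec()].
#' @param backbone_length Required when `pair` is a bare truth tibble.
#' @return A tibble of class `depth_track` with columns `pos`, `depth` and
#'   attributes `genome_id` and `truth`.
#' @export
simulate_mixture_depth <- function(pair, titer_a = NULL,
                                   cov = coverage_sim_spec(),
                                   backbone_length = NULL) {
  if (inherits(pair, "strain_pair")) {
    truth <- pair$truth
    L <- pair$spec$backbone_length
    if (is.null(titer_a)) titer_a <- pair$spec$titer_a
  } else {
    truth <- as_tibble(pair)
    L <- check_count(backbone_length, "backbone_length", min = 1)
    if (is.null(titer_a)) abort("`titer_a` required with a bare truth table")
  }
  check_prob(titer_a, "titer_a")
  mult <- rep(1, L)
  for (i in seq_len(nrow(truth))) {
    span <- truth$start[i]:(truth$end[i] - 1L)
    ca <- truth$copies_a[i]
    cb <- truth$copies_b[i]
    mult[span] <- (titer_a * ca + (1 - titer_a) * cb) / ca
  }
  set.seed(cov$seed)
  depth <- rpois(L, cov$mean_depth * mult)
  out <- tibble(pos = seq_len(L), depth = depth)
  attr(out, "genome_id") <- "strain_a"
  attr(out, "truth") <- truth
  class(out) <- c("depth_track", class(out))
  out
}

#' Specify a suppressor backcross simulation
#'
#' Emulates an introgression design: a donor line fixed for alternate alleles
#' genome-wide and homozygous for a dominant MK suppressor `S` is crossed into
#' a recurrent line, and female offspring are repeatedly backcrossed to
#' recurrent-line males. Sampled females from the final backcross generation
#' are genotyped at all sites; a female is phenotyped `MKS` (suppressed) if
#' she carries at least one `S` allele and `MK` otherwise.
#'
#' @param n_contigs Number of contigs.
#' @param sites_per_contig SNP sites per contig (positions drawn uniformly).
#' @param contig_length Contig length in bp.
#' @param suppressor_contig,suppressor_pos Location of the suppressor locus.
#' @param recomb_rate Expected crossovers per contig per meiosis.
#' @param n_lines_mk,n_lines_mks Number of sampled females per phenotype group.
#' @param n_backcrosses Number of backcross generations before sampling.
#' @param missing_rate Per-genotype missingness fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `backcross_sim_spec` list.
#' @export
backcross_sim_spec <- function(n_contigs = 3L, sites_per_contig = 500L,
                               contig_length = 1e7, suppressor_contig = 1L,
                               suppressor_pos = 5e6, recomb_rate = 1,
                               n_lines_mk = 24L, n_lines_mks = 24L,
                               n_backcrosses = 2L, missing_rate = 0.02,
                               seed = 42L) {
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must be in [0, 1)")
  }
  if (suppressor_pos < 1 || suppressor_pos > contig_length) {
    abort("`suppressor_pos` must lie within [1, contig_length]")
  }
  if (recomb_rate < 0) abort("`recomb_rate` must be >= 0")
  structure(
    list(
      n_contigs = check_count(n_contigs, "n_contigs", 1),
      sites_per_contig = check_count(sites_per_contig, "sites_per_contig", 1),
      contig_length = contig_length,
      suppressor_contig = check_count(suppressor_contig, "suppressor_contig", 1),
      suppressor_pos = suppressor_pos,
      recomb_rate = recomb_rate,
      n_lines_mk = check_count(n_lines_mk, "n_lines_mk", 0),
      n_lines_mks = check_count(n_lines_mks, "n_lines_mks", 0),
      n_backcrosses = check_count(n_backcrosses, "n_backcrosses", 1),
      missing_rate = missing_rate,
      seed = as.integer(seed)
    ),
    class = "backcross_sim_spec"
  )
}

# One female meiosis over one contig: given logical donor-ancestry at the
# query positions on the donor-bearing homolog (other homolog is recurrent
# everywhere), return donor ancestry of the transmitted gamete at `pos`.
meiose_contig <- function(donor_at_pos, pos, L, recomb_rate) {
  n_x <- rpois(1L, recomb_rate)
  use_first <- runif(1L) < 0.5
  if (n_x == 0L) {
    if (use_first) donor_at_pos else rep(FALSE, length(pos))
  } else {
    breaks <- sort(runif(n_x, 0, L))
    seg <- findInterval(pos, breaks) # 0..n_x
    on_first <- (seg %% 2L == 0L) == use_first
    donor_at_pos & on_first
  }
}

#' Simulate backcross SNP genotypes segregating a dominant suppressor
#'
#' Simulates independent maternal lineages through the backcross design in
#' [backcross_sim_spec()] and samples females until the requested number of
#' `MK` (no suppressor) and `MKS` (>= 1 `S` allele) individuals is reached.
#' Genotypes are coded 0/1/2 copies of the donor (alternate) allele; after
#' any backcross the donor allele can only be heterozygous, so codes are 0/1
#' with `NA` for missing calls.
#'
#' @param spec A [backcross_sim_spec()].
#' @return A [genotype_matrix()] whose `samples` tibble carries `phenotype`
#'   (`MK`/`MKS`), with attribute `truth` = `list(contig, pos)` giving the
#'   suppressor locus.
#' @export
simulate_backcross_genotypes <- function(spec = backcross_sim_spec()) {
  stopifnot(inherits(spec, "backcross_sim_spec"))
  if (spec$n_lines_mk + spec$n_lines_mks == 0L) {
    abort("at least one line must be requested")
  }
  set.seed(spec$seed)
  L <- spec$contig_length
  sites <- purrr::map(seq_len(spec$n_contigs), function(ct) {
    tibble(
      contig = sprintf("contig_%02d", ct),
      pos = sort(sample.int(L, spec$sites_per_contig))
    )
  }) |> bind_rows()
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, nrow(sites), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1))
  sites <- mutate(sites, ref = ref, alt = alt)

  contig_ids <- unique(sites$contig)
  supp_contig <- contig_ids[spec$suppressor_contig]
  # query positions per contig: SNP sites plus the suppressor locus
  qpos <- purrr::map(contig_ids, function(ct) sites$pos[sites$contig == ct])
  supp_idx_extra <- spec$suppressor_contig

  sim_line <- function() {
    carries_s <- FALSE
    geno <- vector("list", length(contig_ids))
    for (ci in seq_along(contig_ids)) {
      pos <- qpos[[ci]]
      track_supp <- ci == supp_idx_extra
      pq <- if (track_supp) c(pos, spec$suppressor_pos) else pos
      donor <- rep(TRUE, length(pq)) # F1 donor-bearing homolog
      for (bc in seq_len(spec$n_backcrosses)) {
        donor <- meiose_contig(donor, pq, L, spec$recomb_rate)
      }
      if (track_supp) {
        carries_s <- donor[length(pq)]
        donor <- donor[-length(pq)]
      }
      geno[[ci]] <- as.integer(donor) # het where maternal homolog is donor
    }
    list(geno = unlist(geno), mks = carries_s)
  }

  want_mk <- spec$n_lines_mk
  want_mks <- spec$n_lines_mks
  got <- list()
  pheno <- character()
  tries <- 0L
  max_tries <- 200L * (want_mk + want_mks)
  while ((sum(pheno == "MK") < want_mk || sum(pheno == "MKS") < want_mks) &&
         tries < max_tries) {
    tries <- tries + 1L
    ln <- sim_line()
    ph <- if (ln$mks) "MKS" else "MK"
    if ((ph == "MK" && sum(pheno == "MK") < want_mk) ||
        (ph == "MKS" && sum(pheno == "MKS") < want_mks)) {
      got[[length(got) + 1L]] <- ln$geno
      pheno <- c(pheno, ph)
    }
  }
  if (sum(pheno == "MK") < want_mk || sum(pheno == "MKS") < want_mks) {
    abort("failed to sample the requested phenotype groups; check recomb_rate")
  }
  geno <- do.call(rbind, got)
  if (spec$missing_rate > 0) {
    drop <- runif(length(geno)) < spec$missing_rate
    geno[drop] <- NA_integer_
  }
  samples <- tibble(
    sample_id = sprintf("line_%03d", seq_len(nrow(geno))),
    line = "synthetic",
    phenotype = pheno
  )
  rownames(geno) <- samples$sample_id
  gm <- genotype_matrix(geno, sites, samples)
  attr(gm, "truth") <- list(contig = supp_contig, pos = spec$suppressor_pos)
  gm
}
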