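#' Ungapped percent identity between two sequences
#'
#' Positional identity over the compared span, reported at 0.1% resolution
#' (the resolution at which locus identities such as wmk homologies are
#' conventionally quoted). Sequences must already be aligned: unequal spans
#' raise an error instructing the caller to pre-align.
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param range Optional `c(start, end)` 1-based inclusive range compared in
#'   both sequences.
#' @return Percent identity, rounded to 0.1.
#' @examples
#' percent_identity("ACGTACGTAC", "ACGTACGTAT") # 90
#' @export
percent_identity <- function(seq_a, seq_b, range = NULL) {
  a <- toupper(seq_a)
  b <- toupper(seq_b)
  if (nchar(a) == 0L || nchar(b) == 0L) abort("sequences must be non-empty")
  if (!is.null(range)) {
    if (nchar(a) < range[2] || nchar(b) < range[2]) {
      abort("both sequences must cover `range`")
    }
    a <- substr(a, range[1], range[2])
    b <- substr(b, range[1], range[2])
  }
  if (nchar(a) != nchar(b)) {
    abort("compared spans differ in length; pre-align the sequences first")
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  round(100 * mean(ca == cb), 1)
}

#' Premature-stop (pseudogene) check of an open reading frame
#'
#' Translates the sequence in the given frame with the standard genetic code
#' and reports the first in-frame stop codon. A stop whose codon index
#' precedes 90% of the expected ORF length (the full sequence) marks the copy
#' as pseudogenized; the 1-based nucleotide offset of the next ATG after the
#' premature stop is reported as the closest potential re-initiation site.
#'
#' @param seq Nucleotide string (A/C/G/T plus IUPAC N).
#' @param frame_start 1-based frame offset (1, 2 or 3).
#' @return A list: `premature_stop_codon_index` (NA if none),
#'   `next_start_codon_offset` (1-based nt position of the next ATG after the
#'   premature stop; NA if none), `intact` (no premature stop).
#' @export
pseudogene_check <- function(seq, frame_start = 1L) {
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) abort("sequence may contain only A/C/G/T/N")
  if (nchar(s) < 3L) abort("sequence must be at least one codon long")
  coding <- substr(s, frame_start, nchar(s))
  n_codons <- nchar(coding) %/% 3L
  coding <- substr(coding, 1L, 3L * n_codons)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(coding),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
  stops <- gregexpr("\\*", aa)[[1]]
  first_stop <- if (stops[1] == -1L) NA_integer_ else as.integer(stops[1])
  premature <- !is.na(first_stop) && first_stop < 0.9 * n_codons
  next_atg <- NA_integer_
  if (premature) {
    stop_end_nt <- frame_start - 1L + first_stop * 3L
    hit <- regexpr("ATG", substr(s, stop_end_nt + 1L, nchar(s)))
    if (hit != -1L) next_atg <- as.integer(hit) + stop_end_nt
  }
  list(
    premature_stop_codon_index = if (premature) first_stop else NA_integer_,
    first_stop_codon_index = first_stop,
    next_start_codon_offset = next_atg,
    intact = !premature
  )
}

#' Predict collapsed copies in a fragmented assembly
#'
#' When a reference assembly carries `k` identical copies of a locus but a
#' fragmented mixed assembly shows only `m < k`, the assembler has likely
#' collapsed identical copies into one contig; the predicted true count is
#' then `k`. Otherwise the observed mixed count stands.
#'
#' @param reference_copy_count,mixed_copy_count Non-negative counts of
#'   identical copies in each assembly.
#' @return A list with `predicted_true_count` and logical `collapsed`.
#' @examples
#' predict_collapsed_copies(2, 1) # predicted 2, collapsed
#' @export
predict_collapsed_copies <- function(reference_copy_count, mixed_copy_count) {
  k <- check_count(reference_copy_count, "reference_copy_count", 0)
  m <- check_count(mixed_copy_count, "mixed_copy_count", 0)
  if (m < k) {
    list(predicted_true_count = k, collapsed = TRUE)
  } else {
    list(predicted_true_count = m, collapsed = FALSE)
  }
}

# Fraction of a hit interval inside any private region (same contig when a
# contig column is present in `private_regions`).
private_overlap_fraction <- function(contig, start, end, private_regions) {
  if (nrow(private_regions) == 0L) return(0)
  pr <- private_regions
  if ("contig" %in% names(pr) && !is.na(contig)) {
    pr <- pr[pr$contig == contig, , drop = FALSE]
  }
  if (nrow(pr) == 0L) return(0)
  ov <- sum(pmax(0, pmin(end + 1, pr$end) - pmax(start, pr$start)))
  ov / (end - start + 1)
}

hits_identical <- function(h1, h2, identity_tol) {
  if (!is.na(h1$sequence) && !is.na(h2$sequence)) {
    return(toupper(h1$sequence) == toupper(h2$sequence))
  }
  abs(h1$identity_pct - h2$identity_pct) <= identity_tol &&
    h1$qstart == h2$qstart && h1$qend == h2$qend
}

#' Assign candidate loci to the CI or MK strain
#'
#' Applies ordered evidence rules to homolog hits against a single-strain
#' reference assembly and a mixed (doubly infected) assembly: (1) a reference
#' hit mostly inside a region private to the reference strain belongs to the
#' CI strain; a marginal (1-49%) overlap is left unresolved; (2) a mixed hit
#' identical to a reference hit is the reference (CI) strain's copy observed
#' again in the mixed assembly; (3) a mixed hit with no identical reference
#' counterpart is unique to the second (MK) strain; (4) a reference hit
#' outside private regions that is present identically in the mixed assembly
#' is shared evidence only; anything else is unresolved. Assignments are
#' invariant to input row order.
#'
#' @param hits_reference,hits_mixed Hit tables (see [read_hit_table()]) with
#'   columns `query`, `contig`, `start`, `end`, `identity_pct`, `qstart`,
#'   `qend` and optionally `sequence`.
#' @param private_regions Intervals (1-based inclusive-start exclusive-end,
#'   `start`/`end` and optionally `contig`) private to the reference strain,
#'   on reference coordinates.
#' @param identity_tol Identity percentage tolerance for calling two hits of
#'   the same query "identical" when sequences are absent (default exact).
#' @param min_overlap Minimum fraction of a hit inside a private region for
#'   membership.
#' @param reference_length Optional reference length; hits beyond it raise a
#'   coordinate-system error.
#' @return A tibble with one row per hit: `assembly`, `query`, `contig`,
#'   `start`, `end`, `assigned_strain` (`ci_strain`/`mk_strain`/`shared`/
#'   `unresolved`) and `evidence` (comma-joined rule tags).
#' @export
assign_hits <- function(hits_reference, hits_mixed, private_regions,
                        identity_tol = 0, min_overlap = 0.5,
                        reference_length = NULL) {
  norm <- function(h, assembly) {
    h <- as_tibble(h)
    if (!"sequence" %in% names(h)) h$sequence <- NA_character_
    if (!"contig" %in% names(h)) h$contig <- NA_character_
    need <- c("query", "start", "end", "identity_pct", "qstart", "qend")
    if (!all(need %in% names(h))) {
      abort(paste("hit table needs columns:", paste(need, collapse = ", ")))
    }
    if (any(h$start >= h$end)) abort("hit intervals need start < end")
    mutate(h, assembly = assembly)
  }
  ref <- norm(hits_reference, "reference")
  mix <- norm(hits_mixed, "mixed")
  if (!is.null(reference_length) && any(ref$end > reference_length)) {
    abort("reference hit beyond reference length: coordinate-system mismatch")
  }
  pr <- check_intervals(private_regions, Inf, "private_regions")

  ref_has_match <- vapply(seq_len(nrow(ref)), function(i) {
    any(vapply(which(mix$query == ref$query[i]), function(j) {
      hits_identical(ref[i, ], mix[j, ], identity_tol)
    }, logical(1)))
  }, logical(1))
  mix_counterpart <- vapply(seq_len(nrow(mix)), function(j) {
    any(vapply(which(ref$query == mix$query[j]), function(i) {
      hits_identical(ref[i, ], mix[j, ], identity_tol)
    }, logical(1)))
  }, logical(1))

  ref_assign <- purrr::map(seq_len(nrow(ref)), function(i) {
    frac <- private_overlap_fraction(ref$contig[i], ref$start[i], ref$end[i], pr)
    if (frac >= min_overlap) {
      list(strain = "ci_strain", evidence = "private_region_membership")
    } else if (frac > 0) {
      list(strain = "unresolved", evidence = "private_region_membership")
    } else if (ref_has_match[i]) {
      list(strain = "shared", evidence = "identity_class")
    } else {
      list(strain = "unresolved", evidence = "identity_class")
    }
  })
  mix_assign <- purrr::map(seq_len(nrow(mix)), function(j) {
    if (mix_counterpart[j]) {
      list(strain = "ci_strain", evidence = "identity_class")
    } else {
      list(strain = "mk_strain", evidence = "unique_copy")
    }
  })
  out <- bind_rows(
    mutate(ref,
           assigned_strain = map_chr(ref_assign, "strain"),
           evidence = map_chr(ref_assign, "evidence")),
    mutate(mix,
           assigned_strain = map_chr(mix_assign, "strain"),
           evidence = map_chr(mix_assign, "evidence"))
  )
  out |>
    select("assembly", "query", "contig", "start", "end",
           "identity_pct", "assigned_strain", "evidence") |>
    arrange(.data$assembly, .data$query, .data$start)
}
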