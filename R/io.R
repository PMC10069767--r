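# Plain-text interchange: depth tracks as 2/3-column TSV, intervals as
# 3-column BED (coordinates convert between the package's 1-based
# inclusive-start/exclusive-end convention and BED's 0-based half-open one),
# genotypes as a minimal GT-only VCF plus a samples TSV.

#' Read a per-base depth track from TSV
#'
#' Accepts 2 columns (`pos`, `depth`) or 3 (`genome_id`, `pos`, `depth`),
#' with or without a header.
#'
#' @param path File path.
#' @return A `depth_track` tibble with columns `pos`, `depth`.
#' @export
read_depth_track <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("pos", first, ignore.case = TRUE)
  raw <- readr::read_tsv(path, col_names = has_header,
                         show_col_types = FALSE, progress = FALSE)
  if (!has_header) {
    names(raw) <- if (ncol(raw) == 3L) c("genome_id", "pos", "depth") else
      c("pos", "depth")
  }
  gid <- if ("genome_id" %in% names(raw)) raw$genome_id[1] else NA_character_
  out <- raw |>
    select("pos", "depth") |>
    arrange(.data$pos)
  attr(out, "genome_id") <- gid
  class(out) <- c("depth_track", class(out))
  out
}

#' Write a depth track as TSV
#' @param track Data frame with `pos`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  readr::write_tsv(as_tibble(track)[c("pos", "depth")], path, progress = FALSE)
  invisible(path)
}

#' Write a window track as TSV
#' @param wt A `window_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_track <- function(wt, path) {
  readr::write_tsv(
    as_tibble(wt)[c("start", "end", "raw_norm_depth", "capped_norm_depth")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Write intervals as 3-column BED
#'
#' Converts from 1-based inclusive starts to BED's 0-based half-open
#' convention. `end_inclusive = TRUE` treats the input `end` as inclusive
#' (region calls, sweep intervals); the default treats it as exclusive
#' (truth tables, private-region annotations).
#'
#' @param intervals Data frame with `start`, `end` and optionally `contig`
#'   and a `name`-able column.
#' @param path Output path.
#' @param contig Contig name used when the data lack a `contig` column.
#' @param name_col Optional column written as the BED name field.
#' @param end_inclusive Whether `end` is inclusive.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, contig = "genome",
                      name_col = NULL, end_inclusive = FALSE) {
  iv <- as_tibble(intervals)
  bed <- tibble(
    chrom = if ("contig" %in% names(iv)) iv$contig else contig,
    chromStart = as.integer(iv$start - 1L),
    chromEnd = as.integer(if (end_inclusive) iv$end else iv$end - 1L)
  )
  if (!is.null(name_col)) bed$name <- iv[[name_col]]
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a 3+ column BED file into 1-based intervals
#' @param path File path.
#' @return Tibble with `contig`, `start` (1-based inclusive), `end`
#'   (exclusive) and `name` when present.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  out <- tibble(
    contig = raw[[1]],
    start = raw[[2]] + 1L,
    end = raw[[3]] + 1L
  )
  if (ncol(raw) >= 4L) out$name <- raw[[4]]
  out
}

#' Write genotypes as a minimal GT-only VCF plus a samples TSV
#'
#' The VCF carries only the GT FORMAT field with unphased diploid calls
#' (`./.` for missing); sample metadata (line, phenotype) go to a sidecar
#' TSV.
#'
#' @param gm A [genotype_matrix()].
#' @param vcf_path,samples_path Output paths.
#' @return `vcf_path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, vcf_path, samples_path = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(gm$geno), ncol = ncol(gm$geno))
  ok <- !is.na(gm$geno)
  gt[ok] <- gt_code[as.character(gm$geno[ok])]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mkduet",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples$sample_id), collapse = "\t")
  )
  ref <- if ("ref" %in% names(gm$sites)) gm$sites$ref else "A"
  alt <- if ("alt" %in% names(gm$sites)) gm$sites$alt else "T"
  body <- paste(
    gm$sites$contig, gm$sites$pos, ".", ref, alt, ".", "PASS", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  readr::write_lines(c(header, body), vcf_path)
  if (!is.null(samples_path)) {
    readr::write_tsv(gm$samples, samples_path, progress = FALSE)
  }
  invisible(vcf_path)
}

#' Read a biallelic VCF and samples TSV into a genotype matrix
#'
#' Parses genotypes with \pkg{vcfR}; multi-allelic sites are rejected.
#'
#' @param vcf_path Path to a VCF (GT field required).
#' @param samples_path Optional samples TSV with `sample_id` and metadata
#'   columns; defaults to all samples with unknown phenotype.
#' @return A [genotype_matrix()].
#' @export
read_genotype_vcf <- function(vcf_path, samples_path = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) {
    abort("multi-allelic sites are not supported; split or filter them first")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", g), "/"), function(a) {
             sum(a == "1")
           }, integer(1)))
  }
  geno <- apply(gt, 1, count_alt) # samples x sites
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1L)
  storage.mode(geno) <- "integer"
  sites <- tibble(
    contig = vcfR::getCHROM(v),
    pos = as.integer(vcfR::getPOS(v)),
    ref = vcfR::getREF(v),
    alt = alt
  )
  samples <- if (!is.null(samples_path)) {
    readr::read_tsv(samples_path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble(sample_id = colnames(gt), line = NA_character_,
           phenotype = NA_character_)
  }
  samples <- samples[match(colnames(gt), samples$sample_id), ]
  rownames(geno) <- colnames(gt)
  genotype_matrix(geno, sites, samples)
}

#' Read a 12-column tabular homolog hit table
#'
#' The conventional 12-column tabular search output (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore)
#' is renamed to the package's hit-table columns; subject strand is inferred
#' from `sstart > send`.
#'
#' @param path File path (no header).
#' @return A tibble with `query`, `contig`, `identity_pct`, `qstart`,
#'   `qend`, `start`, `end`, `strand`, `evalue`, `bitscore`.
#' @export
read_hit_table <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                  "bitscore"),
    show_col_types = FALSE, progress = FALSE
  )
  raw |>
    mutate(
      strand = if_else(.data$sstart <= .data$send, "+", "-"),
      start = pmin(.data$sstart, .data$send),
      end = pmax(.data$sstart, .data$send)
    ) |>
    select(query = "qseqid", contig = "sseqid", identity_pct = "pident",
           "qstart", "qend", "start", "end", "strand", "evalue", "bitscore")
}

#' Write a strain pair as FASTA
#' @param pair A `strain_pair` with materialised sequences.
#' @param path Output FASTA path.
#' @param names Sequence names.
#' @return `path`, invisibly.
#' @export
write_strain_fasta <- function(pair, path,
                               names = c("strain_a", "strain_b")) {
  if (is.null(pair$genome_a)) {
    abort("pair has no sequences; rerun make_strain_pair(sequences = TRUE)")
  }
  seqs <- Biostrings::DNAStringSet(c(pair$genome_a, pair$genome_b))
  names(seqs) <- names
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
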