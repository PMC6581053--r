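#' Default RNA-editing thresholds
#'
#' @param min_coverage Minimum reads at the site in a supporting sample.
#' @param min_alt_reads Minimum alternate (edited) reads in a supporting
#'   sample.
#' @param min_alt_fraction Minimum alternate fraction in a supporting
#'   sample.
#' @param max_unlabeled_alt Maximum alternate reads tolerated in any
#'   matched unlabeled sample (0: a single unlabeled alternate read vetoes
#'   the site as a genomic-variant mimic).
#' @param min_samples Minimum number of supporting labeled samples.
#' @return Named list.
#' @export
edit_thresholds <- function(min_coverage = 10, min_alt_reads = 3,
                            min_alt_fraction = 0.1, max_unlabeled_alt = 0,
                            min_samples = 2) {
  list(min_coverage = min_coverage, min_alt_reads = min_alt_reads,
       min_alt_fraction = min_alt_fraction,
       max_unlabeled_alt = max_unlabeled_alt, min_samples = min_samples)
}

#' Call putative A-to-G RNA-editing sites
#'
#' Scans pileup base counts restricted to annotated coding exons for the
#' canonical ADAR signature: A-to-G on the transcribed strand, observed as
#' T-to-C in reference coordinates for minus-strand genes. A site is called
#' when it passes per-sample thresholds in at least `min_samples` labeled
#' samples and no unlabeled sample shows alternate reads above
#' `max_unlabeled_alt` (sites altered in the unlabeled sort are genomic
#' variants, not edits). Mismatches other than the strand-resolved A-to-G
#' are reported separately and never called.
#'
#' @param pileups Tibble `chrom`, `pos`, `ref`, `sample`, `A`, `C`, `G`,
#'   `T`.
#' @param ann A `genome_annotation` (CDS intervals and gene strands).
#' @param thresholds From [edit_thresholds()].
#' @return List: `calls` (per called site: `chrom`, `pos`, `gene_id`,
#'   `strand`, `ref`, `alt`, `supporting_samples` list-column,
#'   `n_supporting`), `other_mismatch` (sites whose alternate is not the
#'   canonical change), `n_outside_cds` (skipped sites).
#' @export
call_edits <- function(pileups, ann, thresholds = edit_thresholds()) {
  th <- thresholds
  cds <- ann$cds |>
    dplyr::left_join(dplyr::select(ann$genes, "gene_id", "chrom", "strand"),
                     by = "gene_id")
  sites <- dplyr::distinct(pileups, .data$chrom, .data$pos, .data$ref)
  hit <- dplyr::inner_join(sites, cds, by = "chrom",
                           relationship = "many-to-many") |>
    dplyr::filter(.data$pos >= .data$start, .data$pos < .data$end) |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$gene_id,
                    .data$strand)
  n_outside <- nrow(dplyr::anti_join(sites, hit, by = c("chrom", "pos")))
  labeled <- parse_sample_key(unique(pileups$sample))
  pl <- dplyr::left_join(pileups,
                         dplyr::select(labeled, "sample", "labeled"),
                         by = "sample")
  per_site <- dplyr::inner_join(pl, hit, by = c("chrom", "pos", "ref"))
  canon_alt <- function(strand) ifelse(strand == "+", "G", "C")
  canon_ref <- function(strand) ifelse(strand == "+", "A", "T")
  per_site <- per_site |>
    dplyr::mutate(
      coverage = .data$A + .data$C + .data$G + .data$`T`,
      alt_base = canon_alt(.data$strand),
      alt_n = dplyr::case_when(.data$strand == "+" ~ .data$G,
                               TRUE ~ .data$C),
      canonical = .data$ref == canon_ref(.data$strand))
  # non-canonical reference base (or non A->G alternate dominating): report,
  # never call
  other <- per_site |>
    dplyr::filter(!.data$canonical) |>
    dplyr::distinct(.data$chrom, .data$pos, .data$gene_id, .data$ref)
  res <- per_site |>
    dplyr::filter(.data$canonical) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$gene_id, .data$strand,
                    .data$ref, .data$alt_base) |>
    dplyr::summarise(
      supporting_samples = list(.data$sample[
        .data$labeled & .data$coverage >= th$min_coverage &
          .data$alt_n >= th$min_alt_reads &
          .data$alt_n / pmax(1, .data$coverage) >= th$min_alt_fraction]),
      unlabeled_alt = sum(.data$alt_n[!.data$labeled]),
      .groups = "drop") |>
    dplyr::mutate(n_supporting = lengths(.data$supporting_samples)) |>
    dplyr::filter(.data$n_supporting >= th$min_samples,
                  .data$unlabeled_alt <= th$max_unlabeled_alt) |>
    dplyr::rename(alt = "alt_base") |>
    dplyr::select("chrom", "pos", "gene_id", "strand", "ref", "alt",
                  "supporting_samples", "n_supporting")
  list(calls = res, other_mismatch = other, n_outside_cds = n_outside)
}

#' Annotate the coding consequence of an edit
#'
#' Recomputes the affected codon with the edited base (G on the coding
#' strand) under the standard genetic code. For premature stops, reports
#' how many amino acids of the original protein are lost (the edited codon
#' and everything downstream of it).
#'
#' @param calls Call tibble from [call_edits()].
#' @param ann A `genome_annotation`.
#' @param cds_seqs Named character vector (or `Biostrings::DNAStringSet`) of
#'   spliced CDS sequences, coding strand 5'->3', one per gene.
#' @return `calls` with `cds_pos` (0-based in the spliced CDS), `codon`,
#'   `codon_edited`, `aa_ref`, `aa_alt`, `consequence`
#'   (`synonymous` / `missense` / `stop_gained`), and `truncated_aa`
#'   (`NA` unless `stop_gained`).
#' @export
annotate_consequence <- function(calls, ann, cds_seqs) {
  cds_seqs <- stats::setNames(as.character(cds_seqs), names(cds_seqs))
  code <- Biostrings::GENETIC_CODE
  out <- purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    cpos <- cds_position(ann, call$gene_id, call$pos)
    seq <- cds_seqs[[call$gene_id]]
    if (is.na(cpos) || is.null(seq)) {
      return(dplyr::mutate(call, cds_pos = NA_integer_, codon = NA_character_,
                           codon_edited = NA_character_,
                           aa_ref = NA_character_, aa_alt = NA_character_,
                           consequence = NA_character_,
                           truncated_aa = NA_integer_))
    }
    n_codons <- nchar(seq) %/% 3
    if (nchar(seq) %% 3 != 0) {
      rlang::warn(paste0("CDS length of ", call$gene_id,
                         " is not a multiple of 3; partial codon skipped"))
    }
    ci <- cpos %/% 3
    if (ci >= n_codons) {
      return(dplyr::mutate(call, cds_pos = cpos, codon = NA_character_,
                           codon_edited = NA_character_,
                           aa_ref = NA_character_, aa_alt = NA_character_,
                           consequence = NA_character_,
                           truncated_aa = NA_integer_))
    }
    codon <- substr(seq, ci * 3 + 1, ci * 3 + 3)
    off <- cpos %% 3
    codon_ed <- codon
    # alt is recorded in reference coordinates; flip to the coding strand
    alt <- if ("alt" %in% names(call)) call$alt else "G"
    coding_alt <- if (call$strand == "+") alt else chartr("ACGT", "TGCA", alt)
    substr(codon_ed, off + 1, off + 1) <- coding_alt
    aa_ref <- code[[codon]]
    aa_alt <- code[[codon_ed]]
    # protein length excludes the terminal stop codon when present
    n_aa <- if (code[[substr(seq, (n_codons - 1) * 3 + 1, n_codons * 3)]] == "*") {
      n_codons - 1
    } else n_codons
    consequence <- if (aa_alt == aa_ref) "synonymous"
    else if (aa_alt == "*") "stop_gained" else "missense"
    dplyr::mutate(call, cds_pos = cpos, codon = codon,
                  codon_edited = codon_ed, aa_ref = aa_ref, aa_alt = aa_alt,
                  consequence = consequence,
                  truncated_aa = if (consequence == "stop_gained") {
                    n_aa - ci
                  } else NA_integer_)
  })
  out
}

# 0-based position within the spliced CDS (coding strand) of a genomic
# coordinate; NA when outside the CDS
cds_position <- function(ann, gene_id, pos) {
  cds <- ann$cds[ann$cds$gene_id == gene_id, ]
  if (nrow(cds) == 0) return(NA_integer_)
  cds <- dplyr::arrange(cds, .data$start)
  strand <- ann$genes$strand[ann$genes$gene_id == gene_id]
  inside <- which(pos >= cds$start & pos < cds$end)
  if (length(inside) == 0) return(NA_integer_)
  i <- inside[1]
  if (strand == "+") {
    before <- if (i > 1) sum(cds$end[seq_len(i - 1)] - cds$start[seq_len(i - 1)]) else 0L
    as.integer(before + pos - cds$start[i])
  } else {
    after <- if (i < nrow(cds)) {
      sum(cds$end[(i + 1):nrow(cds)] - cds$start[(i + 1):nrow(cds)])
    } else 0L
    as.integer(after + cds$end[i] - 1L - pos)
  }
}

#' Check support for a catalogue of known editing sites
#'
#' For each supplied site, totals coverage and alternate reads over
#' samples and assigns a verdict: `strong` when the alternate fraction
#' reaches `min_fraction` in at least `min_samples` samples, `weak` when
#' any alternate read exists, `none` otherwise (including zero coverage,
#' flagged).
#'
#' @param pileups Pileup tibble.
#' @param site_list Tibble `chrom`, `pos`, `ref`, `alt`.
#' @param min_fraction,min_samples Strong-support thresholds (defaults 0.1
#'   and 2).
#' @return Tibble per site: `chrom`, `pos`, `coverage`, `alt_reads`,
#'   `n_supporting_samples`, `verdict`, `no_coverage`.
#' @export
check_known_sites <- function(pileups, site_list, min_fraction = 0.1,
                              min_samples = 2) {
  purrr::map_dfr(seq_len(nrow(site_list)), function(i) {
    st <- site_list[i, ]
    pl <- dplyr::filter(pileups, .data$chrom == st$chrom,
                        .data$pos == st$pos)
    cov <- pl$A + pl$C + pl$G + pl$`T`
    alt <- pl[[st$alt]]
    strong_n <- sum(cov > 0 & alt / pmax(1, cov) >= min_fraction & alt > 0)
    verdict <- if (sum(cov) == 0) "none"
    else if (strong_n >= min_samples) "strong"
    else if (sum(alt) > 0) "weak" else "none"
    tibble::tibble(chrom = st$chrom, pos = st$pos, coverage = sum(cov),
                   alt_reads = sum(alt),
                   n_supporting_samples = strong_n, verdict = verdict,
                   no_coverage = sum(cov) == 0)
  })
}
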