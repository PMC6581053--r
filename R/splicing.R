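#' Classify observed splice junctions against the annotation
#'
#' Each junction (an intron interval, 0-based half-open) gets exactly one
#' label:
#' \itemize{
#'   \item `confirmed` — both splice sites match an annotated intron;
#'   \item `novel_internal` — unannotated but lying wholly within a single
#'     annotated transcript (an intron missing from the gene model);
#'   \item `extension` — within `flank` bp (default 500) of an annotated
#'     transcript boundary, a possible extension of an existing model;
#'   \item `novel_distal` — more than `flank` bp from every transcript, or
#'     spanning the boundaries of two or more transcripts (a possible
#'     unannotated gene).
#' }
#'
#' @param junctions Tibble `chrom`, `strand`, `donor`, `acceptor` (intron
#'   start and end, `donor < acceptor` in reference coordinates).
#' @param ann A `genome_annotation`.
#' @param flank The distance rule, in bp (default 500).
#' @return The input with a `class` column added.
#' @export
classify_introns <- function(junctions, ann, flank = 500) {
  known <- annotated_introns(ann)
  known_key <- paste(known$chrom, known$strand, known$start, known$end)
  tx <- ann$transcripts |>
    dplyr::left_join(dplyr::select(ann$genes, "gene_id", "chrom", "strand"),
                     by = "gene_id")
  classify_one <- function(chrom, strand, donor, acceptor) {
    if (paste(chrom, strand, donor, acceptor) %in% known_key) {
      return("confirmed")
    }
    t_ <- tx[tx$chrom == chrom, ]
    if (nrow(t_) == 0) return("novel_distal")
    within <- t_$start <= donor & acceptor <= t_$end
    if (any(within)) return("novel_internal")
    # transcripts whose body the junction overlaps at all
    overlaps <- t_$start < acceptor & donor < t_$end
    if (sum(overlaps) >= 2) return("novel_distal")
    gap <- pmax(t_$start - acceptor, donor - t_$end)  # <0 when overlapping
    if (min(gap) <= flank) return("extension")
    "novel_distal"
  }
  junctions |>
    dplyr::mutate(class = purrr::pmap_chr(
      list(.data$chrom, .data$strand, .data$donor, .data$acceptor),
      classify_one))
}

#' Detect and classify splice-leader sites
#'
#' A site is kept when its total SL1 + SL2 support reaches `min_support`
#' reads. Sites with at least `min_class_support` reads of \emph{both}
#' leaders are classified `both`; otherwise the majority leader wins
#' (`SL1-only` / `SL2-only`).
#'
#' @param sl Tibble with per-site columns `sl1` and `sl2` (read counts);
#'   other columns pass through.
#' @param min_support Minimum total reads to keep a site (default 2).
#' @param min_class_support Minimum minority-leader reads for `both`
#'   (default 2).
#' @return The kept sites with `sl_class` and `sl1_fraction` columns added.
#' @export
detect_sl_sites <- function(sl, min_support = 2, min_class_support = 2) {
  sl |>
    dplyr::filter(.data$sl1 + .data$sl2 >= min_support) |>
    dplyr::mutate(
      sl_class = dplyr::case_when(
        pmin(.data$sl1, .data$sl2) >= min_class_support ~ "both",
        .data$sl1 >= .data$sl2 ~ "SL1-only",
        TRUE ~ "SL2-only"),
      sl1_fraction = sl1_fraction(.data$sl1, .data$sl2))
}

#' SL1 usage fraction
#'
#' SL1 reads over total SL reads; `NA` when there is no support.
#'
#' @param sl1,sl2 Read counts (vectorized).
#' @return Numeric vector in `[0, 1]`.
#' @export
sl1_fraction <- function(sl1, sl2) {
  tot <- sl1 + sl2
  dplyr::if_else(tot > 0, sl1 / tot, NA_real_)
}

#' Gene-level SL1 fraction
#'
#' Pools all sites of a gene: count-weighted, i.e. total SL1 reads over
#' total SL reads.
#'
#' @param sites Site tibble with `gene_id`, `sl1`, `sl2`.
#' @return Tibble `gene_id`, `sl1`, `sl2`, `sl1_fraction`.
#' @export
gene_sl1_fraction <- function(sites) {
  sites |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(sl1 = sum(.data$sl1), sl2 = sum(.data$sl2),
                     .groups = "drop") |>
    dplyr::mutate(sl1_fraction = sl1_fraction(.data$sl1, .data$sl2))
}

#' SL class census
#'
#' @param sites Classified sites from [detect_sl_sites()].
#' @return Tibble `sl_class`, `n`, `pct` (percent of kept sites).
#' @export
sl_class_census <- function(sites) {
  sites |>
    dplyr::count(.data$sl_class) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n))
}

#' Differential exon usage between two groups
#'
#' For each exon, usage is the exon's reads against the rest of its gene's
#' reads; the two groups are compared with a Fisher exact test on the
#' summed 2x2 table (exon vs rest-of-gene x group), with BH correction
#' across the tested exons. The usage log2 fold change uses a pseudocount.
#' First-exon features can be flagged for alternative-start analyses via
#' the optional `first_exon` column, which passes through.
#'
#' @param exon_counts Tibble `gene_id`, `exon_id`, `group` and `count`
#'   (summed over the samples of each group), with exactly two groups, plus
#'   optional passthrough columns.
#' @param gene_counts Tibble `gene_id`, `group`, `count` of whole-gene
#'   totals.
#' @param pseudocount For the usage ratio (default 0.5).
#' @return Tibble per exon: `gene_id`, `exon_id`, usage in both groups,
#'   `log2fc`, `pvalue`, `padj`.
#' @export
exon_usage_test <- function(exon_counts, gene_counts, pseudocount = 0.5) {
  groups <- sort(unique(exon_counts$group))
  stopifnot(length(groups) == 2)
  wide <- exon_counts |>
    dplyr::select("gene_id", "exon_id", "group", "count") |>
    tidyr::pivot_wider(names_from = "group", values_from = "count",
                       values_fill = 0L) |>
    dplyr::rename(exon_a = dplyr::all_of(groups[1]),
                  exon_b = dplyr::all_of(groups[2]))
  gw <- gene_counts |>
    tidyr::pivot_wider(names_from = "group", values_from = "count",
                       values_fill = 0L) |>
    dplyr::rename(gene_a = dplyr::all_of(groups[1]),
                  gene_b = dplyr::all_of(groups[2]))
  tab <- dplyr::left_join(wide, gw, by = "gene_id") |>
    dplyr::mutate(rest_a = .data$gene_a - .data$exon_a,
                  rest_b = .data$gene_b - .data$exon_b)
  if (any(tab$rest_a < 0 | tab$rest_b < 0)) {
    rlang::abort("gene count smaller than exon count")
  }
  res <- tab |>
    dplyr::mutate(
      pvalue = purrr::pmap_dbl(
        list(.data$exon_a, .data$rest_a, .data$exon_b, .data$rest_b),
        function(ea, ra, eb, rb) {
          stats::fisher.test(matrix(c(ea, ra, eb, rb), 2))$p.value
        }),
      usage_a = .data$exon_a / pmax(1, .data$rest_a),
      usage_b = .data$exon_b / pmax(1, .data$rest_b),
      log2fc = log2(((.data$exon_a + pseudocount) / (.data$rest_a + pseudocount)) /
                      ((.data$exon_b + pseudocount) / (.data$rest_b + pseudocount))),
      padj = stats::p.adjust(.data$pvalue, "BH"))
  dplyr::select(res, "gene_id", "exon_id", "exon_a", "exon_b", "usage_a",
                "usage_b", "log2fc", "pvalue", "padj")
}
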