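#' Assign ChIP-seq peaks to genes through promoter windows
#'
#' A TF is assigned to a gene when any of its peaks overlaps the gene's
#' strand-aware promoter window (default `[tss - 1000, tss + 200)` in
#' transcription direction). One peak may serve several genes. Peaks on
#' chromosomes absent from the annotation are skipped with a warning.
#'
#' @param peaks Tibble `tf`, `chrom`, `start`, `end` (0-based half-open).
#' @param ann A `genome_annotation`.
#' @param upstream,downstream Promoter window extent (bp).
#' @return Tibble `gene_id`, `tf` (distinct pairs).
#' @export
assign_peaks_to_genes <- function(peaks, ann, upstream = 1000,
                                  downstream = 200) {
  proms <- gene_promoters(ann, upstream, downstream)
  unknown <- !peaks$chrom %in% proms$chrom
  if (any(unknown)) {
    rlang::warn(paste0(sum(unknown), " peak(s) on unknown chromosome skipped"))
    peaks <- peaks[!unknown, ]
  }
  peaks |>
    dplyr::rename(peak_start = "start", peak_end = "end") |>
    dplyr::inner_join(dplyr::select(proms, "gene_id", "chrom", "prom_start",
                                    "prom_end"),
                      by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(.data$peak_start < .data$prom_end,
                  .data$prom_start < .data$peak_end) |>
    dplyr::distinct(.data$gene_id, .data$tf)
}

#' Peak enrichment of DE genes for one TF
#'
#' Two-sided Fisher exact test on the 2x2 table of {DE, non-DE} x {has
#' peak, no peak}, comparing the fraction of DE genes with a promoter peak
#' of the TF to the fraction among non-DE background genes. Direction is
#' read off the odds ratio; the heatmap value is `-log10(p)` for enrichment
#' and `+log10(p)` (negative) for depletion. An optional seeded permutation
#' p-value (random DE-sized gene draws) cross-checks the parametric choice.
#'
#' @param de_genes,background_genes Disjoint gene-id vectors.
#' @param tf_target_genes Genes with a peak for this TF.
#' @param n_perm Permutation draws (0 to skip).
#' @param seed Seed for the permutation draw.
#' @return One-row tibble: `a`, `b`, `c`, `d`, `pvalue`, `direction`,
#'   `heat`, `significant`, `perm_pvalue`.
#' @export
enrichment_test <- function(de_genes, background_genes, tf_target_genes,
                            n_perm = 0, seed = 1) {
  if (length(de_genes) == 0) {
    return(tibble::tibble(a = NA_integer_, b = NA_integer_, c = NA_integer_,
                          d = NA_integer_, pvalue = NA_real_,
                          direction = NA_character_, heat = NA_real_,
                          significant = NA, perm_pvalue = NA_real_))
  }
  a <- sum(de_genes %in% tf_target_genes)
  b <- length(de_genes) - a
  c_ <- sum(background_genes %in% tf_target_genes)
  d <- length(background_genes) - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  ht <- stats::fisher.test(tab)
  enriched <- (a / max(1, a + b)) >= (c_ / max(1, c_ + d))
  perm_p <- NA_real_
  if (n_perm > 0) {
    pool <- c(de_genes, background_genes)
    obs <- a
    hits <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        sum(sample(pool, length(de_genes)) %in% tf_target_genes)
      }, numeric(1))
    })
    tail_hi <- (sum(hits >= obs) + 1) / (n_perm + 1)
    tail_lo <- (sum(hits <= obs) + 1) / (n_perm + 1)
    perm_p <- min(1, 2 * min(tail_hi, tail_lo))
  }
  tibble::tibble(
    a = a, b = b, c = c_, d = d, pvalue = ht$p.value,
    direction = if (enriched) "enriched" else "depleted",
    heat = if (enriched) -log10(ht$p.value) else log10(ht$p.value),
    significant = ht$p.value <= 0.01, perm_pvalue = perm_p)
}

#' Enrichment grid over TFs, tissues and times
#'
#' Runs [enrichment_test()] for every (TF, tissue, time) cell: DE genes are
#' the specificity calls for that tissue/time, the background is all
#' analyzed (robust) genes not DE there.
#'
#' @param calls Specificity calls ([call_tissue_specific()] output).
#' @param analyzed_genes Character vector of robust genes.
#' @param gene_tfs Gene-to-TF map from [assign_peaks_to_genes()].
#' @param tfs TFs to test (default: all in `gene_tfs`).
#' @return Tibble with `tf`, `tissue`, `time` and the [enrichment_test()]
#'   columns.
#' @export
enrichment_grid <- function(calls, analyzed_genes, gene_tfs,
                            tfs = unique(gene_tfs$tf)) {
  cells <- dplyr::distinct(calls, .data$tissue, .data$time)
  purrr::map_dfr(tfs, function(tf) {
    targets <- gene_tfs$gene_id[gene_tfs$tf == tf]
    purrr::map_dfr(seq_len(nrow(cells)), function(i) {
      de <- calls$gene_id[calls$tissue == cells$tissue[i] &
                            calls$time == cells$time[i]]
      de <- intersect(de, analyzed_genes)
      bg <- setdiff(analyzed_genes, de)
      enrichment_test(de, bg, targets) |>
        dplyr::mutate(tf = tf, tissue = cells$tissue[i],
                      time = cells$time[i], .before = 1)
    })
  })
}

#' Signed enrichment heatmap matrix
#'
#' TFs x (tissue, time) matrix of signed `-log10(p)` values. Cells that do
#' not reach `p <= alpha` are masked (`NA`, the "gray" cells); TFs with no
#' significant cell anywhere are dropped entirely.
#'
#' @param cells Output of [enrichment_grid()].
#' @param alpha Significance cutoff (default 0.01).
#' @param tissues Column ordering (tissue-major, time-minor).
#' @return Numeric matrix; attribute `n_masked` counts masked cells among
#'   kept rows.
#' @export
build_tf_heatmap <- function(cells, alpha = 0.01,
                             tissues = unique(cells$tissue)) {
  keep <- cells |>
    dplyr::group_by(.data$tf) |>
    dplyr::filter(any(.data$pvalue <= alpha, na.rm = TRUE)) |>
    dplyr::ungroup()
  if (nrow(keep) == 0) {
    m <- matrix(numeric(), 0, 0)
    attr(m, "n_masked") <- 0L
    return(m)
  }
  wide <- keep |>
    dplyr::mutate(tissue = factor(.data$tissue, levels = tissues)) |>
    dplyr::arrange(.data$tissue, .data$time) |>
    dplyr::mutate(col = paste0(.data$tissue, ":", .data$time),
                  val = dplyr::if_else(.data$pvalue <= alpha, .data$heat,
                                       NA_real_)) |>
    dplyr::select("tf", "col", "val") |>
    tidyr::pivot_wider(names_from = "col", values_from = "val")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$tf
  attr(m, "n_masked") <- sum(is.na(m))
  m
}
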