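#' Expression thresholds
#'
#' The TPM thresholds used throughout: a gene is \emph{detected} at TPM >= 1
#' in at least one sample and \emph{robust} at TPM >= 15 in at least one
#' sample (both inclusive); the census bins split samples at TPM <= 6
#' (poorly expressed), 6 < TPM < 100 (modest, strict bounds), and
#' TPM >= 100.
#'
#' @param detected_tpm,robust_tpm,low_bin_tpm,mid_bin_tpm Numeric cutoffs.
#' @return A named list.
#' @export
expression_thresholds <- function(detected_tpm = 1, robust_tpm = 15,
                                  low_bin_tpm = 6, mid_bin_tpm = 100) {
  stopifnot(detected_tpm < robust_tpm, low_bin_tpm < mid_bin_tpm)
  list(detected_tpm = detected_tpm, robust_tpm = robust_tpm,
       low_bin_tpm = low_bin_tpm, mid_bin_tpm = mid_bin_tpm)
}

#' Compute TPM with histone/rRNA exclusion
#'
#' `TPM_g = 1e6 * (c_g / L_g) / sum_{g' not excluded} (c_{g'} / L_{g'})`,
#' with gene length the union-exon length. Histone and rRNA genes vary
#' wildly between tissues and times (histones alone can reach 35-43% of
#' early reads in rapidly dividing lineages), so they are excluded from both
#' the denominator and the reported values: excluded genes get `NA`.
#'
#' @param counts Long count tibble (`gene_id`, `sample`, ..., `count`).
#' @param ann A `genome_annotation` providing lengths and biotypes.
#' @param exclude Biotypes to exclude (default histone and rRNA).
#' @return The input with a `tpm` column added (`NA` for excluded genes).
#' @export
compute_tpm <- function(counts, ann, exclude = c("histone", "rRNA")) {
  lens <- gene_lengths(ann)
  bt <- dplyr::select(ann$genes, "gene_id", "biotype")
  out <- counts |>
    dplyr::left_join(lens, by = "gene_id") |>
    dplyr::left_join(bt, by = "gene_id") |>
    dplyr::mutate(rate = .data$count / .data$length) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(denom = sum(.data$rate[!.data$biotype %in% exclude])) |>
    dplyr::ungroup()
  if (any(out$denom == 0)) {
    rlang::abort("zero total count rate in at least one sample")
  }
  out |>
    dplyr::mutate(tpm = dplyr::if_else(.data$biotype %in% exclude,
                                       NA_real_,
                                       1e6 * .data$rate / .data$denom)) |>
    dplyr::select(-"rate", -"denom", -"length", -"biotype")
}

#' Histone read fraction per sample
#'
#' @param counts Long count tibble.
#' @param ann A `genome_annotation`.
#' @return Tibble `sample`, `histone_fraction` (histone counts over total
#'   mapped counts).
#' @export
histone_fraction <- function(counts, ann) {
  his <- ann$genes$gene_id[ann$genes$biotype == "histone"]
  counts |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      histone_fraction = if (length(his) == 0) 0 else
        sum(.data$count[.data$gene_id %in% his]) / sum(.data$count),
      .groups = "drop")
}

#' Replicate-averaged expression profiles
#'
#' Averages TPM over the labeled replicates of each (tissue, time) point,
#' yielding the T x P (default 35-dimensional) profile per gene that
#' clustering and expression distances operate on. Unlabeled samples are
#' excluded.
#'
#' @param tpm Long tibble with `gene_id`, `tissue`, `time`, `labeled`,
#'   `tpm`.
#' @return Tibble `gene_id`, `tissue`, `time`, `tpm` (replicate mean).
#' @export
profile_means <- function(tpm) {
  tpm |>
    dplyr::filter(.data$labeled) |>
    dplyr::group_by(.data$gene_id, .data$tissue, .data$time) |>
    dplyr::summarise(tpm = mean(.data$tpm), .groups = "drop")
}

#' max1 normalization
#'
#' Divides each gene's profile by its maximum over samples, so the peak
#' sample equals one; all-zero genes stay zero.
#'
#' @param profiles Long tibble `gene_id`, ..., `tpm` (typically from
#'   [profile_means()]).
#' @return The input with `tpm` replaced by a `max1` column.
#' @export
max1_normalize <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(.mx = max(.data$tpm),
                  max1 = dplyr::if_else(.data$.mx > 0,
                                        .data$tpm / .data$.mx, 0)) |>
    dplyr::ungroup() |>
    dplyr::select(-"tpm", -".mx")
}

#' Profile matrix
#'
#' Pivot a long profile tibble into a genes x (tissue, time) matrix, columns
#' ordered tissue-major then time, as the clustering input and heatmaps
#' expect.
#'
#' @param profiles Long tibble with `gene_id`, `tissue`, `time` and one
#'   value column.
#' @param value Name of the value column (`"max1"` or `"tpm"`).
#' @param tissues Tissue ordering (default: order of appearance).
#' @return Numeric matrix with rownames `gene_id` and colnames
#'   `tissue:time`.
#' @export
profile_matrix <- function(profiles, value = "max1",
                           tissues = unique(profiles$tissue)) {
  wide <- profiles |>
    dplyr::mutate(tissue = factor(.data$tissue, levels = tissues)) |>
    dplyr::arrange(.data$tissue, .data$time) |>
    dplyr::mutate(col = paste0(.data$tissue, ":", .data$time)) |>
    dplyr::select("gene_id", "col", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "col",
                       values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  m
}

#' Expression census
#'
#' Per sample, counts genes below `low_bin_tpm`, strictly between
#' `low_bin_tpm` and `mid_bin_tpm` ("modestly expressed"), and at or above
#' `mid_bin_tpm`; overall, counts genes detected (TPM >= 1 anywhere) and
#' robust (TPM >= 15 anywhere).
#'
#' @param tpm Long tibble with `gene_id`, `sample`, `tpm` (excluded genes'
#'   `NA`s are dropped).
#' @param thresholds See [expression_thresholds()].
#' @return List with `per_sample` (tibble `sample`, `n_low`, `n_mid`,
#'   `n_high`) and `overall` (tibble `n_detected`, `n_robust`).
#' @export
expression_census <- function(tpm, thresholds = expression_thresholds()) {
  th <- thresholds
  tpm <- dplyr::filter(tpm, !is.na(.data$tpm))
  per_sample <- tpm |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_low = sum(.data$tpm <= th$low_bin_tpm),
      n_mid = sum(.data$tpm > th$low_bin_tpm & .data$tpm < th$mid_bin_tpm),
      n_high = sum(.data$tpm >= th$mid_bin_tpm),
      .groups = "drop")
  overall <- tpm |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mx = max(.data$tpm), .groups = "drop") |>
    dplyr::summarise(n_detected = sum(.data$mx >= th$detected_tpm),
                     n_robust = sum(.data$mx >= th$robust_tpm))
  list(per_sample = per_sample, overall = overall)
}

#' Robustly expressed genes
#'
#' @param tpm Long TPM tibble.
#' @param robust_tpm Threshold (default 15, inclusive).
#' @return Character vector of gene ids with TPM >= threshold in at least
#'   one sample.
#' @export
robust_genes <- function(tpm, robust_tpm = 15) {
  tpm |>
    dplyr::filter(!is.na(.data$tpm)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mx = max(.data$tpm), .groups = "drop") |>
    dplyr::filter(.data$mx >= robust_tpm) |>
    dplyr::pull("gene_id")
}

#' Per-exon usage matrix
#'
#' Normalizes each exon's counts to a maximum of one across samples (per-exon
#' max1) and orders samples tissue-major, time-minor, the layout used for
#' exon-usage heatmaps of differentially spliced genes.
#'
#' @param exon_counts Long tibble `exon_id`, `tissue`, `time`, `count`
#'   (already replicate-summed or -averaged).
#' @param tissues Tissue ordering.
#' @return Matrix exons x (tissue, time), values in `[0, 1]`.
#' @export
exon_usage_matrix <- function(exon_counts,
                              tissues = unique(exon_counts$tissue)) {
  norm <- exon_counts |>
    dplyr::group_by(.data$exon_id) |>
    dplyr::mutate(.mx = max(.data$count),
                  u = dplyr::if_else(.data$.mx > 0,
                                     .data$count / .data$.mx, 0)) |>
    dplyr::ungroup()
  wide <- norm |>
    dplyr::mutate(tissue = factor(.data$tissue, levels = tissues)) |>
    dplyr::arrange(.data$tissue, .data$time) |>
    dplyr::mutate(col = paste0(.data$tissue, ":", .data$time)) |>
    dplyr::select("exon_id", "col", "u") |>
    tidyr::pivot_wider(names_from = "col", values_from = "u")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$exon_id
  m
}
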