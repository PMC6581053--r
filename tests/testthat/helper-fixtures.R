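suppressPackageStartupMessages({
  library(dplyr)
  library(tidyr)
  library(tibble)
  library(purrr)
})

# small study-shaped config for module tests
tiny_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 150, n_operons = 8, replicates = 2),
    list(...))
  do.call(sim_config, args)
}

# hand-built annotation on one chromosome (0-based half-open)
toy_ann <- function() {
  genome_annotation(
    genes = tibble::tribble(
      ~gene_id, ~chrom, ~strand, ~start, ~end, ~biotype,
      "gA", "chrI", "+", 100L, 1100L, "coding",
      "gB", "chrI", "-", 2000L, 3000L, "coding",
      "gH", "chrI", "+", 4000L, 4500L, "histone"
    ),
    exons = tibble::tribble(
      ~gene_id, ~start, ~end,
      "gA", 100L, 400L,
      "gA", 600L, 1100L,
      "gB", 2000L, 2400L,
      "gB", 2600L, 3000L,
      "gH", 4000L, 4500L
    ),
    chrom_lengths = c(chrI = 10000)
  )
}

# long count tibble from a named matrix (rows genes, cols sample keys)
counts_from_matrix <- function(m) {
  keys <- parse_sample_key(colnames(m))
  tibble::as_tibble(m, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample",
                        values_to = "count") |>
    dplyr::left_join(keys, by = "sample") |>
    dplyr::relocate("count", .after = dplyr::last_col())
}

# shape-based program classifier operating on noiseless true mean TPM;
# the per-(tissue, time) compositional factor is removed by dividing each
# column by its geometric mean across genes before reading off features
classify_programs <- function(true_tpm, tissues) {
  corrected <- true_tpm |>
    dplyr::group_by(tissue, time) |>
    dplyr::mutate(rel = true_tpm / exp(mean(log(pmax(true_tpm, 1e-12))))) |>
    dplyr::ungroup()
  corrected |>
    dplyr::group_by(gene_id) |>
    dplyr::group_modify(function(d, key) {
      m <- matrix(0, length(tissues), max(d$time) + 1,
                  dimnames = list(tissues, NULL))
      m[cbind(match(d$tissue, tissues), d$time + 1)] <- d$rel
      by_tissue <- rowMeans(m)
      spread <- max(by_tissue) / stats::median(by_tissue)
      if (spread > 3) {
        early <- names(which.max(rowMeans(m[, 1:2])))
        late <- names(which.max(rowMeans(m[, ncol(m) - 1:0])))
        lab <- if (early == late) "tissue_specific" else "switch"
      } else {
        p <- colMeans(m)
        r <- p[length(p)] / p[1]
        lab <- if (r > 2.5) "zygotic" else if (r < 0.4) "maternal" else "stable"
      }
      tibble::tibble(call = lab)
    }) |>
    dplyr::ungroup()
}

# spearman helper used by recovery comparisons
spearman <- function(x, y) stats::cor(x, y, method = "spearman")

# per-gene fragment counts with zeros filled in
gene_counts_of <- function(frags, all_genes) {
  frags |>
    dplyr::count(gene_id) |>
    dplyr::right_join(tibble::tibble(gene_id = all_genes), by = "gene_id") |>
    dplyr::mutate(n = dplyr::coalesce(n, 0L))
}
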