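#' Classify adjacent gene pairs by orientation
#'
#' Walks each chromosome left to right and pairs nearest-neighbor genes:
#' opposite strands with 5' ends adjacent are `head_to_head` (divergent,
#' potentially sharing a regulatory region), opposite strands with 3' ends
#' adjacent are `tail_to_tail`, and same-strand neighbors are
#' `head_to_tail`. Consecutive operon members form the `operon` class, and
#' pairs touching a downstream operon gene are excluded from the adjacency
#' classes (their expression is expected to track the first gene). A seeded
#' `random` baseline of non-adjacent gene pairs of the same size as the
#' adjacency classes is added.
#'
#' @param ann A `genome_annotation`.
#' @param seed Seed for the random baseline.
#' @param n_random Number of random pairs (default: as many as the adjacent
#'   pairs).
#' @return Tibble `gene_a`, `gene_b`, `orientation`, `genomic_distance`
#'   (bp gap between the facing gene ends, 0 if overlapping).
#' @export
classify_gene_pairs <- function(ann, seed = 1, n_random = NULL) {
  g <- dplyr::arrange(ann$genes, .data$chrom, .data$start)
  down <- downstream_operon_genes(ann)
  adj <- g |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(next_gene = dplyr::lead(.data$gene_id),
                  next_strand = dplyr::lead(.data$strand),
                  next_start = dplyr::lead(.data$start)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$next_gene)) |>
    dplyr::transmute(
      gene_a = .data$gene_id, gene_b = .data$next_gene,
      orientation = dplyr::case_when(
        .data$strand == .data$next_strand ~ "head_to_tail",
        .data$strand == "-" & .data$next_strand == "+" ~ "head_to_head",
        TRUE ~ "tail_to_tail"),
      genomic_distance = pmax(0L, .data$next_start - .data$end)) |>
    dplyr::filter(!.data$gene_a %in% down, !.data$gene_b %in% down)
  ops <- operon_pairs(ann) |>
    dplyr::left_join(dplyr::select(g, "gene_id", a_start = "start",
                                   a_end = "end"),
                     by = c(gene_a = "gene_id")) |>
    dplyr::left_join(dplyr::select(g, "gene_id", b_start = "start",
                                   b_end = "end"),
                     by = c(gene_b = "gene_id")) |>
    dplyr::transmute(.data$gene_a, .data$gene_b, orientation = "operon",
                     genomic_distance = pmax(
                       0L, pmax(.data$a_start, .data$b_start) -
                         pmin(.data$a_end, .data$b_end)))
  n_random <- n_random %||% nrow(adj)
  rnd <- with_seed(seed, {
    ij <- matrix(sample.int(nrow(g), 2 * n_random, replace = TRUE), ncol = 2)
    ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
    tibble::tibble(gene_a = g$gene_id[ij[, 1]], gene_b = g$gene_id[ij[, 2]],
                   orientation = "random", genomic_distance = NA_integer_)
  })
  dplyr::bind_rows(adj, ops, rnd)
}

#' Euclidean expression distance between gene pairs
#'
#' Distance in the T x P (default 35-dimensional) replicate-averaged
#' expression space. Profiles are max1-normalized by default so the
#' distance reflects pattern, not magnitude; pass `normalize = FALSE` for
#' raw-TPM distances.
#'
#' @param pairs Tibble with `gene_a`, `gene_b`.
#' @param profiles Long profile tibble from [profile_means()].
#' @param normalize max1-normalize per gene first? (default `TRUE`).
#' @return `pairs` with an `expression_distance` column; pairs with a
#'   missing profile get `NA`.
#' @export
pair_expression_distance <- function(pairs, profiles, normalize = TRUE) {
  m <- if (normalize) {
    profile_matrix(max1_normalize(profiles), "max1")
  } else {
    profile_matrix(profiles, "tpm")
  }
  d <- function(a, b) {
    if (!(a %in% rownames(m)) || !(b %in% rownames(m))) return(NA_real_)
    sqrt(sum((m[a, ] - m[b, ])^2))
  }
  dplyr::mutate(pairs, expression_distance = purrr::map2_dbl(
    .data$gene_a, .data$gene_b, d))
}

#' Compare expression distances between orientation classes
#'
#' Welch two-sample t-tests on the pairwise expression distances of every
#' pair of orientation classes, plus per-class summaries of expression and
#' genomic distance.
#'
#' @param pairs Output of [pair_expression_distance()].
#' @return List with `summary` (per class: n, mean/median expression
#'   distance, median genomic distance) and `tests` (per class pair:
#'   `class_a`, `class_b`, `t`, `p_value`).
#' @export
compare_orientation_distances <- function(pairs) {
  pairs <- dplyr::filter(pairs, !is.na(.data$expression_distance))
  classes <- unique(pairs$orientation)
  summary <- pairs |>
    dplyr::group_by(.data$orientation) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_distance = mean(.data$expression_distance),
                     median_distance = stats::median(.data$expression_distance),
                     median_genomic = stats::median(.data$genomic_distance,
                                                    na.rm = TRUE),
                     .groups = "drop")
  combos <- utils::combn(sort(classes), 2, simplify = FALSE)
  tests <- purrr::map_dfr(combos, function(p) {
    a <- pairs$expression_distance[pairs$orientation == p[1]]
    b <- pairs$expression_distance[pairs$orientation == p[2]]
    ht <- stats::t.test(a, b)
    tibble::tibble(class_a = p[1], class_b = p[2],
                   t = unname(ht$statistic), p_value = ht$p.value)
  })
  list(summary = summary, tests = tests)
}

#' SL usage trends in downstream operon genes
#'
#' Two classic operon trends: (1) SL1 fraction of downstream genes rises
#' with the expression distance to the upstream gene (independent promoters
#' decouple expression and initiate with SL1); (2) SL2 fraction falls as
#' downstream-gene expression rises. Reports per-bin means and the
#' unbinned Spearman correlations.
#'
#' @param op_pairs Operon pairs with `expression_distance` (from
#'   [pair_expression_distance()] on [operon_pairs()] rows).
#' @param sl_sites Classified SL sites with `gene_id`, `sl1`, `sl2`.
#' @param profiles Replicate-averaged TPM (for downstream-gene expression).
#' @param bins Number of quantile bins (default 5).
#' @return List: `distance_bins` (per-bin mean SL1 fraction),
#'   `expression_bins` (per-bin mean SL2 fraction), `rho_sl1_distance`,
#'   `p_sl1_distance`, `rho_sl2_expression`, `p_sl2_expression`,
#'   `n_excluded` (downstream genes without SL data).
#' @export
operon_sl_trend <- function(op_pairs, sl_sites, profiles, bins = 5) {
  gene_sl <- gene_sl1_fraction(sl_sites)
  expr <- profiles |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(expr = max(.data$tpm), .groups = "drop")
  d <- op_pairs |>
    dplyr::transmute(gene_id = .data$gene_b,
                     expression_distance = .data$expression_distance) |>
    dplyr::left_join(gene_sl, by = "gene_id") |>
    dplyr::left_join(expr, by = "gene_id")
  n_excluded <- sum(is.na(d$sl1_fraction))
  d <- dplyr::filter(d, !is.na(.data$sl1_fraction),
                     !is.na(.data$expression_distance))
  qbin <- function(x) {
    cut(x, breaks = unique(stats::quantile(x, probs = seq(0, 1, 1 / bins))),
        include.lowest = TRUE, labels = FALSE)
  }
  distance_bins <- d |>
    dplyr::mutate(bin = qbin(.data$expression_distance)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_sl1_fraction = mean(.data$sl1_fraction),
                     .groups = "drop")
  expression_bins <- d |>
    dplyr::mutate(bin = qbin(.data$expr)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_sl2_fraction = mean(1 - .data$sl1_fraction),
                     .groups = "drop")
  ct1 <- suppressWarnings(stats::cor.test(d$sl1_fraction,
                                          d$expression_distance,
                                          method = "spearman"))
  ct2 <- suppressWarnings(stats::cor.test(1 - d$sl1_fraction, d$expr,
                                          method = "spearman"))
  list(distance_bins = distance_bins, expression_bins = expression_bins,
       rho_sl1_distance = unname(ct1$estimate), p_sl1_distance = ct1$p.value,
       rho_sl2_expression = unname(ct2$estimate),
       p_sl2_expression = ct2$p.value, n_excluded = n_excluded)
}

#' TF-binding clusters vs operon expression distance
#'
#' A downstream operon gene has a "TF cluster" when at least `min_tfs`
#' distinct transcription factors peak in its promoter window. Compares the
#' cluster frequency between the top and bottom quantiles of expression
#' distance with a Fisher exact test.
#'
#' @param op_pairs Operon pairs with `expression_distance`.
#' @param gene_tfs Gene-to-TF map from [assign_peaks_to_genes()].
#' @param min_tfs Cluster definition (default 3 distinct TFs).
#' @param quantile Tail size (default 0.25: quartiles).
#' @return List: `table` (2x2), `freq_top`, `freq_bottom`, `p_value`.
#' @export
tf_cluster_vs_distance <- function(op_pairs, gene_tfs, min_tfs = 3,
                                   quantile = 0.25) {
  ntf <- gene_tfs |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_tfs = dplyr::n_distinct(.data$tf), .groups = "drop")
  d <- op_pairs |>
    dplyr::filter(!is.na(.data$expression_distance)) |>
    dplyr::transmute(gene_id = .data$gene_b,
                     expression_distance = .data$expression_distance) |>
    dplyr::left_join(ntf, by = "gene_id") |>
    dplyr::mutate(n_tfs = dplyr::coalesce(.data$n_tfs, 0L),
                  has_cluster = .data$n_tfs >= min_tfs)
  lo <- stats::quantile(d$expression_distance, quantile)
  hi <- stats::quantile(d$expression_distance, 1 - quantile)
  top <- d$has_cluster[d$expression_distance >= hi]
  bottom <- d$has_cluster[d$expression_distance <= lo]
  tab <- matrix(c(sum(top), sum(!top), sum(bottom), sum(!bottom)), 2,
                dimnames = list(c("cluster", "no_cluster"),
                                c("top", "bottom")))
  p <- if (sum(tab) == 0 || sum(tab["cluster", ]) == 0) 1 else
    stats::fisher.test(tab)$p.value
  list(table = tab, freq_top = mean(top), freq_bottom = mean(bottom),
       p_value = p)
}
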