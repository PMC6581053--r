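#' Negative-binomial Wald test between two sample groups
#'
#' A per-gene two-group test on counts: library sizes are normalized by the
#' median-of-ratios method, per-gene dispersion is estimated by method of
#' moments on normalized counts and shrunk toward a fitted mean-dispersion
#' trend, and the log fold change is tested with a Wald statistic using the
#' delta-method variance `Var(log mean) ~ (1/n) * (1/mean + alpha)`.
#' P-values are BH-adjusted across genes; all-zero genes get `NA` p-values
#' and are excluded from the BH denominator.
#'
#' @param counts Long count tibble (`gene_id`, `sample`, `count`).
#' @param group_a,group_b Character vectors of sample keys (numerator group
#'   first: positive `log2fc` means higher in `group_a`).
#' @param pseudocount Added to group means before the ratio (normalized-count
#'   scale, default 0.5).
#' @param prior_df Weight (pseudo-replicates) of the trend in dispersion
#'   shrinkage.
#' @return Tibble `gene_id`, `base_mean`, `log2fc`, `dispersion`, `stat`,
#'   `pvalue`, `padj`.
#' @export
nb_test <- function(counts, group_a, group_b, pseudocount = 0.5,
                    prior_df = 10) {
  sub <- dplyr::filter(counts, .data$sample %in% c(group_a, group_b))
  m <- sub |>
    dplyr::select("gene_id", "sample", "count") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count")
  genes <- m$gene_id
  m <- as.matrix(m[, -1])
  sf <- size_factors(m)
  q <- sweep(m, 2, sf, "/")
  a_idx <- colnames(m) %in% group_a
  b_idx <- colnames(m) %in% group_b
  na <- sum(a_idx); nb <- sum(b_idx)
  mu_a <- rowMeans(q[, a_idx, drop = FALSE])
  mu_b <- rowMeans(q[, b_idx, drop = FALSE])
  base_mean <- rowMeans(q)
  # method-of-moments dispersion pooled over the two groups
  v_a <- apply(q[, a_idx, drop = FALSE], 1, stats::var)
  v_b <- apply(q[, b_idx, drop = FALSE], 1, stats::var)
  pooled_v <- ((na - 1) * v_a + (nb - 1) * v_b) / pmax(1, na + nb - 2)
  pooled_m <- (mu_a + mu_b) / 2
  disp_raw <- pmax(0, (pooled_v - pooled_m) / pooled_m^2)
  disp_raw[!is.finite(disp_raw)] <- 0
  # gamma-family trend alpha(mu) = a1/mu + a0, fitted on moment estimates
  ok <- pooled_m > 0 & disp_raw > 0
  trend <- if (sum(ok) >= 10) {
    fit <- stats::lm(disp_raw[ok] ~ I(1 / pooled_m[ok]))
    pmax(1e-8, stats::coef(fit)[1] + stats::coef(fit)[2] / pooled_m)
  } else rep(stats::median(disp_raw[ok]) %||% 0.1, length(disp_raw))
  trend[!is.finite(trend)] <- 1e-8
  df <- na + nb - 2
  disp <- (disp_raw * df + trend * prior_df) / (df + prior_df)
  log2fc <- log2((mu_a + pseudocount) / (mu_b + pseudocount))
  se2 <- (1 / na) * (1 / (mu_a + pseudocount) + disp) +
    (1 / nb) * (1 / (mu_b + pseudocount) + disp)
  stat <- log(2) * log2fc / sqrt(se2)
  pvalue <- 2 * stats::pnorm(-abs(stat))
  allzero <- rowSums(m) == 0
  pvalue[allzero] <- NA_real_
  tibble::tibble(gene_id = genes, base_mean = base_mean, log2fc = log2fc,
                 dispersion = disp, stat = stat, pvalue = pvalue,
                 padj = stats::p.adjust(pvalue, "BH"))
}

# median-of-ratios size factors; falls back to library-size ratios when no
# gene is positive everywhere
size_factors <- function(m) {
  logg <- rowMeans(log(m))
  use <- is.finite(logg)
  if (sum(use) < 1) {
    cs <- colSums(m)
    return(cs / exp(mean(log(cs))))
  }
  apply(m[use, , drop = FALSE], 2,
        function(col) exp(stats::median(log(col) - logg[use])))
}

#' All pairwise tissue DE tests at each time point
#'
#' Runs [nb_test()] for every unordered tissue pair at every time point on
#' labeled samples, the input the specificity caller needs.
#'
#' @param counts Long count tibble with key columns.
#' @param tissues,times Subsets to test (defaults: all present).
#' @return Tibble with `tissue_a`, `tissue_b`, `time` and the [nb_test()]
#'   columns.
#' @export
de_pairwise <- function(counts, tissues = NULL, times = NULL) {
  counts <- dplyr::filter(counts, .data$labeled)
  tissues <- tissues %||% unique(counts$tissue)
  times <- times %||% sort(unique(counts$time))
  pairs <- utils::combn(sort(tissues), 2, simplify = FALSE)
  purrr::map_dfr(times, function(tp) {
    sub <- dplyr::filter(counts, .data$time == tp)
    purrr::map_dfr(pairs, function(p) {
      ga <- unique(sub$sample[sub$tissue == p[1]])
      gb <- unique(sub$sample[sub$tissue == p[2]])
      nb_test(sub, ga, gb) |>
        dplyr::mutate(tissue_a = p[1], tissue_b = p[2], time = tp,
                      .before = 1)
    })
  })
}

#' Call tissue-specific genes with related-tissue exclusion
#'
#' Per gene and time point, the top tissue by replicate-averaged TPM is
#' compared against the highest-expressed tissue that does not share cells
#' with it (the related-tissue matrix). The call requires
#' `log2((top + pc) / (second + pc)) >= lfc_min` and the adjusted p-value
#' of the corresponding pairwise DE test `<= padj_max`. A gene is
#' \emph{specific} to a tissue if called there at one or more time points
#' and never called for a different, non-related tissue.
#'
#' @param profiles Replicate-averaged TPM ([profile_means()]).
#' @param de Pairwise results from [de_pairwise()] (or an external table
#'   with columns `tissue_a`, `tissue_b`, `time`, `gene_id`, `padj`).
#' @param related Logical matrix from [related_tissue_matrix()].
#' @param lfc_min,padj_max Call thresholds (defaults 1 and 0.1).
#' @param pseudocount TPM pseudocount in the top/second ratio (default 1).
#' @param min_top_tpm Minimum top TPM to consider a gene at a time point
#'   (default 15, the robust threshold).
#' @return Tibble of per-(gene, time) calls: `gene_id`, `tissue`, `time`,
#'   `top_tpm`, `second_tissue`, `second_tpm`, `log2fc`, `padj`, plus a
#'   `specific` flag marking genes whose calls all agree on one tissue.
#' @export
call_tissue_specific <- function(profiles, de, related = related_tissue_matrix(),
                                 lfc_min = 1, padj_max = 0.1,
                                 pseudocount = 1, min_top_tpm = 15) {
  ranked <- profiles |>
    dplyr::group_by(.data$gene_id, .data$time) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, dplyr::desc(.data$tpm), .data$tissue)
      top <- d$tissue[1]
      rel <- related[top, d$tissue]
      comp <- which(!rel)[1]
      if (is.na(comp)) return(tibble::tibble())
      tibble::tibble(tissue = top, top_tpm = d$tpm[1],
                     second_tissue = d$tissue[comp],
                     second_tpm = d$tpm[comp])
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(log2fc = log2((.data$top_tpm + pseudocount) /
                                  (.data$second_tpm + pseudocount)))
  de_key <- de |>
    dplyr::mutate(t1 = pmin(.data$tissue_a, .data$tissue_b),
                  t2 = pmax(.data$tissue_a, .data$tissue_b)) |>
    dplyr::select("gene_id", "t1", "t2", "time", "padj")
  calls <- ranked |>
    dplyr::mutate(t1 = pmin(.data$tissue, .data$second_tissue),
                  t2 = pmax(.data$tissue, .data$second_tissue)) |>
    dplyr::left_join(de_key, by = c("gene_id", "t1", "t2", "time"))
  missing <- calls |>
    dplyr::filter(is.na(.data$padj), .data$log2fc >= lfc_min,
                  .data$top_tpm >= min_top_tpm)
  if (nrow(missing) > 0) {
    rlang::abort(paste0("missing DE result for pair ", missing$t1[1], " vs ",
                        missing$t2[1], " at time ", missing$time[1]))
  }
  calls <- calls |>
    dplyr::filter(.data$top_tpm >= min_top_tpm,
                  .data$log2fc >= lfc_min, !is.na(.data$padj),
                  .data$padj <= padj_max) |>
    dplyr::select(-"t1", -"t2")
  if (nrow(calls) == 0) {
    return(dplyr::mutate(calls, specific = logical()))
  }
  # specific = never called for a different non-related tissue
  consistent <- calls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(specific = all(related[.data$tissue[1], .data$tissue]),
                     .groups = "drop")
  dplyr::left_join(calls, consistent, by = "gene_id")
}

#' Tissue-specific gene table
#'
#' Collapses per-time calls to one row per specific gene (its tissue and
#' called time points).
#'
#' @param calls Output of [call_tissue_specific()].
#' @return Tibble `gene_id`, `tissue`, `times` (list-column), `n_times`.
#' @export
specific_genes <- function(calls) {
  calls |>
    dplyr::filter(.data$specific) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(tissue = .data$tissue[1],
                     times = list(sort(unique(.data$time))),
                     n_times = dplyr::n_distinct(.data$time),
                     .groups = "drop")
}

#' Detect tissue-switch genes
#'
#' Genes called for one tissue at an early time point and a different,
#' non-related tissue at a strictly later time point (e.g. neurons early,
#' pharynx late), i.e. genes whose tissue specificity changes during
#' development.
#'
#' @param calls Per-time calls from [call_tissue_specific()].
#' @param related Related-tissue matrix (switches between related tissues
#'   are not counted).
#' @return Tibble `gene_id`, `tissue_early`, `time_early`, `tissue_late`,
#'   `time_late`.
#' @export
detect_tissue_switch <- function(calls, related = related_tissue_matrix()) {
  calls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$time)
      out <- tibble::tibble()
      for (i in seq_len(nrow(d))) {
        later <- d[d$time > d$time[i] &
                     !related[d$tissue[i], d$tissue], , drop = FALSE]
        if (nrow(later) > 0) {
          out <- tibble::tibble(tissue_early = d$tissue[i],
                                time_early = d$time[i],
                                tissue_late = later$tissue[nrow(later)],
                                time_late = later$time[nrow(later)])
          break
        }
      }
      out
    }) |>
    dplyr::ungroup()
}

#' Detect stably expressed genes
#'
#' A gene is stable in a tissue if it is robustly expressed there (max TPM
#' over time >= `robust_tpm`) and its expression varies minimally over
#' time: `(max + pc) / (min + pc) <= fold_threshold` on replicate-averaged
#' TPM. "Stably expressed" overall means stable in at least one tissue.
#'
#' @param profiles Replicate-averaged TPM ([profile_means()]).
#' @param fold_threshold Maximum max/min fold change over time (default 2).
#' @param robust_tpm Robust-expression floor (default 15).
#' @param pseudocount Added to max and min (default 1).
#' @return List with `per_tissue` (tibble `gene_id`, `tissue`, `stable`)
#'   and `stable_genes` (character vector).
#' @export
detect_stable <- function(profiles, fold_threshold = 2, robust_tpm = 15,
                          pseudocount = 1) {
  per_tissue <- profiles |>
    dplyr::group_by(.data$gene_id, .data$tissue) |>
    dplyr::summarise(
      stable = max(.data$tpm) >= robust_tpm &
        (max(.data$tpm) + pseudocount) / (min(.data$tpm) + pseudocount) <=
          fold_threshold,
      .groups = "drop")
  list(per_tissue = per_tissue,
       stable_genes = per_tissue |>
         dplyr::filter(.data$stable) |>
         dplyr::distinct(.data$gene_id) |>
         dplyr::pull("gene_id"))
}

#' Operon membership vs stable expression: chi-squared association
#'
#' Builds the 2x2 table {stable, not stable} x {in operon, not in operon}
#' over the analyzed genes and applies Pearson's chi-squared test without
#' continuity correction. Also reports the fraction of stable genes in
#' operons and of analyzed genes in operons.
#'
#' @param stable Character vector of stably expressed gene ids.
#' @param operon Character vector of operon-member gene ids.
#' @param analyzed Character vector of all analyzed gene ids (the robust
#'   set).
#' @return List: `table` (2x2 matrix), `p_value`, `statistic`,
#'   `pct_stable_in_operon`, `pct_operon_in_analyzed`.
#' @export
operon_stability_test <- function(stable, operon, analyzed) {
  stable <- intersect(stable, analyzed)
  operon <- intersect(operon, analyzed)
  a <- length(intersect(stable, operon))
  b <- length(setdiff(stable, operon))
  c_ <- length(setdiff(operon, stable))
  d <- length(analyzed) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(c("stable", "not_stable"),
                                c("operon", "not_operon")))
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(table = tab, p_value = ht$p.value,
       statistic = unname(ht$statistic),
       pct_stable_in_operon = 100 * a / length(stable),
       pct_operon_in_analyzed = 100 * length(operon) / length(analyzed))
}
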