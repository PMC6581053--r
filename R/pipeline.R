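#' Pipeline configuration
#'
#' Collects every stage's parameters with the package defaults; unknown
#' names are rejected. Stage seeds are derived from the global seed by
#' stable hashing of the stage name, so each stage is reproducible
#' independently of execution order.
#'
#' @param seed Global seed.
#' @param sim Arguments for [sim_config()].
#' @param dedup List: `window`, `low_cov`.
#' @param expression List: thresholds, see [expression_thresholds()].
#' @param differential List: `lfc_min`, `padj_max`, `fold_threshold`.
#' @param clustering List: `k`, `m`, `tol`, `max_iter`.
#' @param splicing List: `min_support`, `min_class_support`.
#' @param tf List: `upstream`, `downstream`, `alpha`.
#' @param editing List: see [edit_thresholds()].
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, sim = list(), dedup = list(),
                            expression = list(), differential = list(),
                            clustering = list(), splicing = list(),
                            tf = list(), editing = list()) {
  merge_known <- function(defaults, given, where) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown) > 0) {
      rlang::abort(paste0("unknown ", where, " option: ", unknown[1]))
    }
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    seed = as.integer(seed),
    sim = sim,  # validated by sim_config()
    dedup = merge_known(list(window = 1000, low_cov = 10), dedup, "dedup"),
    expression = merge_known(expression_thresholds(), expression,
                             "expression"),
    differential = merge_known(list(lfc_min = 1, padj_max = 0.1,
                                    fold_threshold = 2), differential,
                               "differential"),
    clustering = merge_known(list(k = 60, m = 2, tol = 1e-6, max_iter = 500),
                             clustering, "clustering"),
    splicing = merge_known(list(min_support = 2, min_class_support = 2),
                           splicing, "splicing"),
    tf = merge_known(list(upstream = 1000, downstream = 200, alpha = 0.01),
                     tf, "tf"),
    editing = merge_known(edit_thresholds(), editing, "editing"))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full pipeline on synthetic data
#'
#' Simulates a dataset, then runs every stage in dependency order —
#' duplicate estimation/removal, TPM quantification and normalization,
#' pairwise DE and specificity calls, stable genes and the operon
#' chi-squared, fuzzy k-means clustering, SL-site classification, gene-pair
#' orientation statistics, TF-peak enrichment, and edit calling — writing
#' stage TSVs plus a JSON manifest into `dir`. With the same config the run
#' is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory (created if missing).
#' @param n_fragments Fragment-library size for the dedup stage.
#' @param k Cluster count override (defaults to `config$clustering$k`,
#'   capped at the number of robust genes).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = tempfile("run"),
                         n_fragments = 2e4, k = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- do.call(sim_config, c(list(seed = stage_seed(config$seed, "simulate")),
                                config$sim))
  ds <- simulate_dataset(scfg, n_fragments = n_fragments)
  write_annotation(ds$ann, file.path(dir, "annotation.gff3"))
  write_fragments(ds$fragments, file.path(dir, "fragments.tsv"))
  write_expression_matrix(ds$counts, file.path(dir, "counts.tsv"))
  # dedup
  est <- estimate_dup_rate(ds$fragments, ds$ann,
                           window = config$dedup$window,
                           low_cov = config$dedup$low_cov)
  kept <- remove_duplicates(ds$fragments, est,
                            seed = stage_seed(config$seed, "dedup"))
  readr::write_tsv(est, file.path(dir, "dedup_estimate.tsv"))
  # expression
  tpm <- compute_tpm(ds$counts, ds$ann)
  prof <- profile_means(tpm)
  m1 <- max1_normalize(prof)
  write_expression_matrix(tpm |> dplyr::filter(!is.na(.data$tpm)),
                          file.path(dir, "tpm.tsv"), value_name = "tpm")
  # differential + stability
  de <- de_pairwise(ds$counts)
  calls <- call_tissue_specific(prof, de,
                                lfc_min = config$differential$lfc_min,
                                padj_max = config$differential$padj_max)
  stable <- detect_stable(prof,
                          fold_threshold = config$differential$fold_threshold)
  analyzed <- robust_genes(tpm)
  op_test <- operon_stability_test(stable$stable_genes,
                                   unique(ds$ann$operons$gene_id), analyzed)
  readr::write_tsv(calls |> dplyr::select(-dplyr::any_of("times")),
                   file.path(dir, "specificity_calls.tsv"))
  # clustering
  mat <- profile_matrix(dplyr::filter(m1, .data$gene_id %in% analyzed),
                        "max1", tissues = scfg$tissues)
  kk <- min(k %||% config$clustering$k, max(2, nrow(mat) - 1))
  model <- fuzzy_kmeans(mat, k = kk, m = config$clustering$m,
                        seed = stage_seed(config$seed, "cluster"),
                        tol = config$clustering$tol,
                        max_iter = config$clustering$max_iter)
  readr::write_tsv(tidy(model), file.path(dir, "clusters.tsv"))
  # splicing
  sl_sites <- detect_sl_sites(ds$sl,
                              min_support = config$splicing$min_support,
                              min_class_support = config$splicing$min_class_support)
  readr::write_tsv(sl_sites |> dplyr::select(-dplyr::any_of(c("true_class",
                                                              "promoter_strength"))),
                   file.path(dir, "sl_sites.tsv"))
  # pairs / operons
  pairs <- classify_gene_pairs(ds$ann,
                               seed = stage_seed(config$seed, "pairs")) |>
    pair_expression_distance(prof)
  ori <- compare_orientation_distances(pairs)
  trend <- operon_sl_trend(dplyr::filter(pairs, .data$orientation == "operon"),
                           sl_sites, prof)
  readr::write_tsv(ori$summary, file.path(dir, "pair_orientation.tsv"))
  # tf enrichment
  gene_tfs <- assign_peaks_to_genes(ds$peaks, ds$ann,
                                    upstream = config$tf$upstream,
                                    downstream = config$tf$downstream)
  grid <- enrichment_grid(calls, analyzed, gene_tfs)
  heat <- build_tf_heatmap(grid, alpha = config$tf$alpha)
  readr::write_tsv(grid, file.path(dir, "tf_enrichment.tsv"))
  # editing
  edits <- call_edits(ds$pileups, ds$ann, thresholds = config$editing)
  readr::write_tsv(edits$calls |>
                     dplyr::mutate(supporting_samples = purrr::map_chr(
                       .data$supporting_samples, paste, collapse = ",")),
                   file.path(dir, "edit_calls.tsv"))
  manifest <- list(
    seed = config$seed,
    parameter_hash = rlang::hash(unclass(config)),
    stages = c("simulate", "dedup", "quantify", "de-call", "cluster", "sl",
               "pairs", "tf-enrich", "edits"),
    n_genes = nrow(ds$ann$genes), n_robust = length(analyzed),
    dup_rate_estimate = est$rate[1],
    n_specific_calls = nrow(calls), n_edit_calls = nrow(edits$calls))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = ds, dedup = list(estimate = est, kept = kept),
                 tpm = tpm, profiles = prof, de = de, calls = calls,
                 stable = stable, operon_test = op_test, model = model,
                 sl_sites = sl_sites, pairs = pairs, orientation = ori,
                 sl_trend = trend, tf_grid = grid, tf_heatmap = heat,
                 edits = edits, manifest = manifest, dir = dir))
}
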