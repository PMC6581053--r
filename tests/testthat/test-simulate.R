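test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(program_mix = c(maternal = 0.5, stable = 0.4)),
               "sum to 1")
  expect_error(sim_config(dup_rate = 1), "dup_rate")
  expect_error(sim_config(n_genes = 20, n_operons = 10), "too small")
  reps <- embryoflow:::replicates_for(sim_config())
  expect_equal(unname(reps[c("muscle", "ABa", "intestine")]), c(4L, 3L, 2L))
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- tiny_cfg(seed = 11)
  expect_identical(sim_annotation(cfg), sim_annotation(cfg))
  ann <- sim_annotation(cfg)
  f1 <- sim_fragments(cfg, ann, n_fragments = 2000)
  f2 <- sim_fragments(cfg, ann, n_fragments = 2000)
  t1 <- tempfile(); t2 <- tempfile()
  write_fragments(f1, t1); write_fragments(f2, t2)
  expect_identical(readLines(t1), readLines(t2))
  expect_identical(sim_expression(cfg, ann)$counts,
                   sim_expression(cfg, ann)$counts)
})

test_that("annotation generator places operons, biotypes and orientations", {
  cfg <- sim_config(seed = 2, n_genes = 500, n_operons = 25)
  ann <- sim_annotation(cfg)
  expect_equal(dplyr::n_distinct(ann$operons$operon_id), 25)
  sizes <- dplyr::count(ann$operons, operon_id)$n
  expect_true(all(sizes >= 2 & sizes <= 4))
  # members consecutive, same chrom/strand, position 1 at the 5' end
  per_op <- ann$operons |>
    dplyr::left_join(ann$genes, by = "gene_id") |>
    dplyr::group_by(operon_id) |>
    dplyr::summarise(one_strand = dplyr::n_distinct(strand) == 1,
                     one_chrom = dplyr::n_distinct(chrom) == 1,
                     first_at_5prime = (strand[1] == "+") ==
                       (gene_id[position == 1] == gene_id[which.min(start)]))
  expect_true(all(per_op$one_strand & per_op$one_chrom &
                    per_op$first_at_5prime))
  expect_equal(sort(unique(ann$genes$chrom)), c("chrI", "chrII"))
  census <- table(ann$genes$biotype)
  expect_gt(census[["histone"]], 0)
  expect_gt(census[["rRNA"]], 0)
  # all three adjacency orientations occur
  pairs <- classify_gene_pairs(ann, seed = 1)
  expect_true(all(c("head_to_head", "head_to_tail", "tail_to_tail") %in%
                    pairs$orientation))
  # no operons requested -> none produced
  expect_equal(nrow(sim_annotation(sim_config(n_operons = 0))$operons), 0)
})

test_that("expression programs follow their designed shapes", {
  cfg <- tiny_cfg(seed = 5, n_genes = 200, n_operons = 10)
  ann <- sim_annotation(cfg)
  pr <- sim_programs(cfg, ann)
  mat <- pr$truth$gene_id[pr$truth$program == "maternal"]
  decay <- pr$true_tpm |>
    dplyr::filter(gene_id %in% mat) |>
    dplyr::group_by(gene_id, tissue) |>
    dplyr::summarise(drops = true_tpm[time == max(time)] <
                       true_tpm[time == 0], .groups = "drop")
  expect_true(all(decay$drops))
  # noiseless program recovery: shape classifier recovers every label
  eligible <- pr$truth |>
    dplyr::filter(program %in% c("maternal", "zygotic", "tissue_specific",
                                 "stable", "switch"),
                  !gene_id %in% downstream_operon_genes(ann))
  calls <- classify_programs(
    dplyr::filter(pr$true_tpm, gene_id %in% eligible$gene_id), cfg$tissues)
  merged <- dplyr::left_join(eligible, calls, by = "gene_id")
  expect_equal(mean(merged$call == merged$program), 1)
})

test_that("replicate noise vanishes as dispersion goes to zero", {
  cfg <- tiny_cfg(seed = 6, n_genes = 80, n_operons = 4, nb_dispersion = 0,
                  lib_size_mean = 1e6, lib_size_sd_log = 0, replicates = 4)
  ann <- sim_annotation(cfg)
  ds <- sim_expression(cfg, ann)
  stable <- ds$truth$gene_id[ds$truth$program %in% "stable"]
  cv <- ds$counts |>
    dplyr::filter(gene_id %in% stable, labeled, tissue == "muscle",
                  time == 0) |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(cv = stats::sd(count) / mean(count)) |>
    dplyr::filter(is.finite(cv))
  # Poisson-only noise at deep coverage: relative spread is tiny
  expect_lt(stats::median(cv$cv), 0.1)
})

test_that("PCR duplication truth matches the configured rate", {
  cfg <- tiny_cfg(seed = 8, dup_rate = 0.3)
  ann <- sim_annotation(cfg)
  fr <- sim_fragments(cfg, ann, n_fragments = 1e5)
  expect_lt(abs(mean(fr$is_pcr_duplicate) - 0.3), 0.01)
  fr0 <- sim_fragments(tiny_cfg(seed = 8, dup_rate = 0), ann,
                       n_fragments = 5000)
  expect_false(any(fr0$is_pcr_duplicate))
})

test_that("SL read generator encodes leader identity and promoter admixture", {
  cfg <- tiny_cfg(seed = 9, n_genes = 300, n_operons = 20)
  ann <- sim_annotation(cfg)
  sl <- sim_sl_reads(cfg, ann, mono_sl2_admixture = 0)
  mono <- sl |> dplyr::filter(true_class == "SL1")
  expect_true(all(mono$sl2 == 0))
  down <- sl |> dplyr::filter(true_class == "SL2")
  # SL1 fraction ~ 0 at zero promoter strength
  weak <- down |> dplyr::filter(promoter_strength < 0.05)
  expect_true(all(weak$sl1 / (weak$sl1 + weak$sl2) < 0.3))
  # monotone mean SL1 fraction across promoter-strength thirds
  bins <- down |>
    dplyr::mutate(bin = cut(promoter_strength, c(0, 1 / 3, 2 / 3, 1),
                            include.lowest = TRUE, labels = FALSE)) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(f = mean(sl1 / (sl1 + sl2)))
  expect_true(all(diff(bins$f) > 0))
})

test_that("peak generator enriches target promoters at the configured odds", {
  cfg0 <- tiny_cfg(seed = 10, tf_count = 0)
  ann0 <- sim_annotation(cfg0)
  expect_equal(nrow(sim_peaks(cfg0, ann0)$peaks), 0)
  hits <- purrr::map_lgl(1:5, function(s) {
    cfg <- sim_config(seed = s, n_genes = 1500, n_operons = 30,
                      tf_count = 1, peak_enrichment_odds = 10)
    ann <- sim_annotation(cfg)
    pr <- sim_programs(cfg, ann)
    pk <- sim_peaks(cfg, ann, truth = pr$truth, cluster_tfs = 0)
    gt <- assign_peaks_to_genes(pk$peaks, ann)
    targets <- pr$truth$gene_id[pr$truth$program %in% "tissue_specific" &
                                  pr$truth$tissue_a ==
                                    pk$tf_truth$target_tissue[1]]
    bg <- setdiff(ann$genes$gene_id, targets)
    withpk <- gt$gene_id[gt$tf == "tf01"]
    tab <- matrix(c(sum(targets %in% withpk), sum(!targets %in% withpk),
                    sum(bg %in% withpk), sum(!bg %in% withpk)), 2)
    stats::fisher.test(tab)$p.value < 1e-4
  })
  expect_true(all(hits))
})

test_that("pileup generator separates true, decoy and singleton sites", {
  cfg <- tiny_cfg(seed = 12, edit_sites = 10)
  ann <- sim_annotation(cfg)
  pe <- sim_pileups(cfg, ann)
  labeled <- parse_sample_key(unique(pe$pileups$sample))
  pl <- dplyr::left_join(pe$pileups,
                         dplyr::select(labeled, sample, labeled),
                         by = "sample") |>
    dplyr::mutate(alt = ifelse(ref == "A", G, ifelse(ref == "T", C,
                                                     ifelse(ref == "C", T, A))))
  per_site <- pl |>
    dplyr::group_by(chrom, pos) |>
    dplyr::summarise(lab_alt = sum(alt > 0 & labeled),
                     unl_alt = sum(alt > 0 & !labeled), .groups = "drop") |>
    dplyr::left_join(pe$truth, by = c("chrom", "pos"))
  true_sites <- dplyr::filter(per_site, class == "true")
  expect_true(all(true_sites$lab_alt >= 2 & true_sites$unl_alt == 0))
  decoys <- dplyr::filter(per_site, class == "decoy")
  expect_true(all(decoys$unl_alt >= 1))
  singles <- dplyr::filter(per_site, class == "singleton")
  expect_true(all(singles$lab_alt == 1))
})
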