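test_that("nb_test log fold change matches the analytic ratio", {
  set.seed(1)
  base <- matrix(rpois(50 * 6, 100), 50, 6)
  m <- rbind(base, c(100, 100, 100, 25, 25, 25))
  rownames(m) <- sprintf("g%02d", 1:51)
  colnames(m) <- paste0("muscle:0:", 1:6)
  counts <- counts_from_matrix(m)
  res <- nb_test(counts, paste0("muscle:0:", 1:3), paste0("muscle:0:", 4:6),
                 pseudocount = 1e-6)
  expect_lt(abs(res$log2fc[res$gene_id == "g51"] - 2), 0.2)
  # BH invariants: padj >= p and monotone in p rank
  ok <- !is.na(res$pvalue)
  expect_true(all(res$padj[ok] >= res$pvalue[ok]))
  o <- order(res$pvalue[ok])
  expect_true(all(diff(res$padj[ok][o]) >= -1e-12))
  # all-zero genes drop out of testing
  m0 <- rbind(m, g00 = 0)
  res0 <- nb_test(counts_from_matrix(m0), paste0("muscle:0:", 1:3),
                  paste0("muscle:0:", 4:6))
  expect_true(is.na(res0$pvalue[res0$gene_id == "g00"]))
})

test_that("nb_test controls the null and detects strong shifts", {
  nullfrac <- purrr::map_dbl(1:3, function(s) {
    set.seed(s)
    mu <- rlnorm(2000, log(100), 1)
    m <- sapply(1:6, function(j) rnbinom(2000, mu = mu, size = 20))
    dimnames(m) <- list(sprintf("g%04d", 1:2000), paste0("muscle:0:", 1:6))
    r <- nb_test(counts_from_matrix(m), paste0("muscle:0:", 1:3),
                 paste0("muscle:0:", 4:6))
    mean(r$padj <= 0.1, na.rm = TRUE)
  })
  expect_lt(mean(nullfrac), 0.12)
  hits <- purrr::map_lgl(1:5, function(s) {
    set.seed(100 + s)
    mu <- rlnorm(500, log(50), 1)
    m <- sapply(1:6, function(j) rnbinom(500, mu = mu, size = 20))
    m[1, 1:3] <- rnbinom(3, mu = 2500, size = 20)
    m[1, 4:6] <- rnbinom(3, mu = 25, size = 20)
    dimnames(m) <- list(sprintf("g%03d", 1:500), paste0("muscle:0:", 1:6))
    r <- nb_test(counts_from_matrix(m), paste0("muscle:0:", 1:3),
                 paste0("muscle:0:", 4:6))
    r$padj[r$gene_id == "g001"] <= 0.1
  })
  expect_true(all(hits))
})

test_that("dispersion estimates collapse on Poisson data", {
  set.seed(9)
  mu <- rlnorm(800, log(200), 0.5)
  m <- sapply(1:8, function(j) rpois(800, mu))
  dimnames(m) <- list(sprintf("g%03d", 1:800), paste0("muscle:0:", 1:8))
  r <- nb_test(counts_from_matrix(m), paste0("muscle:0:", 1:4),
               paste0("muscle:0:", 5:8))
  expect_lt(stats::median(r$dispersion), 0.02)
})

test_that("specificity calls use the best non-related competitor", {
  tissues <- default_tissues()
  rel <- related_tissue_matrix()
  # pharynx top, ABa second but related -> competitor is muscle (next best)
  prof <- tidyr::expand_grid(gene_id = "g1", tissue = tissues, time = 0L) |>
    dplyr::mutate(tpm = dplyr::case_when(tissue == "pharynx" ~ 100,
                                         tissue == "ABa" ~ 80,
                                         tissue == "muscle" ~ 20,
                                         TRUE ~ 5))
  de <- tidyr::expand_grid(tissue_a = tissues, tissue_b = tissues, time = 0L) |>
    dplyr::filter(tissue_a < tissue_b) |>
    dplyr::mutate(gene_id = "g1", padj = 1e-5)
  calls <- call_tissue_specific(prof, de, rel)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$tissue, "pharynx")
  expect_equal(calls$second_tissue, "muscle")
  # hand-computed fold change with pseudocount 1: (100+1)/(20+1)
  expect_equal(calls$log2fc, log2(101 / 21))
  # ratio below twofold is never called
  prof2 <- dplyr::mutate(prof, tpm = dplyr::if_else(tissue == "muscle",
                                                    55, tpm))
  expect_equal(nrow(call_tissue_specific(prof2, de, rel)), 0)
  # missing pair result is reported by name
  expect_error(call_tissue_specific(prof, dplyr::filter(de, time != 0), rel),
               "missing DE result")
})

test_that("tissue-switch detection finds early/late specificity changes", {
  calls <- tibble(gene_id = "g1", tissue = c("neuron", "neuron", "pharynx"),
                  time = c(0L, 1L, 3L), top_tpm = 100, second_tissue = "x",
                  second_tpm = 10, log2fc = 3, padj = 1e-4,
                  specific = FALSE)
  sw <- detect_tissue_switch(calls)
  expect_equal(sw$tissue_early, "neuron")
  expect_equal(sw$tissue_late, "pharynx")
  expect_equal(sw$time_late, 3L)
  single <- dplyr::filter(calls, tissue == "neuron")
  expect_equal(nrow(detect_tissue_switch(single)), 0)
})

test_that("synthetic specificity and switch programs are recovered", {
  cfg <- tiny_cfg(seed = 3, n_genes = 400, n_operons = 20)
  ann <- sim_annotation(cfg)
  ds <- sim_expression(cfg, ann)
  prof <- profile_means(compute_tpm(ds$counts, ann))
  de <- de_pairwise(ds$counts)
  calls <- call_tissue_specific(prof, de)
  down <- downstream_operon_genes(ann)
  sg <- dplyr::filter(specific_genes(calls), !gene_id %in% down)
  truth <- dplyr::filter(ds$truth, !gene_id %in% down)
  ts <- dplyr::filter(truth, program == "tissue_specific")
  expect_gte(mean(ts$gene_id %in% sg$gene_id), 0.9)
  expect_lte(mean(!sg$gene_id %in% ts$gene_id), 0.15)
  # exclusivity invariant: one tissue per gene and time among calls
  per_gt <- calls |> dplyr::count(gene_id, time)
  expect_true(all(per_gt$n == 1))
  sw <- detect_tissue_switch(calls)
  swt <- dplyr::filter(truth, program == "switch")
  expect_equal(mean(swt$gene_id %in% sw$gene_id), 1)
  stable_ids <- truth$gene_id[truth$program == "stable"]
  expect_equal(sum(sw$gene_id %in% stable_ids), 0)
})

test_that("stable genes require robustness and bounded fold range", {
  prof <- tidyr::expand_grid(gene_id = c("flat", "rising", "weak"),
                             tissue = "muscle", time = 0:4) |>
    dplyr::mutate(tpm = dplyr::case_when(
      gene_id == "flat" ~ 50,
      gene_id == "rising" ~ 5 + 48.75 * time,
      gene_id == "weak" ~ 5))
  st <- detect_stable(prof)
  expect_equal(st$stable_genes, "flat")
  cfg <- tiny_cfg(seed = 6, n_genes = 300, n_operons = 15)
  ann <- sim_annotation(cfg)
  ds <- sim_expression(cfg, ann)
  tpm <- compute_tpm(ds$counts, ann)
  st2 <- detect_stable(profile_means(tpm))
  tr <- ds$truth |>
    dplyr::filter(gene_id %in% robust_genes(tpm),
                  !program %in% c("histone", "rRNA"),
                  !gene_id %in% downstream_operon_genes(ann))
  sens <- mean(tr$gene_id[tr$program == "stable"] %in% st2$stable_genes)
  spec <- mean(!tr$gene_id[tr$program != "stable"] %in% st2$stable_genes)
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})

test_that("operon-stability table reproduces the published association", {
  analyzed <- sprintf("g%05d", 1:11408)
  stable <- analyzed[1:1572]
  operon <- c(analyzed[1:913], analyzed[(1572 + 1):(1572 + 3128 - 913)])
  res <- operon_stability_test(stable, operon, analyzed)
  expect_equal(unname(res$table[1, ]), c(913, 659))
  expect_equal(unname(res$table[2, ]), c(2215, 7621))
  expect_lt(res$p_value, 1e-5)
  expect_equal(round(res$pct_stable_in_operon), 58)
  expect_equal(round(res$pct_operon_in_analyzed), 27)
  # perfectly proportional membership is null
  an <- sprintf("x%03d", 1:200)
  res0 <- operon_stability_test(an[1:100], c(an[1:50], an[101:150]), an)
  expect_equal(res0$p_value, 1)
})

test_that("chi-squared p agrees with a permutation null on a small table", {
  analyzed <- sprintf("g%03d", 1:120)
  stable <- analyzed[1:30]
  operon <- c(analyzed[1:18], analyzed[31:60])
  res <- operon_stability_test(stable, operon, analyzed)
  set.seed(2)
  n_perm <- 4e3
  obs <- res$statistic
  perm <- purrr::map_dbl(seq_len(n_perm), function(i) {
    sh <- sample(analyzed, length(stable))
    suppressWarnings(operon_stability_test(sh, operon, analyzed)$statistic)
  })
  p_perm <- (sum(perm >= obs - 1e-9) + 1) / (n_perm + 1)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(res$p_value - p_perm), mc_err + 0.01)
})
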