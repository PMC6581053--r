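frag_row <- function(start, end, read_id, chrom = "chrI", strand = "+",
                     sample = "muscle:0:1") {
  tibble(sample = sample, chrom = chrom, strand = strand,
         start = as.integer(start), end = as.integer(end), read_id = read_id)
}

test_that("duplicate detection groups exact coordinates, keeps lowest id", {
  fr <- bind_rows(frag_row(10, 260, "r3"), frag_row(500, 750, "r1"),
                  frag_row(900, 1150, "r2"))
  det <- detect_duplicates(fr)
  expect_false(any(det$is_detected_duplicate))
  fr4 <- bind_rows(frag_row(10, 260, "r4"), frag_row(10, 260, "r2"),
                   frag_row(10, 260, "r3"), frag_row(10, 260, "r1"))
  det4 <- detect_duplicates(fr4)
  expect_equal(sum(det4$is_detected_duplicate), 3)
  expect_equal(det4$read_id[!det4$is_detected_duplicate], "r1")
})

test_that("grouping equals brute-force pairwise clustering on random input", {
  set.seed(42)
  n <- 200
  fr <- tibble(sample = "s:0:1", chrom = sample(c("chrI", "chrII"), n, TRUE),
               strand = sample(c("+", "-"), n, TRUE),
               start = sample(1:30, n, TRUE),
               end = sample(40:60, n, TRUE),
               read_id = sprintf("r%03d", 1:n))
  det <- detect_duplicates(fr)
  # O(n^2) oracle: same group iff every coordinate field matches
  same <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    fr$chrom[i] == fr$chrom[j] && fr$strand[i] == fr$strand[j] &&
      fr$start[i] == fr$start[j] && fr$end[i] == fr$end[j]
  }))
  oracle_group <- apply(same, 1, function(x) min(which(x)))
  expect_equal(as.integer(factor(det$dup_group)),
               as.integer(factor(oracle_group)))
  # one representative per group
  reps <- det |> dplyr::filter(!is_detected_duplicate) |> dplyr::count(dup_group)
  expect_true(all(reps$n == 1))
  expect_setequal(reps$dup_group, unique(det$dup_group))
})

test_that("rate is zero without ties and errors without low-coverage windows", {
  fr <- purrr::map_dfr(1:30, function(i) frag_row(i * 5000, i * 5000 + 250,
                                                  sprintf("r%02d", i)))
  est <- estimate_dup_rate(fr)
  expect_equal(est$rate, 0)
  dense <- purrr::map_dfr(1:200, function(i) frag_row(i, i + 250,
                                                      sprintf("r%03d", i)))
  expect_error(estimate_dup_rate(dense, window = 1e6), "low-coverage")
})

test_that("estimator recovers the simulated rate in low-coverage windows", {
  cfg <- tiny_cfg(seed = 7, n_genes = 300, n_operons = 15, dup_rate = 0.25)
  ann <- sim_annotation(cfg)
  fr <- sim_fragments(cfg, ann, n_fragments = 1e5)
  est <- estimate_dup_rate(fr, ann)
  expect_lt(abs(est$rate - 0.25), 0.02)
  # the naive global fraction is inflated by chance collisions
  expect_lte(est$rate, naive_dup_fraction(fr)$naive_rate)
})

test_that("estimator error shrinks with library size", {
  cfg <- tiny_cfg(seed = 13, n_genes = 300, n_operons = 15, dup_rate = 0.25)
  ann <- sim_annotation(cfg)
  errs <- purrr::map_dbl(c(1e3, 1e4, 1e5), function(nf) {
    mean(purrr::map_dbl(1:3, function(s) {
      cfg_s <- tiny_cfg(seed = 100 + s, n_genes = 300, n_operons = 15,
                        dup_rate = 0.25)
      abs(estimate_dup_rate(sim_fragments(cfg_s, ann, n_fragments = nf),
                            ann)$rate - 0.25)
    }))
  })
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("proportional removal applies the window formula exactly", {
  # one high-coverage window: N = 100 fragments over 40 distinct coordinates,
  # D = 60 detected duplicates, rate 0.2 -> round(0.2 * 100) = 20 removed
  coords <- tibble(start = seq(10, 400, by = 10))
  fr <- bind_rows(
    purrr::map_dfr(1:40, function(i) frag_row(coords$start[i],
                                              coords$start[i] + 50,
                                              sprintf("a%03d", i))),
    purrr::map_dfr(1:60, function(i) {
      j <- (i - 1) %% 40 + 1
      frag_row(coords$start[j], coords$start[j] + 50, sprintf("b%03d", i))
    }))
  est <- tibble(sample = "muscle:0:1", rate = 0.2, n_low_fragments = 10L,
                n_low_duplicates = 2L, low_cov_threshold = 10,
                window = 1000)
  kept <- remove_duplicates(fr, est, seed = 3)
  expect_equal(nrow(fr) - nrow(kept), 20)
  # representatives all survive
  expect_true(all(sprintf("a%03d", 1:40) %in% kept$read_id))
})

test_that("removal output is a subset keeping one fragment per group", {
  cfg <- tiny_cfg(seed = 14, n_genes = 200, n_operons = 10, dup_rate = 0.35)
  ann <- sim_annotation(cfg)
  fr <- sim_fragments(cfg, ann, n_fragments = 2e4)
  det <- detect_duplicates(fr)
  est <- estimate_dup_rate(det, ann)
  kept <- remove_duplicates(det, est, seed = 5)
  expect_true(all(kept$read_id %in% fr$read_id))
  groups_in <- dplyr::n_distinct(det$dup_group)
  groups_out <- dplyr::n_distinct(detect_duplicates(kept)$dup_group)
  expect_equal(groups_out, groups_in)
  # rate 0 with no low-coverage duplicates leaves the input untouched
  fr0 <- purrr::map_dfr(1:20, function(i) frag_row(i * 3000, i * 3000 + 250,
                                                   sprintf("r%02d", i)))
  est0 <- estimate_dup_rate(fr0)
  expect_equal(nrow(remove_duplicates(fr0, est0, seed = 1)), nrow(fr0))
})

test_that("proportional removal beats naive removal in deep genes", {
  cfg <- tiny_cfg(seed = 21, n_genes = 300, n_operons = 15, dup_rate = 0.3)
  ann <- sim_annotation(cfg)
  fr <- sim_fragments(cfg, ann, n_fragments = 1e5)
  det <- detect_duplicates(fr)
  est <- estimate_dup_rate(det, ann)
  kept <- remove_duplicates(det, est, seed = 21)
  truth <- fr |> dplyr::filter(!is_pcr_duplicate) |>
    dplyr::count(gene_id, name = "true_n")
  d <- truth |>
    dplyr::left_join(dplyr::count(kept, gene_id, name = "prop_n"),
                     by = "gene_id") |>
    dplyr::left_join(det |> dplyr::filter(!is_detected_duplicate) |>
                       dplyr::count(gene_id, name = "naive_n"),
                     by = "gene_id") |>
    dplyr::mutate(dplyr::across(-gene_id, ~ dplyr::coalesce(., 0L))) |>
    dplyr::filter(true_n >= stats::quantile(true_n, 0.9))
  bias <- function(x) stats::median(abs(x / d$true_n - 1))
  expect_lt(bias(d$prop_n), bias(d$naive_n))
})
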