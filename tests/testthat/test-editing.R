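edit_ann <- function() {
  genome_annotation(
    genes = tribble(
      ~gene_id, ~chrom, ~strand, ~start, ~end, ~biotype,
      "plus", "chrI", "+", 1000L, 1300L, "coding",
      "minus", "chrI", "-", 2000L, 2300L, "coding"),
    exons = tribble(~gene_id, ~start, ~end,
                    "plus", 1000L, 1300L, "minus", 2000L, 2300L)
  )
}

pile <- function(pos, ref, sample, alt_n, cov = 30, chrom = "chrI") {
  alt_base <- c(A = "G", T = "C", C = "T", G = "A")[[ref]]
  counts <- stats::setNames(c(0L, 0L, 0L, 0L), c("A", "C", "G", "T"))
  counts[ref] <- cov - alt_n
  counts[alt_base] <- alt_n
  tibble(chrom = chrom, pos = as.integer(pos), ref = ref, sample = sample,
         A = counts[["A"]], C = counts[["C"]], G = counts[["G"]],
         T = counts[["T"]])
}

test_that("edit calling applies replication and unlabeled filters", {
  ann <- edit_ann()
  lab <- c("muscle:0:1", "muscle:0:2", "intestine:1:1")
  unl <- "muscle:0:1:unlabeled"
  pl <- dplyr::bind_rows(
    # replicated A>G in coding exon, clean unlabeled -> called
    purrr::map_dfr(lab, ~ pile(1100, "A", .x, alt_n = 10)),
    pile(1100, "A", unl, alt_n = 0),
    # single-sample support -> rejected
    pile(1150, "A", lab[1], alt_n = 10),
    pile(1150, "A", lab[2], alt_n = 0),
    # replicated but present in the unlabeled sort -> genomic variant
    purrr::map_dfr(lab, ~ pile(1200, "A", .x, alt_n = 12)),
    pile(1200, "A", unl, alt_n = 8),
    # minus-strand gene: T>C in reference coordinates is the A>G edit
    purrr::map_dfr(lab, ~ pile(2100, "T", .x, alt_n = 9)),
    # non-canonical mismatch, reported but never called
    purrr::map_dfr(lab, ~ pile(1250, "C", .x, alt_n = 9)),
    # outside any CDS -> skipped
    pile(5000, "A", lab[1], alt_n = 10))
  res <- call_edits(pl, ann)
  expect_setequal(res$calls$pos, c(1100L, 2100L))
  expect_equal(res$calls$alt[res$calls$pos == 2100], "C")
  expect_equal(res$calls$strand[res$calls$pos == 2100], "-")
  expect_true(all(res$calls$n_supporting >= 2))
  expect_equal(res$other_mismatch$pos, 1250L)
  expect_equal(res$n_outside_cds, 1)
})

test_that("thresholds gate coverage, reads and fraction per sample", {
  ann <- edit_ann()
  lab <- c("muscle:0:1", "muscle:0:2")
  low_cov <- dplyr::bind_rows(purrr::map_dfr(lab, ~ pile(1100, "A", .x,
                                                         alt_n = 3, cov = 8)))
  expect_equal(nrow(call_edits(low_cov, ann)$calls), 0)
  low_frac <- dplyr::bind_rows(purrr::map_dfr(lab, ~ pile(1100, "A", .x,
                                                          alt_n = 3,
                                                          cov = 40)))
  expect_equal(nrow(call_edits(low_frac, ann)$calls), 0)
  ok <- dplyr::bind_rows(purrr::map_dfr(lab, ~ pile(1100, "A", .x,
                                                    alt_n = 4, cov = 30)))
  expect_equal(nrow(call_edits(ok, ann)$calls), 1)
})

test_that("generator truth is recovered end to end at default thresholds", {
  cfg <- tiny_cfg(seed = 23, edit_sites = 10)
  ann <- sim_annotation(cfg)
  pe <- sim_pileups(cfg, ann)
  res <- call_edits(pe$pileups, ann)
  truth_key <- paste(pe$truth$chrom, pe$truth$pos)
  call_key <- paste(res$calls$chrom, res$calls$pos)
  true_sites <- truth_key[pe$truth$class == "true"]
  expect_equal(mean(true_sites %in% call_key), 1)
  expect_equal(sum(!call_key %in% true_sites), 0)
  # soundness: every call sits in a CDS with the canonical change
  cds_genes <- unique(ann$cds$gene_id)
  expect_true(all(res$calls$gene_id %in% cds_genes))
  expect_true(all((res$calls$strand == "+" & res$calls$ref == "A" &
                     res$calls$alt == "G") |
                    (res$calls$strand == "-" & res$calls$ref == "T" &
                       res$calls$alt == "C")))
})

test_that("codon consequences follow the standard genetic code", {
  # plus-strand gene, CDS = one exon; codons: ATG GGA TAT TGG ... TAA
  cds <- paste0("ATG", "GGA", "TAT", "TGG", strrep("GCT", 6), "TAA")
  ann <- genome_annotation(
    genes = tibble(gene_id = "g", chrom = "chrI", strand = "+",
                   start = 0L, end = nchar(cds), biotype = "coding"),
    exons = tibble(gene_id = "g", start = 0L, end = nchar(cds)))
  seqs <- c(g = cds)
  # third position of GGA (cds pos 5): GGA -> GGG, both glycine
  syn <- annotate_consequence(
    tibble(gene_id = "g", chrom = "chrI", pos = 5L, strand = "+",
           ref = "A", alt = "G"), ann, seqs)
  expect_equal(syn$consequence, "synonymous")
  expect_equal(syn$codon_edited, "GGG")
  # TAT -> TGT: tyrosine to cysteine
  mis <- annotate_consequence(
    tibble(gene_id = "g", chrom = "chrI", pos = 7L, strand = "+",
           ref = "A", alt = "G"), ann, seqs)
  expect_equal(mis$aa_ref, "Y")
  expect_equal(mis$aa_alt, "C")
  expect_equal(mis$consequence, "missense")
})

test_that("a premature stop reports the truncated tail length exactly", {
  # 100-codon protein + stop; TGG at codon 74 edited to TGA truncates
  # codons 74..100 = 27 amino acids
  codons <- c("ATG", rep("GCT", 72), "TGG", rep("GAA", 26), "TAA")
  cds <- paste(codons, collapse = "")
  ann <- genome_annotation(
    genes = tibble(gene_id = "g", chrom = "chrI", strand = "+",
                   start = 0L, end = nchar(cds), biotype = "coding"),
    exons = tibble(gene_id = "g", start = 0L, end = nchar(cds)))
  pos_edit <- (74L - 1L) * 3L + 2L   # third base of codon 74, 0-based
  res <- annotate_consequence(
    tibble(gene_id = "g", chrom = "chrI", pos = pos_edit, strand = "+",
           ref = "G", alt = "A"), ann, c(g = cds))
  # manual translation oracle
  expect_equal(Biostrings::GENETIC_CODE[["TGG"]], "W")
  expect_equal(res$codon_edited, "TGA")
  expect_equal(res$consequence, "stop_gained")
  expect_equal(res$truncated_aa, 27L)
})

test_that("minus-strand CDS positions map through spliced coordinates", {
  # '-' gene with two CDS exons; genomic pos in the left exon maps to the
  # far end of the spliced CDS
  ann <- genome_annotation(
    genes = tibble(gene_id = "m", chrom = "chrI", strand = "-",
                   start = 100L, end = 400L, biotype = "coding"),
    exons = tibble(gene_id = "m", start = c(100L, 300L),
                   end = c(200L, 400L)))
  # spliced CDS length 200; genomic 399 is coding position 0
  expect_equal(embryoflow:::cds_position(ann, "m", 399L), 0L)
  expect_equal(embryoflow:::cds_position(ann, "m", 300L), 99L)
  expect_equal(embryoflow:::cds_position(ann, "m", 199L), 100L)
  expect_equal(embryoflow:::cds_position(ann, "m", 100L), 199L)
  expect_true(is.na(embryoflow:::cds_position(ann, "m", 250L)))
})

test_that("known-site checks summarize support with verdicts", {
  pl <- dplyr::bind_rows(
    pile(100, "C", "muscle:0:1", alt_n = 0, cov = 700),
    pile(100, "C", "muscle:0:2", alt_n = 0, cov = 612),
    pile(200, "A", "muscle:0:1", alt_n = 8, cov = 30),
    pile(200, "A", "muscle:0:2", alt_n = 6, cov = 25),
    pile(300, "A", "muscle:0:1", alt_n = 1, cov = 40))
  sites <- tibble(chrom = "chrI", pos = c(100L, 200L, 300L, 400L),
                  ref = c("C", "A", "A", "A"), alt = c("T", "G", "G", "G"))
  rep_ <- check_known_sites(pl, sites)
  # 1312 reference reads -> no support for the catalogued C-to-U site
  expect_equal(rep_$coverage[rep_$pos == 100], 1312)
  expect_equal(rep_$verdict[rep_$pos == 100], "none")
  expect_equal(rep_$verdict[rep_$pos == 200], "strong")
  expect_equal(rep_$verdict[rep_$pos == 300], "weak")
  expect_equal(rep_$verdict[rep_$pos == 400], "none")
  expect_true(rep_$no_coverage[rep_$pos == 400])
})
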