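# embryoflow

Tissue- and time-resolved analysis of bulk RNA-seq from FACS-sorted
embryonic cell populations, modeled on the *C. elegans* embryo: seven
sorted populations (muscle, intestine, neurons, pharynx, hypodermis, and
the ABa/ABala lineages) sampled at five 90-minute intervals with matched
unlabeled sorts. Every gene becomes a 35-dimensional profile (7 tissues ×
5 time points, replicate-averaged), and the package provides the bespoke
stages such a study needs around a standard alignment core:

* **PCR-duplicate handling without UMIs** — the duplicate rate is
  estimated in low-coverage genome windows, where coordinate collisions
  between distinct molecules are rare, and removal in high-coverage
  windows is *proportional* (`min(D, round(rate × N))` per window) rather
  than remove-all, so highly expressed genes are not deflated by chance
  collisions.
* **Quantification** — gene-level TPM over union-exon lengths with
  histone/rRNA exclusion, `TPM_g = 10^6 (c_g/L_g) / Σ (c_{g'}/L_{g'})`,
  plus max1 normalization (each gene's peak sample scaled to 1) and an
  expression census (detected: TPM ≥ 1; robust: TPM ≥ 15).
* **Specificity logic** — per time point, the top tissue must beat the
  best *non-related* competitor (lineage-sharing populations are
  excluded) at log2FC ≥ 1 and adjusted p ≤ 0.1; plus tissue-switch genes,
  stably expressed genes (≤ 2-fold over time), and the stable × operon
  chi-squared association.
* **Fuzzy k-means clustering** of max1 profiles in 35-D (memberships
  `u ∝ (1/d²)^{1/(m−1)}`, `u^m`-weighted centroids, k-means++ seeding).
* **Splicing** — novel-intron classification with the 500-bp rule,
  SL1/SL2 trans-splice-site classification, exon-usage tests.
* **Operons and gene pairs** — 35-D expression distances by orientation
  (operon, head-to-head, head-to-tail, tail-to-tail, random), SL1
  fraction vs expression distance and SL2 vs expression trends, TF-peak
  clusters on downstream genes.
* **TF ChIP-peak enrichment** — Fisher tests of DE vs non-DE genes per
  (TF, tissue, time) with a signed −log10 p heatmap.
* **A-to-G RNA-editing calls** from pileups with replication and
  unlabeled-sample filters, and codon-consequence annotation.
* A fully seeded **synthetic-data generator** reproducing the design
  (programs, operons with internal promoters, PCR duplication, SL tags,
  enriched peaks, injected edits) so every stage is tested against ground
  truth.

## Worked example

```r
library(embryoflow)
library(dplyr)

cfg <- sim_config(seed = 1, n_genes = 300, n_operons = 15)
ann <- sim_annotation(cfg)
ds  <- sim_expression(cfg, ann)

# PCR duplicates: estimate in low-coverage windows, remove proportionally
frags <- sim_fragments(cfg, ann, n_fragments = 1e5)
(est <- estimate_dup_rate(frags, ann))
#>   sample      rate n_low_fragments n_low_duplicates low_cov_threshold window
#> 1 muscle:0:1 0.242            1058              256                10   1000
kept <- remove_duplicates(frags, est, seed = 1)
nrow(kept)  # 75689 of 99636 fragments survive (true rate was 0.25)

# quantify, call tissue-specific and stable genes, operon association
tpm   <- compute_tpm(ds$counts, ann)
prof  <- profile_means(tpm)
calls <- call_tissue_specific(prof, de_pairwise(ds$counts))
nrow(specific_genes(calls))
#> [1] 100
st  <- detect_stable(prof)
res <- operon_stability_test(st$stable_genes, unique(ann$operons$gene_id),
                             robust_genes(tpm))
res$table
#>            operon not_operon
#> stable         23         46
#> not_stable     21        201
sprintf("stable-in-operon %.0f%%, operon-overall %.0f%%, p = %.2g",
        res$pct_stable_in_operon, res$pct_operon_in_analyzed, res$p_value)
#> "stable-in-operon 33%, operon-overall 15%, p = 1.3e-06"

# cluster max1-normalized profiles in 35-D
x <- profile_matrix(
  max1_normalize(prof) |> semi_join(tibble(gene_id = robust_genes(tpm)),
                                    by = "gene_id"),
  tissues = cfg$tissues)
fit <- fuzzy_kmeans(x, k = 12, seed = 1)
generics::glance(fit)
#>       k     m iterations converged objective
#> 1    12     2         37 TRUE           48.6
generics::tidy(fit)      # gene -> cluster assignments
plot_cluster_heatmap(fit, x)
```

The duplicate estimate (0.242) recovers the generator's configured rate
(0.25) from low-coverage windows alone; the 2×2 table shows operon genes
over-represented among stably expressed genes (33% of stable genes are in
operons vs 15% of all analyzed genes), the association the chi-squared
test quantifies; and the fuzzy fit converges with a monotone objective.
`run_pipeline(pipeline_config(seed = 1), dir)` chains every stage and
writes per-stage TSVs plus a reproducibility manifest.

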