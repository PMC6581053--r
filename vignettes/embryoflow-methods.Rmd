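---
title: "Methods: tissue- and time-resolved embryonic RNA-seq analysis"
author: "embryoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue- and time-resolved embryonic RNA-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoflow)
library(dplyr)
```

# The setting

embryoflow analyzes bulk RNA-seq of FACS-sorted embryonic cell populations
collected as a time course: by default seven populations of the
*C. elegans* embryo (muscle, intestine, neurons, pharynx, hypodermis, and
the ABa and ABala lineages) sampled at five 90-minute intervals, with two
biological replicates per series (three for ABa, four for muscle) and a
matched unlabeled (reporter-negative) sort next to every labeled sample.
Each gene therefore has a 35-dimensional replicate-averaged expression
profile — seven tissues by five time points — and all comparative machinery
(clustering, gene-pair distances, specificity calls) operates in that
space.

The package provides the bespoke stages such a study needs around the
standard alignment/quantification core: PCR-duplicate handling without
UMIs, TPM with histone/rRNA exclusion, tissue-specificity and stability
calling, fuzzy k-means clustering, splice-leader (SL1/SL2) analysis,
operon and gene-pair regulatory statistics, ChIP-peak enrichment, and
A-to-G editing calls. A fully seeded synthetic-data generator reproduces
the statistical structure each stage assumes, so every stage is exercised
against ground truth.

# Coordinates and formats

Internally every interval is 0-based half-open. GFF3 (1-based inclusive)
and SAM (1-based positions) are converted at the reading boundary; BED
passes through unchanged. Multi-transcript genes collapse to union exons —
the union-exon length is the TPM length denominator — while per-transcript
bounds are kept because the novel-intron rule needs them. Operons are
encoded as `operon` features whose `genes` attribute lists members 5'→3'
in transcription direction.

# PCR-duplicate rate estimation and proportional removal

Without UMIs, read pairs with identical fragment coordinates are either
PCR duplicates or distinct molecules that collided by chance; the
collision probability grows with local coverage. Removing *every*
coordinate tie therefore deflates exactly the highly expressed genes one
most cares about. The package instead:

1. groups fragments by exact `(sample, chrom, strand, start, end)` —
   both mates' coordinates, not the read start alone — keeping the
   lexicographically smallest `read_id` as representative;
2. estimates the duplicate rate in **low-coverage windows** (1 kb tiles
   holding at most 10 *distinct fragment coordinates*), where collisions
   are rare so detected duplicates are almost all true PCR copies;
3. removes all detected duplicates in low-coverage windows and, in each
   high-coverage window with `N` fragments, `min(D, round(rate × N))` of
   the `D` detected duplicates, chosen uniformly at random under a seed.

Two numerical choices deserve a note. Window coverage is counted in
distinct coordinates, not raw fragments: conditioning on a low raw count
preferentially keeps windows whose molecules amplified little, which
biases the estimated rate downward (we measured roughly −0.04 at a true
rate of 0.25 under the fragment-count definition). Counting molecules
makes the conditioning independent of the amplification process. Second,
rRNA-gene windows are excluded from estimation; their extreme coverage
violates the rare-collision assumption and rRNA reads are discarded
downstream anyway.

On simulated libraries of 10^5 fragments the estimator's mean absolute
error is below 0.01 across true rates 0.1–0.4, and proportional removal
preserves the rank of per-gene counts among the top-decile (deep) genes
better than remove-all-duplicates, which can lose half of a short, deep
gene's reads to coordinate saturation.

# Quantification and normalization

TPM is computed at gene level over union-exon lengths:
`TPM_g = 1e6 (c_g/L_g) / Σ_{g'} (c_{g'}/L_{g'})`, with histone and rRNA
genes excluded from both the denominator and the reported values. Histone
messages are non-polyadenylated and can reach a third or more of early
fast-dividing samples, so leaving them in would make TPMs incomparable
across tissues and times; `histone_fraction()` reports their share per
sample as a QC statistic.

Replicate-averaged profiles (labeled samples only) feed two
normalizations: **max1**, dividing each gene's profile by its maximum so
the peak sample equals one (all-zero genes stay zero), used for
clustering and pattern distances; and per-exon max1 for exon-usage
heatmaps. The expression census uses TPM ≥ 1 (detected) and TPM ≥ 15
(robust), both inclusive; the per-sample bins are TPM ≤ 6, 6 < TPM < 100,
and TPM ≥ 100 — whether the published bins are open or closed at 6 and
100 is not documented, so the boundary convention here (6 falls in the
low bin, 100 in the high bin) is a package decision that keeps the three
bins a partition.

# Differential expression and specificity logic

`nb_test()` is a deliberately compact negative-binomial Wald test:
median-of-ratios size factors, method-of-moments dispersions shrunk
toward a `a0 + a1/μ` trend with 10 pseudo-replicates of prior weight, and
a delta-method variance for the log fold change. It is a stand-in with
documented behavior (simulated type-I under BH at `padj ≤ 0.1` is far
below 0.12; a 100-fold shift at dispersion 0.05 with 3v3 replicates is
always detected); externally computed tables (e.g. from DESeq2) can be
supplied to the specificity caller instead, which is where the
scientific logic lives.

A gene is called **tissue-specific** at a time point when its top tissue
beats the best *non-related* competitor at `log2FC ≥ 1` (pseudocount 1
TPM) and the pairwise test's `padj ≤ 0.1`. Related tissues — sorted
populations sharing cells by lineage, e.g. ABa contains pharyngeal,
hypodermal and neuronal precursors — are excluded from the competitor
search via a symmetric matrix shipped as an editable default.
**Tissue-switch** genes are called for one tissue early and a different,
non-related tissue strictly later. **Stable** genes are robust in a
tissue (max TPM ≥ 15) with max/min over time ≤ 2 (pseudocount 1);
"varied minimally" has no published definition, so the twofold default is
a package choice, configurable. The operon association test builds the
2×2 stable × operon table over analyzed genes and applies Pearson's
chi-squared without continuity correction.

# Fuzzy k-means clustering

Robust genes' max1 profiles are clustered by standard fuzzy c-means:
memberships `u_{gj} ∝ (1/d²_{gj})^{1/(m−1)}` normalized per gene,
centroids as `u^m`-weighted means, k-means++ seeding, stop at relative
objective change < 1e-6 or 500 iterations; the objective is
non-increasing by construction and a point coinciding with a centroid
gets membership one. Only `k` (default 60) and the max1 input are fixed
by the study design this mirrors; `m = 2`, the tolerance, the seeding and
the argmax assignment rule (ties to the lowest index) are package
defaults. `nstart` restarts keep the best objective; recovery tests use
five. Choosing `k` itself is out of scope — the package reports
within-cluster variance and leaves `k` to the analyst.
`embed_profiles()` offers a deterministic PCA projection to two
dimensions for visualization only; no quantitative claim rests on the
embedding.

# Splicing, splice leaders, operons and gene pairs

Observed junctions are classified against the annotation with a 500-bp
rule: `confirmed` (exact annotated intron), `novel_internal` (wholly
inside one transcript), `extension` (within 500 bp of a transcript
boundary), `novel_distal` (farther than 500 bp from everything, or
spanning two or more transcripts' boundaries). The classes partition all
junctions.

SL sites keep `sl1 + sl2 ≥ 2` reads and are `both` when each leader has
at least 2 reads, otherwise the majority leader wins; both thresholds are
configurable since the original criteria are not published. Gene-level
SL1 fraction is count-weighted (pooled reads, not a mean of per-site
fractions). In operons, SL2 marks processing of the polycistronic
precursor and SL1 marks independent initiation, so two trends are
diagnostic of internal promoters in downstream genes: SL1 fraction rising
with the 35-D expression distance to the upstream gene, and SL2 fraction
falling as downstream expression rises. Both are summarized with quintile
bins and unbinned Spearman correlations.

Adjacent gene pairs are classified head-to-head (divergent, 5' ends
facing), head-to-tail (same strand) or tail-to-tail; consecutive operon
members form their own class and pairs touching downstream operon genes
are excluded from the adjacency classes. Distances default to max1
profiles (scale-free, matching the clustering input; raw-TPM mode is
available) and class comparisons use Welch's t-test. A seeded random-pair
baseline completes the picture.

# TF ChIP-peak enrichment

A TF is assigned to a gene when a peak overlaps the strand-aware promoter
window `[TSS − 1000, TSS + 200)` — the published peak-to-gene association
is not specified, so the window is explicit and configurable. Each
(TF, tissue, time) cell contrasts DE genes against non-DE robust genes
with a two-sided Fisher exact test; a seeded permutation p-value is
available as a cross-check of the parametric choice. The heatmap shows
`−log10 p` for enrichment and `+log10 p` (negative) for depletion, masks
cells with `p > 0.01`, and drops TFs that are never significant. Base 10
is a package choice; the published figure does not state its base.

# RNA editing

Candidate edits are A→G on the transcribed strand (observed T→C in
reference coordinates on minus-strand genes), restricted to annotated
CDS. A call requires per-sample coverage ≥ 10, ≥ 3 alternate reads and
alternate fraction ≥ 0.1 in at least two labeled samples, and zero
alternate reads in every matched unlabeled sample — a site altered in the
unlabeled sort is a genomic variant, not an edit. Mismatch classes other
than the canonical change are reported separately and never called. The
numeric thresholds are package defaults (the original pipeline's are not
published) and all are configurable. Coding consequences recompute the
affected codon under the standard genetic code; premature stops report
the number of residues truncated. `check_known_sites()` audits a
catalogue of previously reported sites with none/weak/strong verdicts.

# The synthetic-data generator

`sim_config()` freezes the study conditions: 7 tissues × 5 time points,
replicates (2/3/4 by tissue), matched unlabeled sorts, 600 genes in 30
operons by default, program mix 20% maternal decay / 25% broad zygotic
rise / 30% tissue-specific / 20% stable / 5% tissue switch, NB dispersion
0.05, PCR duplicate rate 0.25, and log-normal library sizes around
120,000 fragment pairs. The real study averages 12 million pairs per
sample; the generator emulates that depth in proportion at desk scale —
large enough that a two-replicate design has the power the recovery
analyses assume, small enough that a full pipeline run takes seconds.

Design features worth knowing when interpreting test results:

* **Programs and composition.** True mean TPM surfaces are built per
  program and renormalized per condition so included genes sum to 10^6 —
  TPM is compositional, so a drift shared by many genes cancels. For that
  reason the off-target "leakage" of restricted programs drifts over time
  with a per-gene random direction (emulating sorting contamination that
  tracks the zygotic wave), which survives renormalization.
* **Operons.** Operon genes are housekeeping-like (stable-biased
  programs, tight baseline spread). A downstream member's mRNA is a fixed
  read-through fraction (0.7) of the first gene's profile plus an
  independent tissue-specific component scaled by the gene's
  internal-promoter strength `s ~ U(0,1)`; its SL1 fraction is
  binomial with probability `s`. Expression distance, downstream
  expression and SL1 usage are therefore linked exactly as the operon
  analyses assume.
* **Head-to-head sharing.** Divergent neighbor pairs share their program
  with probability 0.7, giving the orientation analysis its signal. The
  TF-enrichment null check runs with sharing disabled, because genes
  sharing both a promoter region and a peak are not independent units
  under a Fisher null.
* **Fragments.** Unique fragments are placed uniformly over gene bodies
  with heavy-tailed per-gene weights (log-normal, sdlog 2.5) and
  near-fixed fragment length (sd 1 bp); each molecule is amplified
  `k ~ Geometric(1 − dup_rate)` extra times. The narrow length
  distribution deliberately shrinks the fragment coordinate space so that
  deep genes saturate it at desk scale the way they do at 12M-pair depth
  — this is what makes the duplicate problem nontrivial and is the regime
  the estimator exists for. Positional bias within genes is not modeled.
* **Edits.** True A→G sites appear in three labeled samples and no
  unlabeled one; decoys (genomic-variant mimics) also appear in unlabeled
  samples; singletons appear once; two non-A→G sites exercise the
  mismatch filter. The generator is built to the caller's default
  thresholds, so full recovery demonstrates filter soundness, not
  threshold robustness on real data.

What passing tests therefore show — and do not show: the recovery suites
demonstrate that each stage inverts the generative structure it assumes
(NB counts, geometric amplification, binomial SL admixture, promoter
windows). Real libraries add positional coverage bias, isoform mixtures,
mapping artifacts and batch structure that the generator intentionally
omits; conclusions about those require real data.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run simulations at 150–600
genes, 8–40 operons and 10^5-fragment libraries, with 8–50 seeds per
simulation study — sizes chosen so a full check completes in minutes on a
laptop while keeping every recovery margin wide. All stages are
deterministic given a seed; `run_pipeline()` derives per-stage seeds from
one global seed by stable hashing of stage names, so stage outputs do not
depend on execution order, and two runs with the same config are
byte-identical.

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(seed = 1,
                       sim = list(n_genes = 300, n_operons = 15),
                       clustering = list(k = 12))
res <- run_pipeline(cfg, dir = "run1")
res$dedup$estimate
res$operon_test$p_value
generics::glance(res$model)
```

# Known limitations

* `nb_test()` is a two-group Wald test, not a GLM over the full design;
  time-course spline models are out of scope.
* The exon-usage test pools counts per group (no replicate dispersion);
  it flags candidates rather than providing calibrated inference, and
  external tables can be substituted.
* SL leader identification from raw reads (matching clipped 5' bases) is
  upstream of this package; per-leader counts are consumed as given.
* The related-tissue matrix ships as a lineage-derived default and should
  be edited for any other sorting design.
* Editing calls apply no alignment-level artifact filters (splice-site
  proximity, homopolymers) beyond the CDS restriction.
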