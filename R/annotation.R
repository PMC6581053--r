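#' Construct a genome annotation
#'
#' The coordinate substrate shared by every pipeline stage. All coordinates
#' are 0-based half-open `[start, end)` on the internal side; readers convert
#' GFF3 (1-based inclusive) and SAM (1-based) at the boundary, BED passes
#' through.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `strand` (`"+"/"-"`),
#'   `start`, `end`, `biotype` (one of `"coding"`, `"histone"`, `"rRNA"`,
#'   `"other"`).
#' @param exons Tibble `gene_id`, `start`, `end`: the union exon set per gene
#'   (multi-transcript genes are collapsed to union exons for counting).
#' @param transcripts Tibble `transcript_id`, `gene_id`, `start`, `end`.
#'   Transcript bounds are retained per mRNA for the 500-bp novel-intron
#'   rule even though exons are collapsed. Defaults to one transcript
#'   spanning each gene.
#' @param cds Tibble `gene_id`, `start`, `end` of coding intervals; defaults
#'   to the exons of coding genes.
#' @param operons Tibble `operon_id`, `gene_id`, `position` (1 = first gene
#'   in transcription direction). May be `NULL`.
#' @param chrom_lengths Named numeric vector or tibble `chrom`, `length`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, exons, transcripts = NULL, cds = NULL,
                              operons = NULL, chrom_lengths = NULL) {
  genes <- tibble::as_tibble(genes)
  exons <- tibble::as_tibble(exons)
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end", "biotype") %in%
                  names(genes)))
  if (anyDuplicated(genes$gene_id)) {
    rlang::abort("gene identifiers must be unique")
  }
  if (!all(exons$gene_id %in% genes$gene_id)) {
    rlang::abort("exon with unknown gene_id")
  }
  if (is.null(transcripts)) {
    transcripts <- tibble::tibble(
      transcript_id = paste0(genes$gene_id, ".t1"),
      gene_id = genes$gene_id, start = genes$start, end = genes$end
    )
  }
  if (is.null(cds)) {
    coding <- genes$gene_id[genes$biotype == "coding"]
    cds <- dplyr::filter(exons, .data$gene_id %in% coding)
  }
  if (!is.null(operons)) {
    operons <- tibble::as_tibble(operons)
    if (!all(operons$gene_id %in% genes$gene_id)) {
      rlang::abort("operon member gene does not exist in annotation")
    }
    sizes <- dplyr::count(operons, .data$operon_id)
    if (any(sizes$n < 2)) rlang::abort("operons must have >= 2 members")
  } else {
    operons <- tibble::tibble(operon_id = character(), gene_id = character(),
                              position = integer())
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- if (nrow(genes) == 0) {
      tibble::tibble(chrom = character(), length = numeric())
    } else {
      genes |>
        dplyr::group_by(.data$chrom) |>
        dplyr::summarise(length = max(.data$end) + 1000L, .groups = "drop")
    }
  } else if (!is.data.frame(chrom_lengths)) {
    chrom_lengths <- tibble::tibble(chrom = names(chrom_lengths),
                                    length = unname(chrom_lengths))
  }
  # exons inside gene bounds and sorted/disjoint per gene
  ex <- dplyr::arrange(exons, .data$gene_id, .data$start)
  chk <- ex |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(ok = all(.data$end > .data$start) &&
                       all(diff(.data$start) >= 0) &&
                       all(.data$start[-1] >= .data$end[-dplyr::n()]),
                     .groups = "drop")
  if (!all(chk$ok)) {
    rlang::abort(paste0("overlapping or malformed exons in gene ",
                        chk$gene_id[!chk$ok][1]))
  }
  structure(
    list(genes = genes, exons = ex, transcripts = tibble::as_tibble(transcripts),
         cds = tibble::as_tibble(cds), operons = operons,
         chrom_lengths = tibble::as_tibble(chrom_lengths)),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", nrow(x$genes), " genes, ",
      nrow(x$exons), " union exons, ",
      dplyr::n_distinct(x$operons$operon_id), " operons, ",
      nrow(x$chrom_lengths), " chromosomes\n", sep = "")
  invisible(x)
}

#' Gene table with strand-aware TSS/TES and promoter windows
#'
#' @param ann A `genome_annotation`.
#' @param upstream,downstream Promoter window extent around the TSS, in bp
#'   (strand-aware; default `[tss - 1000, tss + 200)` on the transcribed
#'   strand). The window is clipped at zero.
#' @return Tibble of genes with `tss`, `tes`, `prom_start`, `prom_end` added.
#' @export
gene_promoters <- function(ann, upstream = 1000, downstream = 200) {
  g <- ann$genes
  plus <- g$strand == "+"
  tss <- ifelse(plus, g$start, g$end)
  tes <- ifelse(plus, g$end, g$start)
  prom_start <- ifelse(plus, tss - upstream, tss - downstream)
  prom_end <- ifelse(plus, tss + downstream, tss + upstream)
  dplyr::mutate(g, tss = tss, tes = tes,
                prom_start = pmax(0, prom_start), prom_end = prom_end)
}

#' Union-exon gene lengths
#'
#' Gene length is the sum of the union exon intervals, the gene-level
#' surrogate used as the TPM length denominator.
#'
#' @param ann A `genome_annotation`.
#' @return Tibble `gene_id`, `length`.
#' @export
gene_lengths <- function(ann) {
  ann$exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(length = sum(.data$end - .data$start), .groups = "drop")
}

#' Annotated introns
#'
#' Gaps between consecutive union exons of each gene, as 0-based half-open
#' intervals.
#'
#' @param ann A `genome_annotation`.
#' @return Tibble `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
annotated_introns <- function(ann) {
  ann$exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::reframe(intron_start = utils::head(.data$end, -1),
                   intron_end = .data$start[-1]) |>
    dplyr::rename(start = "intron_start", end = "intron_end") |>
    dplyr::filter(.data$end > .data$start) |>
    dplyr::left_join(dplyr::select(ann$genes, "gene_id", "chrom", "strand"),
                     by = "gene_id") |>
    dplyr::select("gene_id", "chrom", "strand", "start", "end")
}

#' Consecutive operon gene pairs
#'
#' @param ann A `genome_annotation`.
#' @return Tibble `operon_id`, `gene_a` (upstream), `gene_b` (downstream).
#' @export
operon_pairs <- function(ann) {
  ann$operons |>
    dplyr::arrange(.data$operon_id, .data$position) |>
    dplyr::group_by(.data$operon_id) |>
    dplyr::reframe(gene_a = .data$gene_id[-dplyr::n()],
                   gene_b = .data$gene_id[-1])
}

#' Downstream operon genes
#'
#' All operon members after the first gene in transcription direction; these
#' receive SL2 trans-splicing predominantly and are treated separately in the
#' gene-pair orientation analysis.
#'
#' @param ann A `genome_annotation`.
#' @return Character vector of gene ids.
#' @export
downstream_operon_genes <- function(ann) {
  ann$operons$gene_id[ann$operons$position > 1]
}
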