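#' Read a genome annotation from GFF3
#'
#' Parses `gene`, `mRNA`, `exon` and `CDS` features (via rtracklayer) into a
#' [genome_annotation()]. GFF3 1-based inclusive coordinates are converted to
#' the internal 0-based half-open convention at this boundary. Gene biotype
#' is taken from a `biotype` attribute (default `coding`). Operons are read
#' from `operon` features carrying a `genes` attribute (comma-separated
#' member ids, 5'->3' in transcription direction), or from a sidecar TSV
#' with columns `operon_id`, `gene_id`, `position`.
#'
#' Multi-transcript genes collapse to the union exon set; transcript bounds
#' are retained per mRNA.
#'
#' @param path Path to a GFF3 file.
#' @param operons Optional path to an operon sidecar TSV.
#' @return A `genome_annotation`.
#' @export
read_annotation <- function(path, operons = NULL) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   rlang::abort(paste0("malformed GFF3 '", path, "': ",
                                       conditionMessage(e)))
                 })
  if (length(gr) == 0) {
    rlang::warn("empty annotation file")
    return(genome_annotation(
      genes = tibble::tibble(gene_id = character(), chrom = character(),
                             strand = character(), start = integer(),
                             end = integer(), biotype = character()),
      exons = tibble::tibble(gene_id = character(), start = integer(),
                             end = integer())
    ))
  }
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = purrr::map_chr(as.list(gr$Parent), ~ if (length(.x)) .x[[1]] else NA_character_),
    biotype = if (!is.null(gr$biotype)) as.character(gr$biotype) else NA_character_,
    genes_attr = if (!is.null(gr$genes)) {
      # multi-value attributes arrive comma-split
      purrr::map_chr(as.list(gr$genes), paste, collapse = ",")
    } else NA_character_
  )
  genes <- df |>
    dplyr::filter(.data$type == "gene") |>
    dplyr::transmute(gene_id = .data$id, chrom = .data$chrom,
                     strand = .data$strand, start = .data$start,
                     end = .data$end,
                     biotype = dplyr::coalesce(.data$biotype, "coding"))
  tx <- df |>
    dplyr::filter(.data$type %in% c("mRNA", "transcript")) |>
    dplyr::transmute(transcript_id = .data$id, gene_id = .data$parent,
                     start = .data$start, end = .data$end)
  tx2gene <- stats::setNames(tx$gene_id, tx$transcript_id)
  subfeat <- function(ty) {
    df |>
      dplyr::filter(.data$type == ty) |>
      dplyr::transmute(
        gene_id = dplyr::if_else(.data$parent %in% names(tx2gene),
                                 unname(tx2gene[.data$parent]), .data$parent),
        start = .data$start, end = .data$end) |>
      dplyr::distinct() |>
      collapse_union()
  }
  exons <- subfeat("exon")
  cds <- subfeat("CDS")
  bad <- exons |>
    dplyr::left_join(dplyr::select(genes, "gene_id", g_start = "start",
                                   g_end = "end"), by = "gene_id") |>
    dplyr::filter(.data$start < .data$g_start | .data$end > .data$g_end)
  if (nrow(bad) > 0) {
    rlang::abort(paste0("exon outside gene bounds for ", bad$gene_id[1]))
  }
  op <- NULL
  op_feat <- dplyr::filter(df, .data$type == "operon")
  if (nrow(op_feat) > 0) {
    op <- op_feat |>
      dplyr::transmute(operon_id = .data$id, genes_attr = .data$genes_attr) |>
      dplyr::mutate(gene_id = stringr::str_split(.data$genes_attr, ",")) |>
      tidyr::unnest("gene_id") |>
      dplyr::group_by(.data$operon_id) |>
      dplyr::mutate(position = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::select("operon_id", "gene_id", "position")
  }
  if (!is.null(operons)) {
    op <- readr::read_tsv(operons, show_col_types = FALSE,
                          col_types = readr::cols(position = "i"))
  }
  genome_annotation(genes = genes, exons = exons,
                    transcripts = if (nrow(tx)) tx else NULL,
                    cds = if (nrow(cds)) cds else NULL, operons = op)
}

# merge overlapping/adjacent intervals per gene
collapse_union <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv |>
    dplyr::arrange(.data$gene_id, .data$start) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                        default = -1L))) |>
    dplyr::group_by(.data$gene_id, .data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select(-"grp")
}

#' Write a genome annotation to GFF3
#'
#' Inverse of [read_annotation()]: emits gene / mRNA / exon / CDS features
#' (union exons attached to the gene's first transcript) plus `operon`
#' features, converting back to 1-based inclusive coordinates.
#'
#' @param ann A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  lines <- "##gff-version 3"
  g <- ann$genes
  lines <- c(lines, sprintf(
    "%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
    g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$biotype))
  tx <- dplyr::left_join(ann$transcripts,
                         dplyr::select(g, "gene_id", "chrom", "strand"),
                         by = "gene_id")
  lines <- c(lines, sprintf(
    "%s\t.\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
    tx$chrom, tx$start + 1L, tx$end, tx$strand, tx$transcript_id, tx$gene_id))
  first_tx <- tx |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  emit <- function(iv, ty) {
    iv <- iv |>
      dplyr::left_join(dplyr::select(first_tx, "gene_id", "transcript_id",
                                     "chrom", "strand"), by = "gene_id")
    sprintf("%s\t.\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
            iv$chrom, ty, iv$start + 1L, iv$end, iv$strand, iv$transcript_id)
  }
  lines <- c(lines, emit(ann$exons, "exon"), emit(ann$cds, "CDS"))
  if (nrow(ann$operons) > 0) {
    ops <- ann$operons |>
      dplyr::arrange(.data$operon_id, .data$position) |>
      dplyr::group_by(.data$operon_id) |>
      dplyr::summarise(genes = paste(.data$gene_id, collapse = ","),
                       .groups = "drop") |>
      dplyr::left_join(
        ann$operons |>
          dplyr::left_join(g, by = "gene_id") |>
          dplyr::group_by(.data$operon_id) |>
          dplyr::summarise(chrom = .data$chrom[1], strand = .data$strand[1],
                           start = min(.data$start), end = max(.data$end),
                           .groups = "drop"),
        by = "operon_id")
    lines <- c(lines, sprintf(
      "%s\t.\toperon\t%d\t%d\t.\t%s\t.\tID=%s;genes=%s",
      ops$chrom, ops$start + 1L, ops$end, ops$strand, ops$operon_id, ops$genes))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read aligned fragments
#'
#' Accepts either a fragment TSV (columns `sample`, `chrom`, `strand`,
#' `start`, `end`, `read_id`; 0-based half-open) or a minimal SAM dialect
#' (plain text; header, FLAG, POS and TLEN are honored). In SAM mode one
#' fragment is emitted per properly paired primary pair, taken from the
#' leftmost mate (`TLEN > 0`): the fragment is `[POS - 1, POS - 1 + TLEN)`
#' and its strand is that of read 1 (`+` when the leftmost mate is first in
#' pair, `-` otherwise). Secondary (0x100) and supplementary (0x800)
#' alignments are excluded; unpaired reads are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param path Input path; format detected from content (`@`-header or
#'   `.sam` extension means SAM).
#' @param sample Sample key to assign in SAM mode (SAM carries no sample
#'   column).
#' @return Tibble `sample`, `chrom`, `strand`, `start`, `end`, `read_id`.
#' @export
read_fragments <- function(path, sample = "sample:0:1") {
  first <- readLines(path, n = 1)
  is_sam <- grepl("\\.sam$", path) || startsWith(first, "@")
  if (!is_sam) {
    frags <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("sample", "chrom", "strand", "start", "end", "read_id")
    if (!all(need %in% names(frags))) {
      rlang::abort("fragment TSV must have columns sample, chrom, strand, start, end, read_id")
    }
    return(dplyr::select(frags, dplyr::all_of(need)))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), read_id = character()))
  }
  f <- stringr::str_split_fixed(lines, "\t", 10)
  flag <- as.integer(f[, 2])
  pos <- as.integer(f[, 4])
  tlen <- as.integer(f[, 9])
  primary <- bitwAnd(flag, 0x100) == 0 & bitwAnd(flag, 0x800) == 0
  paired <- bitwAnd(flag, 0x1) != 0 & bitwAnd(flag, 0x2) != 0
  keep <- primary & paired & tlen > 0
  n_skipped <- sum(primary & !(paired & abs(tlen) > 0))
  out <- tibble::tibble(
    sample = sample,
    chrom = f[keep, 3],
    strand = ifelse(bitwAnd(flag[keep], 0x40) != 0, "+", "-"),
    start = pos[keep] - 1L,
    end = pos[keep] - 1L + tlen[keep],
    read_id = f[keep, 1]
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write fragments to TSV
#'
#' @param frags Fragment tibble as returned by [read_fragments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  readr::write_tsv(frags[, c("sample", "chrom", "strand", "start", "end",
                             "read_id")], path)
  invisible(path)
}

#' Read ChIP-seq peaks from BED
#'
#' BED is natively 0-based half-open and passes through unchanged. The TF
#' name is taken from BED column 4 unless `tf` is given for the whole file.
#' Input need not be sorted; output is sorted by (chrom, start).
#'
#' @param path BED3+ file.
#' @param tf Optional TF name overriding column 4.
#' @return Tibble `tf`, `chrom`, `start`, `end`.
#' @export
read_peaks <- function(path, tf = NULL) {
  if (length(readLines(path, n = 1)) == 0) {
    return(tibble::tibble(tf = character(), chrom = character(),
                          start = integer(), end = integer()))
  }
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::start(gr) < 1)) rlang::abort("negative BED coordinate")
  name <- if (!is.null(tf)) tf
  else if (!is.null(gr$name)) as.character(gr$name)
  else NA_character_
  tibble::tibble(
    tf = name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
    end = GenomicRanges::end(gr)
  ) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Write peaks to BED
#' @param peaks Tibble `tf`, `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", peaks$chrom, peaks$start, peaks$end,
                     peaks$tf), path)
  invisible(path)
}

#' Read and write expression matrices
#'
#' On disk an expression matrix is a TSV with a `gene_id` column and one
#' column per sample, headed by the sample key (`tissue:time:rep[:unlabeled]`).
#' In memory it is a long tibble with parsed key columns.
#'
#' @param path File path.
#' @param value_name Name for the value column (`"count"` or `"tpm"`).
#' @return `read_expression_matrix()`: a long tibble `gene_id`, `sample`,
#'   `tissue`, `time`, `rep`, `labeled`, `<value_name>`.
#' @export
read_expression_matrix <- function(path, value_name = "count") {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  long <- tidyr::pivot_longer(wide, -"gene_id", names_to = "sample",
                              values_to = value_name)
  keys <- parse_sample_key(unique(long$sample))
  dplyr::left_join(long, keys, by = "sample") |>
    dplyr::relocate(dplyr::all_of(value_name), .after = dplyr::last_col())
}

#' @rdname read_expression_matrix
#' @param x Long expression tibble (must contain `gene_id`, `sample` and the
#'   value column).
#' @export
write_expression_matrix <- function(x, path, value_name = "count") {
  wide <- x |>
    dplyr::select("gene_id", "sample", dplyr::all_of(value_name)) |>
    tidyr::pivot_wider(names_from = "sample",
                       values_from = dplyr::all_of(value_name))
  readr::write_tsv(wide, path)
  invisible(path)
}
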