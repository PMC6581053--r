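#' Default tissue panel
#'
#' The seven sorted embryonic cell populations the pipeline is organised
#' around: five tissue/organ populations (muscle, intestine, neuron, pharynx,
#' hypodermis, marked in the worm by \emph{hlh-1}, \emph{end-1}, \emph{cnd-1},
#' \emph{pha-4} and \emph{nhr-25} reporters) and two lineage populations
#' (ABa, ABala).
#'
#' @return Character vector of tissue names, in canonical order.
#' @export
default_tissues <- function() {
  c("muscle", "intestine", "neuron", "pharynx", "hypodermis", "ABa", "ABala")
}

#' Encode and decode sample keys
#'
#' Samples are identified throughout the pipeline by the string
#' `tissue:time:rep` with an optional `:unlabeled` suffix for the matched
#' unlabeled (reporter-negative) sort collected alongside each labeled sample.
#' Time indices are 0-based (`0 .. n_times - 1`, 90-minute spacing by
#' default design).
#'
#' @param tissue,time,rep,labeled Vectors (recycled) describing the samples.
#' @return `format_sample_key()`: character vector of keys.
#'   `parse_sample_key()`: a tibble with columns `sample`, `tissue`, `time`,
#'   `rep`, `labeled`.
#' @examples
#' format_sample_key("muscle", 0, 1)
#' parse_sample_key(c("muscle:0:1", "ABa:4:2:unlabeled"))
#' @export
format_sample_key <- function(tissue, time, rep, labeled = TRUE) {
  key <- paste(tissue, time, rep, sep = ":")
  ifelse(labeled, key, paste0(key, ":unlabeled"))
}

#' @rdname format_sample_key
#' @param key Character vector of sample keys.
#' @export
parse_sample_key <- function(key) {
  parts <- stringr::str_split(key, stringr::fixed(":"))
  bad <- lengths(parts) < 3 | lengths(parts) > 4
  if (any(bad)) {
    rlang::abort(paste0("malformed sample key: ", key[bad][1]))
  }
  tibble::tibble(
    sample = key,
    tissue = purrr::map_chr(parts, 1),
    time = as.integer(purrr::map_chr(parts, 2)),
    rep = as.integer(purrr::map_chr(parts, 3)),
    labeled = !purrr::map_lgl(parts, ~ length(.x) == 4 && .x[4] == "unlabeled")
  )
}

#' Related-tissue matrix
#'
#' Sorted populations can share cells by lineage (the ABa lineage contains
#' pharyngeal, hypodermal and neuronal precursors; ABala contains neurons;
#' the \emph{ceh-32} marker used for ABala also labels some hypodermal
#' cells). Tissue pairs that share cells are excluded when searching for the
#' second-highest-expressing competitor in specificity calls. The default
#' matrix encodes those lineage overlaps; pass `pairs` to override.
#'
#' @param tissues Character vector of tissue names.
#' @param pairs A two-column data frame (or list of length-2 character
#'   vectors) of related pairs. Defaults to the lineage overlaps above when
#'   `tissues` is the default panel, otherwise to no overlaps.
#' @return A symmetric logical matrix with `TRUE` on the diagonal.
#' @export
related_tissue_matrix <- function(tissues = default_tissues(), pairs = NULL) {
  m <- diag(TRUE, length(tissues))
  dimnames(m) <- list(tissues, tissues)
  if (is.null(pairs) && setequal(tissues, default_tissues())) {
    pairs <- list(
      c("ABa", "pharynx"), c("ABa", "hypodermis"), c("ABa", "neuron"),
      c("ABa", "ABala"), c("ABala", "neuron"), c("ABala", "hypodermis")
    )
  }
  if (is.data.frame(pairs)) pairs <- purrr::transpose(pairs) |> purrr::map(unlist)
  for (p in pairs) {
    if (!all(p %in% tissues)) next
    m[p[1], p[2]] <- TRUE
    m[p[2], p[1]] <- TRUE
  }
  m
}
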