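#' Detect PCR duplicates by exact fragment coordinates
#'
#' Fragments (read pairs reduced to their outer coordinates) sharing an
#' identical (sample, chrom, strand, start, end) tuple form one duplicate
#' group. Within each group the fragment with the lexicographically smallest
#' `read_id` is the kept representative; the remaining `group_size - 1`
#' members are detected duplicates. Duplicate identity uses both fragment
#' ends, not the read start alone.
#'
#' @param frags Fragment tibble (`sample`, `chrom`, `strand`, `start`,
#'   `end`, `read_id`).
#' @return The input with columns `dup_group` (integer group id per sample)
#'   and `is_detected_duplicate` added.
#' @export
detect_duplicates <- function(frags) {
  key <- paste(frags$sample, frags$chrom, frags$strand, frags$start,
               frags$end, sep = "\r")
  o <- order(key, frags$read_id, method = "radix")
  det <- logical(nrow(frags))
  det[o] <- duplicated(key[o])
  dplyr::mutate(frags, dup_group = match(key, unique(key)),
                is_detected_duplicate = det)
}

#' Estimate the PCR duplicate rate from low-coverage windows
#'
#' The genome is tiled into fixed windows; windows holding at most
#' `low_cov` distinct fragment coordinates are "low-coverage" regions where
#' coincidental coordinate collisions between distinct molecules are rare,
#' so detected duplicates there are almost all true PCR duplicates. The
#' rate is the detected-duplicate fraction among fragments whose window is
#' low-coverage. Coverage is counted in distinct coordinates, not raw
#' fragments: conditioning on a low raw count would select against heavily
#' amplified molecules and bias the rate downward.
#' Windows overlapping rRNA genes are excluded: their extreme coverage
#' violates the rare-by-chance assumption (and rRNA reads are discarded
#' downstream anyway).
#'
#' @param frags Fragments of one or more samples.
#' @param ann Optional `genome_annotation` used only to mask rRNA windows.
#' @param window Window size in bp (default 1000).
#' @param low_cov Maximum fragments per window for the window to count as
#'   low-coverage (default 10).
#' @return Tibble per sample: `sample`, `rate`, `n_low_fragments`,
#'   `n_low_duplicates`, `low_cov_threshold`, `window`.
#' @export
estimate_dup_rate <- function(frags, ann = NULL, window = 1000,
                              low_cov = 10) {
  stopifnot(low_cov > 0)
  det <- if (!"is_detected_duplicate" %in% names(frags)) {
    detect_duplicates(frags)
  } else frags
  det <- dplyr::mutate(det, win = floor(.data$start / window))
  if (!is.null(ann)) {
    rr <- dplyr::filter(ann$genes, .data$biotype == "rRNA")
    if (nrow(rr) > 0) {
      rr_win <- purrr::map_dfr(seq_len(nrow(rr)), function(i) {
        tibble::tibble(chrom = rr$chrom[i],
                       win = seq(floor(rr$start[i] / window),
                                 floor((rr$end[i] - 1) / window)))
      })
      det <- dplyr::anti_join(det, rr_win, by = c("chrom", "win"))
    }
  }
  est <- det |>
    dplyr::group_by(.data$sample, .data$chrom, .data$win) |>
    dplyr::mutate(win_n = dplyr::n_distinct(.data$dup_group)) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_low_fragments = sum(.data$win_n <= low_cov),
      n_low_duplicates = sum(.data$is_detected_duplicate[.data$win_n <= low_cov]),
      .groups = "drop") |>
    dplyr::mutate(rate = .data$n_low_duplicates / .data$n_low_fragments,
                  low_cov_threshold = low_cov, window = window) |>
    dplyr::relocate("rate", .after = "sample")
  if (any(est$n_low_fragments == 0)) {
    rlang::abort(paste0(
      "no fragments in low-coverage windows for sample ",
      est$sample[est$n_low_fragments == 0][1],
      "; increase low_cov or window size"))
  }
  est
}

#' Remove PCR duplicates, proportionally in high-coverage regions
#'
#' In low-coverage windows every detected duplicate is removed. In each
#' high-coverage window with `N` fragments and `D` detected duplicates,
#' `r = min(D, round(rate * N))` duplicates are removed, chosen uniformly at
#' random (seeded) among the detected duplicates. Representatives are never
#' removed, so at least one fragment survives per duplicate group. Removing
#' only the expected number, rather than every coordinate collision,
#' avoids deflating the counts of highly expressed genes where distinct
#' molecules collide by chance.
#'
#' @param frags Fragment tibble.
#' @param est Estimate from [estimate_dup_rate()] for the same sample(s).
#' @param seed Seed for the uniform draw in high-coverage windows.
#' @return The retained fragments (input columns only).
#' @export
remove_duplicates <- function(frags, est, seed = 1) {
  cols <- names(frags)[!names(frags) %in%
                         c("dup_group", "is_detected_duplicate", "win")]
  det <- if (!"is_detected_duplicate" %in% names(frags)) {
    detect_duplicates(frags)
  } else frags
  window <- est$window[1]
  low_cov <- est$low_cov_threshold[1]
  rates <- stats::setNames(est$rate, est$sample)
  det <- det |>
    dplyr::mutate(win = floor(.data$start / window)) |>
    dplyr::group_by(.data$sample, .data$chrom, .data$win) |>
    dplyr::mutate(win_n = dplyr::n(),
                  win_groups = dplyr::n_distinct(.data$dup_group)) |>
    dplyr::ungroup()
  with_seed(seed, {
    drop <- det |>
      dplyr::mutate(.row = dplyr::row_number()) |>
      dplyr::filter(.data$is_detected_duplicate) |>
      dplyr::group_by(.data$sample, .data$chrom, .data$win) |>
      dplyr::group_modify(function(d, key) {
        if (nrow(d) == 0) return(d)
        if (d$win_groups[1] <= low_cov) return(d)  # all duplicates go
        r <- min(nrow(d), round(rates[[key$sample]] * d$win_n[1]))
        d[sample.int(nrow(d), r), ]
      }) |>
      dplyr::ungroup()
  })
  out <- det |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::filter(!.data$.row %in% drop$.row)
  out[, cols]
}

#' @describeIn estimate_dup_rate Naive global detected-duplicate fraction
#'   (inflated by chance collisions wherever coverage is high).
#' @export
naive_dup_fraction <- function(frags) {
  det <- if (!"is_detected_duplicate" %in% names(frags)) {
    detect_duplicates(frags)
  } else frags
  det |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(naive_rate = mean(.data$is_detected_duplicate),
                     .groups = "drop")
}
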