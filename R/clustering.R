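#' Fuzzy k-means (c-means) clustering
#'
#' Soft clustering of max1-normalized expression profiles by alternating
#' fuzzy c-means updates: memberships
#' `u_gj \propto (1 / d_gj^2)^(1 / (m - 1))` normalized over clusters, and
#' centroids as the `u^m`-weighted row means. Initial centroids are chosen
#' k-means++ style (seeded). Iteration stops when the relative change of the
#' objective `J = sum_g sum_j u_gj^m d_gj^2` falls below `tol` or after
#' `max_iter` sweeps; `J` is non-increasing by construction. A point that
#' coincides with a centroid gets membership 1 there.
#'
#' @param x Numeric matrix, genes in rows (typically a [profile_matrix()] of
#'   max1 values in 35 dimensions).
#' @param k Number of clusters (default 60).
#' @param m Fuzziness exponent > 1 (default 2; near 1 approaches hard
#'   k-means).
#' @param seed Seed for initialization.
#' @param tol Relative objective tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @param nstart Number of seeded restarts; the fit with the lowest final
#'   objective is kept (default 1).
#' @return Object of class `fuzzy_kmeans`: `centroids` (k x p),
#'   `membership` (n x k, rows sum to 1), `objective` (trace over
#'   iterations), `k`, `m`, `iterations`, `converged`.
#' @export
fuzzy_kmeans <- function(x, k = 60, m = 2, seed = 1, tol = 1e-6,
                         max_iter = 500, nstart = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0) rlang::abort("empty input matrix")
  if (k > n) rlang::abort("k exceeds the number of rows")
  if (m <= 1) rlang::abort("fuzziness exponent m must be > 1")
  if (nstart > 1) {
    fits <- lapply(seq_len(nstart), function(i) {
      fuzzy_kmeans(x, k = k, m = m, seed = seed + i - 1, tol = tol,
                   max_iter = max_iter, nstart = 1)
    })
    objs <- vapply(fits, function(f) utils::tail(f$objective, 1), numeric(1))
    return(fits[[which.min(objs)]])
  }
  centroids <- with_seed(seed, kmeanspp_init(x, k))
  obj <- numeric()
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist(x, centroids)
    u <- memberships_from_d2(d2, m)
    um <- u^m
    obj[it] <- sum(um * d2)
    centroids <- crossprod(um, x) / colSums(um)
    if (it > 1 && abs(obj[it - 1] - obj[it]) / max(obj[it], 1e-300) < tol) {
      break
    }
  }
  rownames(centroids) <- NULL
  structure(list(centroids = centroids, membership = u, objective = obj,
                 k = k, m = m, iterations = length(obj),
                 converged = length(obj) < max_iter,
                 gene_ids = rownames(x), colnames = colnames(x)),
            class = "fuzzy_kmeans")
}

# squared Euclidean distances, n x k
sq_dist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  pmax(d2, 0)
}

memberships_from_d2 <- function(d2, m) {
  w <- d2^(-1 / (m - 1))
  zero <- d2 < 1e-300
  hit <- rowSums(zero) > 0
  w[hit, ] <- zero[hit, , drop = FALSE] * 1
  w / rowSums(w)
}

# k-means++ seeding: spread initial centroids by squared-distance sampling
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- apply(sq_dist(x, x[idx, , drop = FALSE]), 1, min)
    d2[idx] <- 0
    idx <- c(idx, if (sum(d2) > 0) {
      sample.int(n, 1, prob = d2)
    } else sample.int(n, 1))
  }
  x[idx, , drop = FALSE]
}

#' @export
print.fuzzy_kmeans <- function(x, ...) {
  cat("<fuzzy_kmeans> k =", x$k, ", m =", x$m, ",", nrow(x$membership),
      "genes,", x$iterations, "iterations, J =",
      signif(utils::tail(x$objective, 1), 6), "\n")
  invisible(x)
}

#' Hard cluster assignments from a fuzzy model
#'
#' Each gene goes to its highest-membership cluster; ties break to the
#' lowest cluster index.
#'
#' @param model A [fuzzy_kmeans()] fit.
#' @return Tibble `gene_id`, `cluster` (1-based), `membership` (the winning
#'   membership value).
#' @export
assign_clusters <- function(model) {
  u <- model$membership
  cl <- apply(u, 1, which.max)  # which.max takes the first (lowest) on ties
  tibble::tibble(
    gene_id = model$gene_ids %||% as.character(seq_len(nrow(u))),
    cluster = as.integer(cl),
    membership = u[cbind(seq_len(nrow(u)), cl)])
}

#' Characterize clusters
#'
#' Labels each cluster with its enriched tissue (a tissue whose mean
#' centroid block exceeds the runner-up block at least `enrich_fold`-fold),
#' its temporal trend from the centroid's time slope (rising / falling /
#' flat), and the fraction of member genes in supplied stable and broad
#' sets.
#'
#' @param model A [fuzzy_kmeans()] fit on a tissue-major
#'   [profile_matrix()].
#' @param assignments From [assign_clusters()].
#' @param stable_genes,broad_genes Optional gene-id vectors.
#' @param enrich_fold Fold threshold for tissue enrichment (default 2).
#' @return Tibble per cluster: `cluster`, `n_genes`, `enriched_tissue`
#'   (`NA` when none), `trend`, `stable_fraction`, `broad_fraction`.
#' @export
characterize_clusters <- function(model, assignments, stable_genes = NULL,
                                  broad_genes = NULL, enrich_fold = 2) {
  cols <- stringr::str_split_fixed(model$colnames, ":", 2)
  tissues <- cols[, 1]
  times <- as.numeric(cols[, 2])
  purrr::map_dfr(seq_len(model$k), function(j) {
    cen <- model$centroids[j, ]
    block <- tapply(cen, tissues, mean)
    block <- sort(block, decreasing = TRUE)
    enriched <- if (block[1] >= enrich_fold * max(block[2], 1e-9)) {
      names(block)[1]
    } else NA_character_
    slope <- stats::coef(stats::lm(cen ~ times))[2]
    span <- max(cen) - min(cen)
    trend <- if (abs(slope) * (max(times) - min(times)) < 0.1 * max(span, 1e-9)) {
      "flat"
    } else if (slope > 0) "rising" else "falling"
    members <- assignments$gene_id[assignments$cluster == j]
    tibble::tibble(
      cluster = j, n_genes = length(members), enriched_tissue = enriched,
      trend = trend,
      stable_fraction = if (is.null(stable_genes) || !length(members)) {
        NA_real_
      } else mean(members %in% stable_genes),
      broad_fraction = if (is.null(broad_genes) || !length(members)) {
        NA_real_
      } else mean(members %in% broad_genes))
  })
}

#' 2-D embedding of expression profiles
#'
#' Principal-component projection of the profile matrix onto two dimensions,
#' for visualizing cluster structure. Deterministic given the input.
#'
#' @param x Profile matrix (genes x dimensions).
#' @param seed Unused for PCA; kept so callers can treat embeddings
#'   uniformly.
#' @return Matrix genes x 2 with the same rownames as `x`.
#' @export
embed_profiles <- function(x, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) == 0) rlang::abort("empty input matrix")
  p <- stats::prcomp(x, rank. = 2)
  out <- p$x[, 1:2, drop = FALSE]
  colnames(out) <- c("dim1", "dim2")
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fuzzy k-means fit
#'
#' @param x A `fuzzy_kmeans` object.
#' @param ... Unused.
#' @return One row per gene: `gene_id`, `cluster`, `membership`.
#' @export
tidy.fuzzy_kmeans <- function(x, ...) {
  assign_clusters(x)
}

#' @rdname tidy.fuzzy_kmeans
#' @return `glance()`: one row with `k`, `m`, `iterations`, `converged`,
#'   `objective`.
#' @export
glance.fuzzy_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, m = x$m, iterations = x$iterations,
                 converged = x$converged,
                 objective = utils::tail(x$objective, 1))
}
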