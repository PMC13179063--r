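#' Embedding backends
#'
#' A backend is any function `(x, n_neighbors, metric, seed) -> n x 2
#' coordinate matrix` that is deterministic given `seed`. Two backends ship
#' with the package: `umap_backend()` wraps [uwot::umap()] (stochastic;
#' seeded through R's RNG; exact k-NN is used since input cohorts are small,
#' other parameters stay at uwot defaults unless overridden), and
#' `pca_backend()` projects onto the first two principal components
#' (deterministic; `seed` and `n_neighbors` are ignored), which is useful as
#' a stub when the stochastic optimizer is not under test.
#'
#' @param ... additional arguments forwarded to [uwot::umap()].
#' @return A backend function.
#' @export
umap_backend <- function(...) {
  extra <- list(...)
  function(x, n_neighbors, metric, seed) {
    set.seed(seed)
    args <- c(list(X = x, n_neighbors = n_neighbors, metric = metric,
                   nn_method = "fnn", n_threads = 1, ret_nn = TRUE), extra)
    res <- do.call(uwot::umap, args)
    unname(res$embedding)
  }
}

#' @rdname umap_backend
#' @export
pca_backend <- function() {
  function(x, n_neighbors, metric, seed) {
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    unname(p$x[, 1:2, drop = FALSE])
  }
}

#' Ensemble embedding distance matrix
#'
#' Individual stochastic embeddings depend on their seed, so the embedding
#' is repeated `n_repeats` times and the per-pair 2D Euclidean distances are
#' averaged across repeats. No per-repeat rescaling is applied by default
#' (embedding scale is arbitrary per run; set `rescale = TRUE` for a
#' unit-RMS normalization of each repeat's distances before averaging).
#'
#' @param data a `normalized_matrix` or plain matrix (brains x regions).
#' @param n_repeats number of embeddings to average (default 20).
#' @param n_neighbors neighborhood size; defaults to `floor(n/3)` (a global
#'   view), with a minimum of 2.
#' @param metric distance metric passed to the backend.
#' @param backend a backend function, see [umap_backend()].
#' @param seeds integer vector of per-repeat seeds (default `1:n_repeats`).
#' @param rescale logical; normalize each repeat's distance matrix to unit
#'   root-mean-square before averaging.
#' @param store_coords keep the per-repeat 2D coordinates in the result.
#' @return An object of class `ensemble_distance`: `mean_distance`
#'   (symmetric, zero-diagonal), `n_repeats`, `embed_params`, and optionally
#'   `per_repeat_coords`.
#' @export
ensemble_embed <- function(data, n_repeats = 20, n_neighbors = NULL,
                           metric = "euclidean", backend = umap_backend(),
                           seeds = NULL, rescale = FALSE,
                           store_coords = FALSE) {
  x <- as_values_matrix(data)
  n <- nrow(x)
  if (is.null(n_neighbors)) n_neighbors <- max(2L, as.integer(floor(n / 3)))
  if (n_neighbors < 2)
    stop_inputmap("n_neighbors must be >= 2", "inputmap_argument_error")
  if (n_neighbors >= n)
    stop_inputmap("n_neighbors must be smaller than the number of brains",
                  "inputmap_argument_error")
  if (is.null(seeds)) seeds <- seq_len(n_repeats)
  stopifnot(length(seeds) == n_repeats)
  acc <- matrix(0, n, n)
  coords_list <- if (store_coords) vector("list", n_repeats) else NULL
  for (r in seq_len(n_repeats)) {
    coords <- tryCatch(backend(x, n_neighbors, metric, seeds[r]),
                       error = function(e)
                         stop("embedding backend failed at repeat ", r, ": ",
                              conditionMessage(e), call. = FALSE))
    if (!is.matrix(coords) || nrow(coords) != n || ncol(coords) != 2)
      stop("backend contract violation at repeat ", r,
           ": expected an n x 2 coordinate matrix", call. = FALSE)
    d <- as.matrix(stats::dist(coords))
    if (rescale) d <- d / sqrt(mean(d^2))
    acc <- acc + d
    if (store_coords) coords_list[[r]] <- coords
  }
  mean_distance <- acc / n_repeats
  dimnames(mean_distance) <- list(rownames(x), rownames(x))
  structure(list(mean_distance = mean_distance, n_repeats = n_repeats,
                 per_repeat_coords = coords_list,
                 embed_params = list(n_neighbors = n_neighbors,
                                     metric = metric, rescale = rescale,
                                     seeds = seeds)),
            class = "ensemble_distance")
}

#' Correlogram leaf ordering of an ensemble distance matrix
#'
#' Rows of the mean-distance matrix are clustered agglomeratively (default
#' linkage: average, recorded in the output for auditability) using
#' Euclidean distances between rows — the construction used by clustered
#' heatmaps of pairwise-distance matrices. Returns the leaf order for
#' heatmap rendering together with the dendrogram.
#'
#' @param distance an `ensemble_distance` (or symmetric matrix).
#' @param labels optional per-brain labels, carried into the result.
#' @param linkage hclust linkage method.
#' @return list with `order` (index permutation), `hclust`, `linkage`,
#'   `labels`.
#' @export
correlogram <- function(distance, labels = NULL, linkage = "average") {
  m <- if (inherits(distance, "ensemble_distance")) distance$mean_distance
       else as.matrix(distance)
  if (!isSymmetric(unname(m), tol = 1e-9))
    stop_inputmap("distance matrix must be symmetric",
                  "inputmap_contract_violation")
  hc <- stats::hclust(stats::dist(m), method = linkage)
  list(order = hc$order, hclust = hc, linkage = linkage, labels = labels)
}
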