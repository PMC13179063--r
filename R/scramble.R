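#' Scramble permutation null for apparent group separation
#'
#' Calibrates the separation seen between conditions in PC space against a
#' null in which both the sample identities and the per-region percentage
#' values are destroyed: each permutation shuffles the group labels and
#' independently permutes every region column across brains, then the
#' separation statistic is recomputed in the PC1-PC2 plane of the scrambled
#' data. The empirical p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' Statistics: `"silhouette"` is the mean silhouette width of the labels in
#' the PC1-PC2 plane; `"between_within_ratio"` is the ratio of mean
#' between-group to mean within-group pairwise distance. Both increase with
#' separation.
#'
#' @param data a `fraction_matrix` (or plain matrix of percentages).
#' @param labels group labels (>= 2 groups, each >= 2 members).
#' @param n_perm number of permutations (>= 100).
#' @param statistic `"silhouette"` or `"between_within_ratio"`.
#' @param seed optional RNG seed.
#' @return list with `observed`, `null` (length `n_perm`), `p`, `statistic`.
#' @export
scramble_null <- function(data, labels, n_perm = 1000,
                          statistic = c("silhouette", "between_within_ratio"),
                          seed = NULL) {
  statistic <- match.arg(statistic)
  x <- as_values_matrix(data)
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop_inputmap("need at least 2 groups", "inputmap_argument_error")
  if (any(table(labels) < 2))
    stop_inputmap("separation statistic undefined for singleton groups",
                  "inputmap_argument_error")
  if (n_perm < 100)
    stop_inputmap("n_perm must be >= 100", "inputmap_argument_error")
  if (!is.null(seed)) set.seed(seed)

  observed <- separation_statistic(pc12(x), labels, statistic)
  n <- nrow(x)
  null <- vapply(seq_len(n_perm), function(i) {
    perm_labels <- labels[sample.int(n)]
    perm_x <- apply(x, 2, function(col) col[sample.int(n)])
    separation_statistic(pc12(perm_x), perm_labels, statistic)
  }, numeric(1))
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(observed = observed, null = null, p = p, statistic = statistic)
}

pc12 <- function(x) {
  z <- zscore_features(x)
  stats::prcomp(z$values, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
}

separation_statistic <- function(xy, labels, statistic) {
  if (statistic == "silhouette") {
    sil <- cluster::silhouette(as.integer(labels), stats::dist(xy))
    return(mean(sil[, "sil_width"]))
  }
  d <- as.matrix(stats::dist(xy))
  same <- outer(labels, labels, "==")
  ut <- upper.tri(d)
  mean(d[ut & !same]) / mean(d[ut & same])
}
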