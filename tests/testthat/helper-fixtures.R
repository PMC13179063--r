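voc <- default_vocabulary()

# Small count table over the full 22-region axis: counts placed in the first
# few regions, remainder zero-filled.
make_table <- function(counts_list, meta = NULL) {
  counts <- t(vapply(counts_list, function(x) {
    v <- stats::setNames(numeric(22), voc$canonical)
    v[seq_along(x)] <- x
    v
  }, numeric(22)))
  if (is.null(meta))
    meta <- data.frame(id = sprintf("b%02d", seq_along(counts_list)),
                       genotype = "DAT-Cre", anesthesia = "isoflurane",
                       treatment = "saline", stringsAsFactors = FALSE)
  input_count_table(counts, meta, voc)
}

write_counts_csv <- function(table, path = tempfile(fileext = ".csv")) {
  write_count_table(table, path)
  path
}

# Independent oracle: PCA via explicit eigendecomposition of the sample
# covariance matrix, with the same largest-|loading|-positive sign fix.
pca_eigen_oracle <- function(x, k) {
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / (nrow(x) - 1)
  e <- eigen(S, symmetric = TRUE)
  loadings <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  list(loadings = loadings,
       scores = xc %*% loadings,
       evr = (e$values / sum(e$values))[seq_len(k)])
}

# Independent oracle: Spearman rho by explicit average-ranking then the
# Pearson product-moment formula on the ranks.
spearman_brute <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Independent oracle: hypergeometric upper tail by direct pmf summation.
hyper_tail_oracle <- function(overlap, set_size, universe_size, n_hits) {
  ks <- overlap:min(set_size, n_hits)
  sum(choose(set_size, ks) * choose(universe_size - set_size, n_hits - ks)) /
    choose(universe_size, n_hits)
}

# Independent oracle: two-level portrait average with explicit pixel loops.
portrait_loop_oracle <- function(groups) {
  H <- nrow(groups[[1]][[1]]$values); W <- ncol(groups[[1]][[1]]$values)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    acc <- 0
    for (g in groups) {
      s <- 0
      for (grid in g) s <- s + grid$values[r, c]
      acc <- acc + s / length(g)
    }
    out[r, c] <- acc / length(groups)
  }
  out
}

two_condition_config <- function(seed, n = 12, effect = 1.0, ...) {
  cohort_config(
    n_per_condition = n,
    conditions = data.frame(genotype = "DAT-Cre", anesthesia = "isoflurane",
                            treatment = c("saline", "cocaine"),
                            stringsAsFactors = FALSE),
    effect_vectors = list(cocaine = c(GPe = effect, DStr = -effect)),
    seed = seed, ...)
}
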