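#' Principal component analysis of normalized input fractions
#'
#' Thin wrapper around [stats::prcomp()] that returns scores, unit-norm
#' loadings, and explained-variance ratios, with a deterministic sign
#' convention: each component is flipped so its largest-magnitude loading is
#' positive (component signs are otherwise arbitrary).
#'
#' @param data a `normalized_matrix` (or plain numeric matrix, brains x
#'   regions).
#' @param n_components number of components to retain; at most
#'   `min(brains - 1, regions)`.
#' @return An object of class `pca_result` with elements `scores` (brains x
#'   k), `loadings` (regions x k), `explained_variance_ratio`,
#'   `component_labels`, and pass-through `meta`.
#' @export
fit_pca <- function(data, n_components = 3) {
  x <- as_values_matrix(data)
  max_k <- min(nrow(x) - 1, ncol(x))
  if (n_components > max_k)
    stop_inputmap(paste0("n_components must be <= ", max_k),
                  "inputmap_argument_error")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  labels <- paste0("PC", seq_len(k))
  colnames(loadings) <- labels
  colnames(scores) <- labels
  evr <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr[seq_len(k)],
                 component_labels = labels,
                 meta = if (is.list(data)) data$meta else NULL),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "brains,", length(x$component_labels),
      "components\n")
  cat("Explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}

#' Group comparison of scores along one principal component
#'
#' Two groups are compared with an unpaired two-sided t test (pooled
#' variance); more than two with a one-way ANOVA. Pairwise t tests are run
#' only when the omnibus p-value is below `alpha`, with the requested
#' multiple-comparison correction: Sidak or Holm over all-pairs t tests,
#' Tukey's HSD, or Dunnett contrasts against a designated control group.
#'
#' @param scores numeric vector of per-brain scores on one component.
#' @param labels group labels (coerced to factor).
#' @param correction one of `"tukey"`, `"sidak"`, `"holm"`, `"dunnett"`.
#' @param control_group control level, required for Dunnett.
#' @param alpha omnibus gate for pairwise testing (default 0.05).
#' @param pc_index optional component index recorded in the result.
#' @return An object of class `group_test_result`: `omnibus` (statistic, p,
#'   method) and `pairwise` (data frame with raw and adjusted p-values).
#' @export
pc_group_test <- function(scores, labels,
                          correction = c("tukey", "sidak", "holm", "dunnett"),
                          control_group = NULL, alpha = 0.05, pc_index = NA) {
  correction <- match.arg(correction)
  labels <- factor(labels)
  sizes <- table(labels)
  if (length(sizes) < 2)
    stop_inputmap("need at least 2 groups", "inputmap_argument_error")
  if (any(sizes < 2))
    stop_inputmap(paste0("group(s) with fewer than 2 members: ",
                         paste(names(sizes)[sizes < 2], collapse = ", ")),
                  "inputmap_insufficient_sample")
  if (correction == "dunnett" && is.null(control_group))
    stop_inputmap("dunnett correction requires control_group",
                  "inputmap_argument_error")

  lv <- levels(labels)
  if (length(lv) == 2) {
    tt <- stats::t.test(scores[labels == lv[1]], scores[labels == lv[2]],
                        var.equal = TRUE)
    omnibus <- list(statistic = unname(tt$statistic), p = tt$p.value,
                    method = "unpaired t")
    pairwise <- data.frame(group1 = lv[1], group2 = lv[2],
                           p_raw = tt$p.value, p_adj = tt$p.value,
                           method = "t", stringsAsFactors = FALSE)
  } else {
    fit <- stats::aov(scores ~ labels)
    a <- summary(fit)[[1]]
    omnibus <- list(statistic = a[["F value"]][1], p = a[["Pr(>F)"]][1],
                    method = "one-way ANOVA")
    pairwise <- NULL
    if (omnibus$p < alpha)
      pairwise <- pairwise_tests(scores, labels, correction, control_group, fit)
  }
  structure(list(pc_index = pc_index, omnibus = omnibus, pairwise = pairwise,
                 correction = correction),
            class = "group_test_result")
}

pairwise_tests <- function(scores, labels, correction, control_group, fit) {
  lv <- levels(labels)
  if (correction == "dunnett") {
    if (!control_group %in% lv)
      stop_inputmap("control_group not among group labels",
                    "inputmap_argument_error")
    labels <- stats::relevel(labels, ref = control_group)
    fit <- stats::aov(scores ~ labels)
    # glht p-values come from randomized multivariate-t quadrature; pin the
    # stream locally so reruns are byte-identical.
    gl <- with_fixed_seed(20211L, summary(
      multcomp::glht(fit, linfct = multcomp::mcp(labels = "Dunnett"))))
    comp <- names(gl$test$coefficients)
    others <- sub(" - .*$", "", comp)
    raw <- vapply(others, function(g) {
      stats::t.test(scores[labels == g], scores[labels == control_group],
                    var.equal = TRUE)$p.value
    }, numeric(1))
    return(data.frame(group1 = others, group2 = control_group,
                      p_raw = unname(raw),
                      p_adj = unname(as.vector(gl$test$pvalues)),
                      method = "dunnett", stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(lv, 2)
  raw <- apply(pairs, 2, function(pr)
    stats::t.test(scores[labels == pr[1]], scores[labels == pr[2]],
                  var.equal = TRUE)$p.value)
  if (correction == "tukey") {
    tk <- stats::TukeyHSD(fit)$labels
    key_tk <- rownames(tk)
    key <- paste(pairs[2, ], pairs[1, ], sep = "-")
    key2 <- paste(pairs[1, ], pairs[2, ], sep = "-")
    idx <- ifelse(key %in% key_tk, match(key, key_tk), match(key2, key_tk))
    adj <- tk[idx, "p adj"]
  } else if (correction == "sidak") {
    m <- ncol(pairs)
    adj <- pmin(1, 1 - (1 - raw)^m)
  } else {
    adj <- stats::p.adjust(raw, method = "holm")
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p_raw = raw,
             p_adj = unname(adj), method = correction,
             stringsAsFactors = FALSE)
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$omnibus$method,
              x$omnibus$statistic, x$omnibus$p))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' 1-SD condition ellipsoids in an embedding plane
#'
#' For each condition with at least two points, the ellipsoid is centered at
#' the condition's mean coordinate and stretched one standard deviation
#' (population convention) along the primary and secondary axes of the
#' condition's 2D scatter. Singleton conditions are skipped with a warning.
#'
#' @param points2d numeric matrix (n x 2) of embedding coordinates.
#' @param labels condition labels.
#' @return List of `condition_ellipsoid` objects (fields `condition`,
#'   `center`, `axes` 2x2 orthonormal columns, `radii`).
#' @export
condition_ellipsoid <- function(points2d, labels) {
  points2d <- as.matrix(points2d)
  stopifnot(ncol(points2d) == 2)
  labels <- factor(labels)
  out <- list()
  for (lv in levels(labels)) {
    pts <- points2d[labels == lv, , drop = FALSE]
    if (nrow(pts) < 2) {
      warning("skipping singleton condition: ", lv)
      next
    }
    center <- colMeans(pts)
    centered <- sweep(pts, 2, center)
    cov_pop <- crossprod(centered) / nrow(pts)
    e <- eigen(cov_pop, symmetric = TRUE)
    out[[lv]] <- structure(list(condition = lv, center = center,
                                axes = e$vectors,
                                radii = sqrt(pmax(0, e$values))),
                           class = "condition_ellipsoid")
  }
  out
}
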