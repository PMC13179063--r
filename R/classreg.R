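#' Gene-class regression against labeling ratios
#'
#' Tests whether the mean regional expression of a class of genes (ion
#' channels, neurotransmitter receptors, ...) predicts the condition-induced
#' change in RABV input labeling. Per region, the class score is the mean
#' over class genes of the log-normalized expression profile (`log_unit`
#' normalization of each gene's raw mean profile by default; the sigmoid
#' scale is available via `expression_scale`). Points pool regions across
#' all supplied condition deltas, pairing class score with the labeling
#' ratio; regions with undefined ratios are dropped. Pearson correlation
#' with a two-sided test is reported on the pooled points.
#'
#' @param atlas an `expression_atlas` (its `raw` per-gene mean profiles are
#'   used).
#' @param gene_class character vector of class member gene ids.
#' @param deltas a `condition_delta` or list of them (one per condition).
#' @param class_name label recorded in the result.
#' @param expression_scale `"log_unit"` (default) or `"scaled_sigmoid"`.
#' @return An object of class `class_regression_result`: `class`, `points`
#'   (region, condition, class_score, ratio), `r`, `p`, `n`.
#' @export
class_regression <- function(atlas, gene_class, deltas,
                             class_name = "class",
                             expression_scale = c("log_unit",
                                                  "scaled_sigmoid")) {
  expression_scale <- match.arg(expression_scale)
  if (inherits(deltas, "condition_delta")) deltas <- list(deltas)
  present <- intersect(gene_class, rownames(atlas$raw))
  if (length(present) < 2)
    stop_inputmap(paste0("fewer than 2 genes of class '", class_name,
                         "' present in the atlas"),
                  "inputmap_argument_error")
  profs <- t(apply(atlas$raw[present, , drop = FALSE], 1,
                   normalize_expression, method = expression_scale))
  score <- colMeans(profs)
  points <- do.call(rbind, lapply(seq_along(deltas), function(i) {
    d <- deltas[[i]]
    regions <- intersect(names(score), names(d$ratio))
    ok <- regions[is.finite(d$ratio[regions])]
    data.frame(region = ok, condition = d$experimental,
               class_score = unname(score[ok]), ratio = unname(d$ratio[ok]),
               stringsAsFactors = FALSE)
  }))
  if (stats::sd(points$class_score) == 0)
    stop_inputmap("class score is constant across regions",
                  "inputmap_degenerate_predictor")
  ct <- stats::cor.test(points$class_score, points$ratio)
  structure(list(class = class_name, points = points,
                 r = unname(ct$estimate), p = ct$p.value, n = nrow(points)),
            class = "class_regression_result")
}

#' @export
print.class_regression_result <- function(x, ...) {
  cat(sprintf("Class regression '%s': r = %.3f, p = %.3g (n = %d points)\n",
              x$class, x$r, x$p, x$n))
  invisible(x)
}

#' Read a two-column gene-class table
#'
#' CSV/TSV with columns `class`, `gene`.
#'
#' @param path file path.
#' @return Named list (by class) of gene-id vectors.
#' @export
read_gene_classes <- function(path) {
  df <- read_delim_auto(path)
  missing <- setdiff(c("class", "gene"), names(df))
  if (length(missing))
    stop_inputmap(paste0("missing gene-class column(s): ",
                         paste(missing, collapse = ", ")),
                  "inputmap_schema_error")
  split(df$gene, df$class)
}
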