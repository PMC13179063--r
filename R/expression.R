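#' Read long-format expression records
#'
#' CSV/TSV with columns `gene`, `experiment_id`, `plane`
#' (coronal/sagittal), `region`, `expression` (nonnegative, arbitrary
#' units). Regions may be Allen atlas codes (aggregated onto the merged
#' 20-region axis downstream) or merged codes directly.
#'
#' @param path file path.
#' @return data frame of expression records.
#' @export
read_expression_records <- function(path) {
  df <- read_delim_auto(path)
  need <- c("gene", "experiment_id", "plane", "region", "expression")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_inputmap(paste0("missing expression column(s): ",
                         paste(missing, collapse = ", ")),
                  "inputmap_schema_error")
  bad <- setdiff(unique(df$plane), c("coronal", "sagittal"))
  if (length(bad))
    stop_inputmap(paste0("unknown section plane(s): ",
                         paste(bad, collapse = ", ")),
                  "inputmap_value_error")
  if (any(!is.finite(df$expression)) || any(df$expression < 0))
    stop_inputmap("expression values must be finite and nonnegative",
                  "inputmap_value_error")
  df
}

# Per-(gene, experiment) profiles on the merged 20-region axis.
# Regions given as merged codes pass through on a fast path; Allen codes are
# averaged onto the merged axis via the vocabulary's atlas map.
experiment_profiles <- function(records, vocabulary = default_vocabulary()) {
  merged <- vocabulary$merged
  all_merged <- all(records$region %in% merged)
  key <- paste(records$gene, records$experiment_id, sep = "\r")
  if (all_merged) {
    # fast path: every experiment must cover every merged region exactly once
    ridx <- match(records$region, merged)
    counts <- table(key)
    if (all(counts == length(merged)) &&
        !anyDuplicated(paste(key, ridx, sep = "\r"))) {
      ord <- order(match(key, unique(key)), ridx)
      profiles <- matrix(records$expression[ord], ncol = length(merged),
                         byrow = TRUE)
      colnames(profiles) <- merged
      first <- ord[seq(1, length(ord), by = length(merged))]
      info <- data.frame(gene = records$gene[first],
                         experiment_id = records$experiment_id[first],
                         plane = records$plane[first],
                         stringsAsFactors = FALSE)
      return(list(info = info, profiles = profiles, regions = merged))
    }
  }
  chunks <- split(records, factor(key, levels = unique(key)))
  profiles <- lapply(chunks, function(ch) {
    v <- stats::setNames(ch$expression, ch$region)
    if (anyDuplicated(names(v)))
      v <- tapply(ch$expression, ch$region, mean)
    if (all(names(v) %in% merged)) {
      missing <- setdiff(merged, names(v))
      if (length(missing))
        stop_inputmap(paste0("experiment ", ch$experiment_id[1],
                             " missing region(s): ",
                             paste(missing, collapse = ", ")),
                      "inputmap_schema_error")
      v[merged]
    } else {
      aggregate_regions(v, vocabulary, mode = "atlas_average")
    }
  })
  info <- data.frame(
    gene = vapply(chunks, function(ch) ch$gene[1], ""),
    experiment_id = vapply(chunks, function(ch) ch$experiment_id[1], ""),
    plane = vapply(chunks, function(ch) ch$plane[1], ""),
    stringsAsFactors = FALSE)
  rownames(info) <- NULL
  list(info = info, profiles = do.call(rbind, profiles), regions = merged)
}

#' Quality filter for multi-experiment expression data
#'
#' A gene is retained if any of its experiments used coronal sections, or if
#' it has at least two experiments whose regional profiles agree: the mean
#' pairwise Pearson correlation over the regions of interest must exceed
#' `r_threshold`. Genes with a single sagittal experiment fail the filter
#' (logged, not an error).
#'
#' @param records long-format expression records (see
#'   [read_expression_records()]).
#' @param vocabulary a `region_vocabulary`; profiles are compared on its
#'   merged axis.
#' @param r_threshold concordance threshold (default 0.5).
#' @return list with `kept` (gene ids) and `log` (data frame gene / kept /
#'   reason).
#' @export
filter_genes <- function(records, vocabulary = default_vocabulary(),
                         r_threshold = 0.5) {
  ep <- experiment_profiles(records, vocabulary)
  genes <- unique(ep$info$gene)
  gene_index <- split(seq_len(nrow(ep$info)),
                      factor(ep$info$gene, levels = genes))
  log <- data.frame(gene = genes, kept = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    idx <- gene_index[[i]]
    if (any(ep$info$plane[idx] == "coronal")) {
      log$kept[i] <- TRUE; log$reason[i] <- "coronal"
    } else if (length(idx) >= 2) {
      profs <- ep$profiles[idx, , drop = FALSE]
      cors <- stats::cor(t(profs))
      mean_r <- mean(cors[upper.tri(cors)])
      if (is.finite(mean_r) && mean_r > r_threshold) {
        log$kept[i] <- TRUE
        log$reason[i] <- sprintf("concordant (mean r = %.3f)", mean_r)
      } else {
        log$reason[i] <- sprintf("discordant (mean r = %.3f)", mean_r)
      }
    } else {
      log$reason[i] <- "single sagittal experiment"
    }
  }
  list(kept = genes[log$kept], log = log)
}

#' Normalize a regional expression profile to \[0, 1\]
#'
#' `scaled_sigmoid` is a robust sigmoid: `1 / (1 + exp(-(x - median) /
#' (IQR / 1.35)))` followed by min-max rescaling to `[0, 1]` (median/IQR
#' make it robust to outliers; 1.35 converts IQR to an SD equivalent).
#' `log_unit` is `log(1 + x)` followed by min-max rescaling. Profiles with
#' zero IQR (or constant after transform) are degenerate and rejected.
#'
#' @param profile named per-region numeric vector.
#' @param method `"scaled_sigmoid"` (default) or `"log_unit"`.
#' @return Named numeric vector in `[0, 1]`.
#' @export
normalize_expression <- function(profile,
                                 method = c("scaled_sigmoid", "log_unit")) {
  method <- match.arg(method)
  if (method == "scaled_sigmoid") {
    if (length(unique(profile)) < 2)
      stop_inputmap("profile has fewer than 2 distinct values",
                    "inputmap_degenerate_profile")
    iqr <- stats::IQR(profile)
    if (iqr == 0)
      stop_inputmap("profile IQR is zero", "inputmap_degenerate_profile")
    s <- 1 / (1 + exp(-(profile - stats::median(profile)) / (iqr / 1.35)))
  } else {
    s <- log1p(profile)
  }
  rng <- range(s)
  if (rng[1] == rng[2])
    stop_inputmap("profile is constant after transform",
                  "inputmap_degenerate_profile")
  (s - rng[1]) / (rng[2] - rng[1])
}

#' Build a normalized expression atlas
#'
#' Applies the quality filter, aggregates each experiment's profile onto the
#' merged 20-region axis, normalizes each experiment profile (scaled
#' sigmoid by default), and averages over each gene's passing experiments.
#' Genes with degenerate (zero-IQR) profiles are excluded and logged. The
#' unnormalized per-gene mean profiles are kept alongside for analyses that
#' need raw-scale expression (gene-class regressions).
#'
#' @param records long-format expression records.
#' @param vocabulary a `region_vocabulary`.
#' @param method normalization method, see [normalize_expression()].
#' @param r_threshold concordance threshold for [filter_genes()].
#' @return An object of class `expression_atlas`: `matrix` (genes x 20,
#'   in `[0, 1]`), `raw` (genes x 20, unnormalized means), `kept_genes`,
#'   `filter_log`.
#' @export
build_expression_atlas <- function(records, vocabulary = default_vocabulary(),
                                   method = c("scaled_sigmoid", "log_unit"),
                                   r_threshold = 0.5) {
  method <- match.arg(method)
  flt <- filter_genes(records, vocabulary, r_threshold)
  ep <- experiment_profiles(records, vocabulary)
  gene_index <- split(seq_len(nrow(ep$info)), ep$info$gene)
  rows <- list(); raw_rows <- list(); degenerate <- character(0)
  for (g in flt$kept) {
    idx <- gene_index[[g]]
    profs <- ep$profiles[idx, , drop = FALSE]
    norm <- tryCatch(
      t(apply(profs, 1, normalize_expression, method = method)),
      inputmap_degenerate_profile = function(e) NULL)
    if (is.null(norm)) { degenerate <- c(degenerate, g); next }
    rows[[g]] <- colMeans(norm)
    raw_rows[[g]] <- colMeans(profs)
  }
  log <- flt$log
  if (length(degenerate)) {
    log$kept[log$gene %in% degenerate] <- FALSE
    log$reason[log$gene %in% degenerate] <- "degenerate profile (zero IQR)"
  }
  structure(list(matrix = do.call(rbind, rows),
                 raw = do.call(rbind, raw_rows),
                 kept_genes = names(rows), filter_log = log,
                 regions = vocabulary$merged, method = method),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat("Expression atlas:", length(x$kept_genes), "genes x",
      length(x$regions), "regions (", x$method, ")\n")
  invisible(x)
}

#' Condition-induced labeling change per region
#'
#' Per-region difference (`delta`) and quotient (`ratio`) of mean input
#' percentages between an experimental and a control cohort, on the merged
#' 20-region axis. Regions whose control mean is zero have an undefined
#' ratio and are listed in `undefined_regions`. `use_counts = TRUE` computes
#' the same quantities from raw count means instead of percentages.
#'
#' @param exp_fractions,ctrl_fractions `fraction_matrix` objects on the
#'   merged axis (see [merge_fractions()]), or `input_count_table`s when
#'   `use_counts = TRUE`.
#' @param labels optional `c(experimental, control)` condition labels.
#' @param use_counts use raw count means instead of percentage means.
#' @return An object of class `condition_delta` with `delta`, `ratio`,
#'   `undefined_regions`, `experimental`, `control`.
#' @export
condition_delta <- function(exp_fractions, ctrl_fractions, labels = NULL,
                            use_counts = FALSE) {
  get_mat <- function(obj) {
    if (use_counts && inherits(obj, "input_count_table")) return(obj$counts)
    as_values_matrix(obj)
  }
  em <- get_mat(exp_fractions); cm <- get_mat(ctrl_fractions)
  if (nrow(em) == 0 || nrow(cm) == 0)
    stop_inputmap("both sides need at least one brain",
                  "inputmap_argument_error")
  if (!identical(colnames(em), colnames(cm)))
    stop_inputmap("experimental and control region axes differ",
                  "inputmap_key_error")
  exp_mean <- colMeans(em); ctrl_mean <- colMeans(cm)
  delta <- exp_mean - ctrl_mean
  ratio <- ifelse(ctrl_mean > 0, exp_mean / ctrl_mean, NA_real_)
  structure(list(delta = delta, ratio = ratio,
                 exp_mean = exp_mean, ctrl_mean = ctrl_mean,
                 undefined_regions = names(ctrl_mean)[ctrl_mean == 0],
                 experimental = labels[1] %||% "experimental",
                 control = labels[2] %||% "control"),
            class = "condition_delta")
}

#' @export
print.condition_delta <- function(x, ...) {
  cat("Condition delta:", x$experimental, "vs", x$control, "over",
      length(x$delta), "regions\n")
  if (length(x$undefined_regions))
    cat("Undefined ratios:", paste(x$undefined_regions, collapse = ", "), "\n")
  invisible(x)
}

# Spearman rho and two-sided p: exact permutation enumeration for n <= 8,
# t approximation otherwise.
spearman_test <- function(x, y) {
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  if (n <= 8) {
    perms <- all_permutations(n)
    rx <- rank(x)
    ry <- rank(y)
    null_rho <- apply(perms, 1, function(p) stats::cor(rx[p], ry))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) return(list(rho = rho, p = 0))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub), n - 1), deparse.level = 0)
  }))
}

#' Genome-wide Spearman screen against a labeling change
#'
#' Correlates every atlas gene's regional expression profile with the
#' per-region labeling delta (Spearman, average-rank ties), and returns the
#' top `k` positively and negatively correlated genes (rank-based lists, no
#' multiplicity correction, mirroring top-k selection by correlation).
#' Constant expression profiles are skipped and logged.
#'
#' @param atlas an `expression_atlas`.
#' @param delta a `condition_delta` (or named per-region vector).
#' @param k size of the top lists (default 50).
#' @return An object of class `gene_screen_result`: `table` (gene, rho, p),
#'   `top_positive`, `top_negative`, `skipped`, `k`.
#' @export
gene_screen <- function(atlas, delta, k = 50) {
  d <- if (inherits(delta, "condition_delta")) delta$delta else delta
  m <- atlas$matrix
  common <- intersect(colnames(m), names(d))
  if (length(common) < 4)
    stop_inputmap("need at least 4 shared regions", "inputmap_argument_error")
  m <- m[, common, drop = FALSE]; d <- d[common]
  keep <- apply(m, 1, function(r) length(unique(r)) > 1)
  skipped <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  n <- ncol(m)
  if (n > 8) {
    # vectorized: Spearman = Pearson on average ranks, t approximation
    rm_ <- t(apply(m, 1, rank))
    rho <- as.vector(stats::cor(t(rm_), rank(d)))
    p <- ifelse(abs(rho) >= 1, 0,
                2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2))
    tab <- data.frame(gene = rownames(m), rho = rho, p = p,
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    res <- apply(m, 1, spearman_test, y = d)
    tab <- data.frame(gene = rownames(m),
                      rho = vapply(res, `[[`, 0, "rho"),
                      p = vapply(res, `[[`, 0, "p"),
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  pos <- tab[tab$rho > 0, ]
  neg <- tab[tab$rho < 0, ]
  top_positive <- pos$gene[order(-pos$rho)][seq_len(min(k, nrow(pos)))]
  top_negative <- neg$gene[order(neg$rho)][seq_len(min(k, nrow(neg)))]
  structure(list(table = tab, top_positive = top_positive,
                 top_negative = top_negative, skipped = skipped, k = k,
                 n_regions = length(common)),
            class = "gene_screen_result")
}

#' @export
print.gene_screen_result <- function(x, ...) {
  cat("Gene screen:", nrow(x$table), "genes over", x$n_regions, "regions\n")
  cat("Top positive:", paste(utils::head(x$top_positive, 5), collapse = ", "),
      "...\n")
  invisible(x)
}
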