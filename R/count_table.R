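#' Construct an input count table
#'
#' Container for per-brain RABV input counts over the canonical 22 regions
#' plus condition metadata. Counts are held as an integer matrix (brains x
#' regions, region order fixed by the vocabulary); metadata as a data frame
#' with one row per brain.
#'
#' @param counts numeric matrix, brains x 22 canonical regions, nonnegative
#'   integers, with column names matching the vocabulary.
#' @param meta data frame with columns `id`, `genotype`, `anesthesia`,
#'   `treatment` and optional `starter_ap`, `starter_ml` (mm).
#' @param vocabulary a `region_vocabulary`.
#' @return An object of class `input_count_table`.
#' @export
input_count_table <- function(counts, meta, vocabulary = default_vocabulary()) {
  counts <- as.matrix(counts)
  if (!setequal(colnames(counts), vocabulary$canonical))
    stop("count matrix columns must be exactly the 22 canonical regions")
  counts <- counts[, vocabulary$canonical, drop = FALSE]
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_inputmap("counts must be finite and nonnegative",
                  "inputmap_value_error")
  if (any(counts != round(counts)))
    stop_inputmap("counts must be integers", "inputmap_value_error")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (is.null(meta$id)) stop("meta must contain an 'id' column")
  if (nrow(meta) != nrow(counts))
    stop("meta and counts must describe the same brains")
  for (col in c("genotype", "anesthesia", "treatment"))
    if (is.null(meta[[col]])) meta[[col]] <- "unknown"
  for (col in c("starter_ap", "starter_ml"))
    if (is.null(meta[[col]])) meta[[col]] <- NA_real_
  validate_metadata(meta, vocabulary)
  rownames(counts) <- meta$id
  structure(list(counts = counts, meta = meta, vocabulary = vocabulary),
            class = "input_count_table")
}

validate_metadata <- function(meta, vocabulary) {
  checks <- list(genotype = vocabulary$genotypes,
                 anesthesia = vocabulary$anesthesias,
                 treatment = vocabulary$treatments)
  for (col in names(checks)) {
    bad <- setdiff(unique(meta[[col]]), c(checks[[col]], "unknown"))
    if (length(bad))
      stop_inputmap(
        paste0("unrecognized ", col, " value(s): ",
               paste(bad, collapse = ", "),
               " (extend the vocabulary config to add new levels)"),
        "inputmap_value_error")
  }
  invisible(meta)
}

#' Read an input count table from delimited text
#'
#' Accepts UTF-8 comma- or tab-delimited files (delimiter sniffed from the
#' header) with columns `id`, optional metadata (`genotype`, `anesthesia`,
#' `treatment`, `starter_ap`, `starter_ml`), and one column per canonical
#' region. Region columns are reordered to the vocabulary order; unknown
#' columns are rejected; missing metadata becomes explicit `"unknown"`.
#'
#' @param path file path.
#' @param vocabulary a `region_vocabulary`.
#' @return An `input_count_table`.
#' @export
read_count_table <- function(path, vocabulary = default_vocabulary()) {
  df <- read_delim_auto(path)
  meta_cols <- c("id", "genotype", "anesthesia", "treatment",
                 "starter_ap", "starter_ml")
  if (is.null(df$id)) stop_inputmap("missing required column: id",
                                    "inputmap_schema_error")
  missing_regions <- setdiff(vocabulary$canonical, names(df))
  if (length(missing_regions))
    stop_inputmap(paste0("missing region column(s): ",
                         paste(missing_regions, collapse = ", ")),
                  "inputmap_schema_error")
  unknown <- setdiff(names(df), c(meta_cols, vocabulary$canonical))
  if (length(unknown))
    stop_inputmap(paste0("unknown column(s): ", paste(unknown, collapse = ", ")),
                  "inputmap_schema_error")
  for (r in vocabulary$canonical) {
    v <- suppressWarnings(as.numeric(df[[r]]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
      stop_inputmap(
        paste0("invalid count '", df[[r]][bad[1]], "' in column ", r,
               ", row ", bad[1], " (counts must be nonnegative integers)"),
        "inputmap_value_error")
    df[[r]] <- v
  }
  counts <- as.matrix(df[, vocabulary$canonical, drop = FALSE])
  meta <- df[, intersect(meta_cols, names(df)), drop = FALSE]
  if (!is.null(meta$starter_ml)) meta$starter_ml <- abs(meta$starter_ml)
  input_count_table(counts, meta, vocabulary)
}

#' Write an input count table as CSV
#'
#' Inverse of [read_count_table()]: counts and metadata round-trip
#' bit-exactly.
#'
#' @param table an `input_count_table`.
#' @param path output file path.
#' @export
write_count_table <- function(table, path) {
  df <- cbind(table$meta, as.data.frame(table$counts, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Exclude under-labeled brains
#'
#' Brains whose total input count across all 22 regions falls below
#' `min_inputs` are excluded (the standard quality filter for RABV
#' quantification; the threshold itself is retained, i.e. a total of exactly
#' `min_inputs` is kept). Excluded brain ids are reported via `message()`.
#'
#' @param table an `input_count_table`.
#' @param min_inputs minimum total labeled inputs (default 200).
#' @return Filtered `input_count_table`.
#' @export
filter_brains <- function(table, min_inputs = 200) {
  stopifnot(inherits(table, "input_count_table"), min_inputs >= 0)
  totals <- rowSums(table$counts)
  keep <- totals >= min_inputs
  if (!any(keep))
    stop_inputmap("all brains excluded by the input-count filter",
                  "inputmap_empty_cohort")
  if (any(!keep))
    message("filter_brains: excluded ",
            paste(table$meta$id[!keep], collapse = ", "),
            " (< ", min_inputs, " total inputs)")
  input_count_table(table$counts[keep, , drop = FALSE],
                    table$meta[keep, , drop = FALSE], table$vocabulary)
}

#' Convert counts to input percentages
#'
#' Each region's count is expressed as the percentage of that brain's total
#' labeled inputs, so every row sums to 100.
#'
#' @param table an `input_count_table`.
#' @return A `fraction_matrix`: list with `values` (brains x regions, percent),
#'   `regions`, `meta`, `vocabulary`.
#' @export
to_percentages <- function(table) {
  stopifnot(inherits(table, "input_count_table"))
  totals <- rowSums(table$counts)
  zero <- which(totals == 0)
  if (length(zero))
    stop_inputmap(paste0("brain(s) with zero total inputs: ",
                         paste(table$meta$id[zero], collapse = ", ")),
                  "inputmap_zero_total")
  values <- 100 * table$counts / totals
  structure(list(values = values, regions = colnames(values),
                 meta = table$meta, vocabulary = table$vocabulary),
            class = "fraction_matrix")
}

#' Column-wise Z-score normalization
#'
#' Standardizes each region's percentage across brains using the population
#' SD convention (denominator n). Constant columns are mapped to zero with a
#' recorded scale of 0, so downstream PCA stays defined.
#'
#' @param fractions a `fraction_matrix` (or plain matrix).
#' @return A `normalized_matrix`: list with `values`, `center`, `scale`,
#'   plus pass-through `meta`/`regions` when available.
#' @export
zscore_features <- function(fractions) {
  x <- as_values_matrix(fractions)
  if (nrow(x) < 2)
    stop_inputmap("Z-score normalization requires at least 2 brains",
                  "inputmap_insufficient_sample")
  center <- colMeans(x)
  scale <- apply(x, 2, pop_sd)
  values <- sweep(x, 2, center, "-")
  nz <- scale > 0
  values[, nz] <- sweep(values[, nz, drop = FALSE], 2, scale[nz], "/")
  values[, !nz] <- 0
  structure(list(values = values, center = center, scale = scale,
                 regions = colnames(x),
                 meta = if (is.list(fractions)) fractions$meta else NULL),
            class = "normalized_matrix")
}

#' Merge a fraction matrix onto the 20-region axis
#'
#' Applies the NAc merge (`merge_fractions` mode of [aggregate_regions()])
#' row-wise; row sums are preserved exactly.
#'
#' @param fractions a `fraction_matrix` on the canonical 22-region axis.
#' @param vocabulary a `region_vocabulary`.
#' @return A `fraction_matrix` on the merged 20-region axis.
#' @export
merge_fractions <- function(fractions, vocabulary = default_vocabulary()) {
  stopifnot(inherits(fractions, "fraction_matrix"))
  merged <- t(apply(fractions$values, 1, aggregate_regions,
                    vocabulary = vocabulary, mode = "merge_fractions"))
  colnames(merged) <- vocabulary$merged
  rownames(merged) <- rownames(fractions$values)
  structure(list(values = merged, regions = vocabulary$merged,
                 meta = fractions$meta, vocabulary = vocabulary),
            class = "fraction_matrix")
}

#' @export
print.input_count_table <- function(x, ...) {
  cat("Input count table:", nrow(x$counts), "brains x",
      ncol(x$counts), "regions\n")
  cat("Total inputs per brain: ",
      paste(range(rowSums(x$counts)), collapse = "-"), "\n", sep = "")
  tab <- table(x$meta$treatment)
  cat("Treatments:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.fraction_matrix <- function(x, ...) {
  cat("Fraction matrix:", nrow(x$values), "brains x",
      ncol(x$values), "regions (percent of total inputs)\n")
  invisible(x)
}
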