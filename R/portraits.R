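#' Projection-density grid
#'
#' A 2D grid of axonal projection density (arbitrary units in `[0, 1]`) for
#' one atlas tracing experiment, restricted to a representative coronal
#' slice. All grids entering one portrait must share shape and slice label.
#'
#' @param values numeric matrix (H x W), finite and nonnegative.
#' @param region region code the injection targeted.
#' @param experiment_id experiment identifier.
#' @param slice_label label of the slice the grid was taken from.
#' @return An object of class `projection_grid`.
#' @export
projection_grid <- function(values, region, experiment_id,
                            slice_label = "slice") {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop_inputmap("grid values must be finite and nonnegative",
                  "inputmap_value_error")
  structure(list(values = values, region = region,
                 experiment_id = experiment_id, slice_label = slice_label),
            class = "projection_grid")
}

#' Read a projection grid from file
#'
#' Grayscale PNG (values already in `[0, 1]`), TIFF, or whitespace-delimited
#' numeric text are accepted. Multi-channel images are averaged to one
#' channel. No registration or resampling is performed.
#'
#' @param path file path; format chosen by extension.
#' @inheritParams projection_grid
#' @return A `projection_grid`.
#' @export
read_grid <- function(path, region, experiment_id = basename(path),
                      slice_label = "slice") {
  ext <- tolower(tools::file_ext(path))
  values <- if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) apply(img, c(1, 2), mean) else img
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF grids requires the 'tiff' package")
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) apply(img, c(1, 2), mean) else img
  } else {
    as.matrix(utils::read.table(path, header = FALSE))
  }
  dimnames(values) <- NULL
  projection_grid(values, region, experiment_id, slice_label)
}

#' Write a projection grid or portrait as numeric text
#'
#' @param grid a `projection_grid` or `portrait`.
#' @param path output path.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(grid$values, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a grid library from a manifest
#'
#' The manifest is a CSV with columns `experiment_id`, `region`, `file`;
#' file paths are resolved relative to the manifest's directory. Returns the
#' grid library used by [build_portrait()].
#'
#' @param path manifest CSV path.
#' @param slice_label slice label assigned to all grids.
#' @return Named list (by region) of lists of `projection_grid` objects.
#' @export
read_grid_manifest <- function(path, slice_label = "slice") {
  df <- read_delim_auto(path)
  need <- c("experiment_id", "region", "file")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_inputmap(paste0("missing manifest column(s): ",
                         paste(missing, collapse = ", ")),
                  "inputmap_schema_error")
  base <- dirname(path)
  library <- list()
  for (i in seq_len(nrow(df))) {
    fp <- df$file[i]
    if (!file.exists(fp)) fp <- file.path(base, df$file[i])
    g <- read_grid(fp, region = df$region[i],
                   experiment_id = df$experiment_id[i],
                   slice_label = slice_label)
    library[[df$region[i]]] <- c(library[[df$region[i]]], list(g))
  }
  library
}

#' Pixelwise mean grid for one region
#'
#' Unweighted pixelwise mean over that region's tracing experiments.
#'
#' @param grids list of `projection_grid` objects for one region, identical
#'   shapes.
#' @return A `projection_grid` whose `experiment_id` lists the members.
#' @export
region_mean_grid <- function(grids) {
  if (!length(grids))
    stop_inputmap("no grids supplied", "inputmap_missing_data")
  dims <- vapply(grids, function(g) dim(g$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_inputmap(
      paste0("grid shape mismatch across experiments: ",
             paste(vapply(grids, `[[`, "", "experiment_id"), collapse = ", ")),
      "inputmap_shape_error")
  mean_values <- Reduce(`+`, lapply(grids, `[[`, "values")) / length(grids)
  projection_grid(mean_values, region = grids[[1]]$region,
                  experiment_id = paste(vapply(grids, `[[`, "", "experiment_id"),
                                        collapse = "+"),
                  slice_label = grids[[1]]$slice_label)
}

#' Build a projection portrait for a group of input regions
#'
#' Two-level averaging: experiments are first averaged within each region,
#' then the per-region mean grids are averaged across regions with equal
#' weight, so regions with many tracing experiments do not dominate the
#' portrait. `pooled = TRUE` switches to a single-level mean over all
#' experiments.
#'
#' @param region_group character vector of region codes.
#' @param library named list (by region) of lists of `projection_grid`s, as
#'   returned by [read_grid_manifest()] or [generate_projection_grids()].
#' @param pooled logical; pool all experiments in one average.
#' @return An object of class `portrait` with `values`, `member_regions`,
#'   `n_experiments_per_region`, `provenance`.
#' @export
build_portrait <- function(region_group, library, pooled = FALSE) {
  missing <- setdiff(region_group, names(library))
  empty <- region_group[vapply(region_group, function(r)
    length(library[[r]] %||% list()) == 0, logical(1))]
  bad <- union(missing, empty)
  if (length(bad))
    stop_inputmap(paste0("no grids available for region(s): ",
                         paste(bad, collapse = ", ")),
                  "inputmap_missing_data")
  groups <- library[region_group]
  if (pooled) {
    all_grids <- do.call(c, unname(groups))
    values <- region_mean_grid(all_grids)$values
  } else {
    means <- lapply(groups, region_mean_grid)
    dims <- vapply(means, function(g) dim(g$values), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop_inputmap("grid shape mismatch across regions",
                    "inputmap_shape_error")
    values <- Reduce(`+`, lapply(means, `[[`, "values")) / length(means)
  }
  structure(list(
    values = values, member_regions = region_group,
    n_experiments_per_region = vapply(groups, length, integer(1)),
    provenance = unlist(lapply(groups, function(gs)
      vapply(gs, `[[`, "", "experiment_id"))),
    pooled = pooled),
    class = "portrait")
}

#' Select a loading-defined region group
#'
#' Picks the `k` regions with the largest loadings of the requested sign on
#' one principal component (ties broken by canonical region order). If fewer
#' than `k` regions match the sign, the list is truncated with a warning.
#' An explicit region list can always be supplied to [build_portrait()]
#' directly instead.
#'
#' @param pca a `pca_result`.
#' @param pc_index component index.
#' @param sign `"+"` or `"-"`.
#' @param k number of regions to select (default 5).
#' @return Character vector of region codes, in loading order.
#' @export
select_loading_group <- function(pca, pc_index, sign = c("+", "-"), k = 5) {
  sign <- match.arg(sign)
  loadings <- pca$loadings[, pc_index]
  if (k < 1 || k > length(loadings))
    stop_inputmap("k must be between 1 and the number of regions",
                  "inputmap_argument_error")
  signed <- if (sign == "+") loadings else -loadings
  candidates <- which(signed > 0)
  ord <- candidates[order(-signed[candidates], candidates)]
  if (length(ord) < k) {
    warning("only ", length(ord), " region(s) with ", sign,
            " loadings on component ", pc_index, "; truncating")
    k <- length(ord)
  }
  names(loadings)[ord[seq_len(k)]]
}

#' @export
print.portrait <- function(x, ...) {
  cat("Projection portrait:", paste(dim(x$values), collapse = " x "),
      "grid over", length(x$member_regions), "regions\n")
  cat("Members:", paste(x$member_regions, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a projection portrait
#'
#' @param x a `portrait` (or `projection_grid`).
#' @param ... passed to [graphics::image()].
#' @export
plot.portrait <- function(x, ...) {
  v <- x$values
  graphics::image(t(v)[, nrow(v):1, drop = FALSE], axes = FALSE,
                  col = grDevices::hcl.colors(64, "inferno"), ...)
}

#' @export
plot.projection_grid <- plot.portrait
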