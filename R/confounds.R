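#' Read a starter-cell distribution table
#'
#' CSV/TSV with columns `id`, `ap_mm`, `ml_mm`, `count` (one row per section
#' or cell cluster). ML coordinates are unsigned distances from the midline;
#' hemisphere signs are normalized to positive on read.
#'
#' @param path file path.
#' @return data frame with one row per record.
#' @export
read_starter_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("id", "ap_mm", "ml_mm", "count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_inputmap(paste0("missing starter column(s): ",
                         paste(missing, collapse = ", ")),
                  "inputmap_schema_error")
  if (any(!is.finite(df$ap_mm)) || any(!is.finite(df$ml_mm)))
    stop_inputmap("starter coordinates must be finite", "inputmap_value_error")
  if (any(df$count < 1 | df$count != round(df$count)))
    stop_inputmap("starter counts must be positive integers",
                  "inputmap_value_error")
  df$ml_mm <- abs(df$ml_mm)
  df
}

#' Starter-cell center of mass
#'
#' The anterior-posterior (AP) center is the count-weighted mean of the AP
#' coordinates across the starter distribution. The medial-lateral (ML)
#' center is then the count-weighted mean ML coordinate restricted to the
#' section(s) whose AP coordinate is nearest the AP center (ties include all
#' tied sections). With `ap_center = "mode"` the AP center is instead the AP
#' coordinate carrying the most starter cells.
#'
#' @param dist data frame with columns `ap_mm`, `ml_mm`, `count`.
#' @param ap_center `"mean"` (count-weighted mean, default) or `"mode"`.
#' @return named numeric vector `c(ap = ..., ml = ...)` in mm.
#' @export
starter_center_of_mass <- function(dist, ap_center = c("mean", "mode")) {
  ap_center <- match.arg(ap_center)
  if (is.null(dist) || nrow(dist) == 0)
    stop_inputmap("empty starter distribution", "inputmap_argument_error")
  stopifnot(all(dist$count >= 1))
  ap_c <- if (ap_center == "mean") {
    stats::weighted.mean(dist$ap_mm, dist$count)
  } else {
    totals <- tapply(dist$count, dist$ap_mm, sum)
    as.numeric(names(totals)[which.max(totals)])
  }
  d <- abs(dist$ap_mm - ap_c)
  nearest <- d <= min(d) + 1e-9
  ml_c <- stats::weighted.mean(dist$ml_mm[nearest], dist$count[nearest])
  c(ap = ap_c, ml = ml_c)
}

#' Regression of a principal component on starter ML position
#'
#' Ordinary least squares of per-brain PC scores on the unsigned ML
#' coordinate of the starter center of mass, with a two-sided test of zero
#' slope. Used to diagnose which component captures injection-site variance
#' rather than treatment effects.
#'
#' @param scores per-brain scores on one component.
#' @param ml_coords per-brain ML center coordinates (mm).
#' @param pc_index optional component index recorded in the result.
#' @return An object of class `location_regression` with `slope`,
#'   `intercept`, `r_squared`, `p`, `n`.
#' @export
pc_location_regression <- function(scores, ml_coords, pc_index = NA) {
  ok <- is.finite(scores) & is.finite(ml_coords)
  scores <- scores[ok]; ml_coords <- ml_coords[ok]
  if (length(scores) < 3)
    stop_inputmap("need at least 3 brains with scores and ML coordinates",
                  "inputmap_argument_error")
  if (stats::sd(ml_coords) == 0)
    stop_inputmap("ML coordinates have zero variance",
                  "inputmap_degenerate_predictor")
  fit <- stats::lm(scores ~ ml_coords)
  s <- summary(fit)
  structure(list(pc_index = pc_index,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 p = s$coefficients[2, 4],
                 n = length(scores)),
            class = "location_regression")
}

#' @export
print.location_regression <- function(x, ...) {
  cat(sprintf("PC ~ ML regression: slope = %.4g, r^2 = %.3f, p = %.3g (n = %d)\n",
              x$slope, x$r_squared, x$p, x$n))
  invisible(x)
}
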