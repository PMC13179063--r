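#' Canonical input-region vocabulary
#'
#' The 22 canonical input regions used to quantify RABV-labeled inputs to VTA
#' cells, the 20-region merged axis in which the three nucleus accumbens
#' subdivisions (NAcMed, NAcLat, NAcCore) collapse into a single NAc entry,
#' and the mapping from each merged region onto the Allen Mouse Brain Atlas
#' region codes that constitute it. Closed metadata vocabularies (genotype,
#' anesthesia, treatment) live here as well so that extending them is an
#' explicit configuration change.
#'
#' @param canonical character vector of 22 canonical region codes.
#' @param merged character vector of 20 merged region codes.
#' @param atlas_map named list mapping each merged code to a character vector
#'   of Allen atlas codes.
#' @param genotypes,anesthesias,treatments closed metadata vocabularies.
#' @return An object of class `region_vocabulary`.
#' @export
region_vocabulary <- function(canonical, merged, atlas_map,
                              genotypes = c("DAT-Cre", "GAD2-Cre", "vGluT2-Cre"),
                              anesthesias = c("isoflurane", "KX"),
                              treatments = c("saline", "fluoxetine", "cocaine",
                                             "methamphetamine", "amphetamine",
                                             "nicotine", "morphine")) {
  canonical <- as.character(canonical)
  merged <- as.character(merged)
  if (length(canonical) != 22L || anyDuplicated(canonical))
    stop("canonical region list must contain exactly 22 unique codes")
  if (length(merged) != 20L || anyDuplicated(merged))
    stop("merged region list must contain exactly 20 unique codes")
  missing_map <- setdiff(merged, names(atlas_map))
  if (length(missing_map))
    stop("atlas_map missing entries for: ", paste(missing_map, collapse = ", "))
  if (any(!vapply(atlas_map[merged], length, 1L)))
    stop("every merged region needs a nonempty atlas_map entry")
  structure(
    list(canonical = canonical, merged = merged,
         atlas_map = lapply(atlas_map[merged], as.character),
         genotypes = as.character(genotypes),
         anesthesias = as.character(anesthesias),
         treatments = as.character(treatments)),
    class = "region_vocabulary"
  )
}

#' Default region vocabulary
#'
#' Ships the standard 22-region quantification scheme for inputs to the VTA
#' together with its Allen-atlas conversion table (36 Allen codes in total).
#' Note the code collisions across naming schemes: the Allen code `LH` is the
#' lateral habenula (our `LHb`), while our `LH` (lateral hypothalamus) is
#' Allen `LHA`.
#'
#' @return A `region_vocabulary`.
#' @export
default_vocabulary <- function() {
  canonical <- c("Cortex", "NAcMed", "NAcLat", "NAcCore", "DStr", "VP", "PO",
                 "Septum", "BNST", "EAM", "EP", "GPe", "PVH", "LHb", "MHb",
                 "CeA", "LH", "ZI", "DR", "LDT", "PBN", "DCN")
  merged <- c("Cortex", "NAc", "DStr", "VP", "PO", "Septum", "BNST", "EAM",
              "EP", "GPe", "PVH", "LHb", "MHb", "CeA", "LH", "ZI", "DR",
              "LDT", "PBN", "DCN")
  atlas_map <- list(
    Cortex = c("PL", "ILA", "ORB", "GU", "AI", "MOs", "MOp"),
    NAc    = "ACB",
    DStr   = "STRd",
    VP     = "PALv",
    PO     = c("MPO", "LPO"),
    Septum = c("LSX", "MS"),
    BNST   = "BST",
    EAM    = c("MEA", "AAA", "NLOT", "COA", "MA", "BMA", "EPv", "NDB"),
    EP     = "GPi",
    GPe    = "GPe",
    PVH    = "PVH",
    LHb    = "LH",
    MHb    = "MH",
    CeA    = "CEA",
    LH     = "LHA",
    ZI     = "ZI",
    DR     = c("DR", "PAG"),
    LDT    = "LDT",
    PBN    = "PB",
    DCN    = "CBN"
  )
  region_vocabulary(canonical, merged, atlas_map)
}

#' Read or write a region vocabulary as YAML
#'
#' The vocabulary (including the atlas conversion table and the closed
#' metadata vocabularies) round-trips through an editable YAML config; the
#' default table ships in `inst/extdata/regions.yaml`.
#'
#' @param path YAML file path.
#' @return `read_vocabulary` returns a `region_vocabulary`;
#'   `write_vocabulary` returns `path` invisibly.
#' @export
read_vocabulary <- function(path) {
  y <- yaml::read_yaml(path)
  region_vocabulary(y$canonical, y$merged, y$atlas_map,
                    genotypes = y$genotypes, anesthesias = y$anesthesias,
                    treatments = y$treatments)
}

#' @rdname read_vocabulary
#' @param vocabulary a `region_vocabulary`.
#' @export
write_vocabulary <- function(vocabulary, path) {
  yaml::write_yaml(unclass(vocabulary), path)
  invisible(path)
}

#' Aggregate per-region values between region axes
#'
#' Three modes: `merge_counts` and `merge_fractions` sum the three NAc
#' subdivisions into a single NAc value (22 regions to 20; both counts and
#' percentage fractions of disjoint regions are additive); `atlas_average`
#' maps values indexed by Allen atlas codes onto the merged 20-region axis by
#' an unweighted mean over each region's atlas code set.
#'
#' @param vector named numeric vector indexed by canonical regions (merge
#'   modes) or Allen atlas codes (`atlas_average`).
#' @param vocabulary a `region_vocabulary`.
#' @param mode one of `"merge_counts"`, `"merge_fractions"`, `"atlas_average"`.
#' @return Named numeric vector on the merged 20-region axis.
#' @export
aggregate_regions <- function(vector, vocabulary = default_vocabulary(),
                              mode = c("merge_counts", "merge_fractions",
                                       "atlas_average")) {
  mode <- match.arg(mode)
  if (is.null(names(vector))) stop("input vector must be named by region")
  if (mode %in% c("merge_counts", "merge_fractions")) {
    unknown <- setdiff(names(vector), vocabulary$canonical)
    if (length(unknown))
      stop_inputmap(paste0("unknown region(s) in input: ",
                           paste(unknown, collapse = ", ")),
                    "inputmap_key_error")
    nac_parts <- c("NAcMed", "NAcLat", "NAcCore")
    out <- vapply(vocabulary$merged, function(r) {
      if (r == "NAc") sum(vector[nac_parts]) else unname(vector[r])
    }, numeric(1))
    return(out)
  }
  # atlas_average
  all_atlas <- unique(unlist(vocabulary$atlas_map))
  unknown <- setdiff(names(vector), all_atlas)
  if (length(unknown))
    stop_inputmap(paste0("unknown atlas region(s) in input: ",
                         paste(unknown, collapse = ", ")),
                  "inputmap_key_error")
  vapply(vocabulary$merged, function(r) {
    codes <- vocabulary$atlas_map[[r]]
    present <- intersect(codes, names(vector))
    if (!length(present))
      stop_inputmap(paste0("no atlas values provided for merged region ", r),
                    "inputmap_key_error")
    mean(vector[present])
  }, numeric(1))
}

#' @export
print.region_vocabulary <- function(x, ...) {
  cat("Region vocabulary: 22 canonical regions, 20 merged regions\n")
  cat("Canonical:", paste(x$canonical, collapse = " "), "\n")
  cat("Atlas codes:", length(unique(unlist(x$atlas_map))), "Allen regions\n")
  invisible(x)
}
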