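#' Read a GMT gene-set file
#'
#' Standard tab-delimited gene-set format: set name, description, then
#' member genes, one set per line.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop_inputmap("malformed GMT line (need name, description, genes)",
                    "inputmap_schema_error")
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail test of over-representation of each gene
#' set within a hit list, against a stated gene universe (a local
#' replacement for web enrichment services). `overlap` is the number of hit
#' genes that are also members of the set; the p-value is the probability of
#' an overlap at least that large when `length(hits)` genes are drawn from
#' the universe without replacement. Benjamini-Hochberg adjustment is
#' applied across sets.
#'
#' @param hits character vector of hit gene ids (subset of `universe`).
#' @param gene_sets named list of gene-id vectors (see [read_gmt()]); each
#'   set is intersected with the universe first.
#' @param universe character vector of all screened gene ids.
#' @return data frame with columns `set`, `n_set`, `overlap`, `p`, `p_adj`,
#'   ordered by `p`.
#' @export
enrich_hypergeom <- function(hits, gene_sets, universe) {
  hits <- unique(hits); universe <- unique(universe)
  if (!length(universe) || !length(hits))
    stop_inputmap("hits and universe must be nonempty",
                  "inputmap_argument_error")
  outside <- setdiff(hits, universe)
  if (length(outside))
    stop_inputmap(paste0("hit gene(s) outside the universe: ",
                         paste(utils::head(outside, 5), collapse = ", ")),
                  "inputmap_argument_error")
  N <- length(universe); n_hit <- length(hits)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    ov <- length(intersect(hits, s))
    p <- stats::phyper(ov - 1, length(s), N - length(s), n_hit,
                       lower.tail = FALSE)
    data.frame(set = nm, n_set = length(s), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
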