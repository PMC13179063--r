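#' Synthetic cohort configuration
#'
#' Describes a synthetic RABV input-tracing cohort with planted structure.
#' Condition effects act additively on softmax logits (not directly on
#' percentages), so compositionality of the resulting input fractions is
#' automatic. A medial-lateral starter-position gradient couples the ML
#' coordinate of each brain's starter center to its input composition
#' through `gradient_vector`.
#'
#' Defaults mimic the scale of a typical study: 22 regions, 5 brains per
#' condition, total labeled inputs roughly lognormal around 2000 with a floor
#' of 200, a drug effect raising GPe and lowering DStr on the logit scale,
#' and an ML gradient carried by accumbens (lateral) versus VP/PO/LHb/DR
#' (medial) inputs, deliberately disjoint from the drug-effect regions.
#'
#' @param n_per_condition brains per condition (scalar or one per condition).
#' @param conditions data frame with columns `genotype`, `anesthesia`,
#'   `treatment`, one row per condition.
#' @param base_logits named per-region baseline logits.
#' @param effect_vectors named list (by condition label) of named per-region
#'   logit offsets; missing conditions get zero effect.
#' @param gradient_vector named per-region logit slope per mm of ML offset
#'   from the midpoint of `ml_range`.
#' @param ml_range starter ML coordinate range (mm, unsigned).
#' @param total_count_law list `(meanlog, sdlog, floor)` for per-brain totals.
#' @param noise_sd per-region logit noise SD.
#' @param seed integer RNG seed.
#' @param vocabulary a `region_vocabulary`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_condition = 5,
                          conditions = default_conditions(),
                          base_logits = default_base_logits(),
                          effect_vectors = default_effect_vectors(),
                          gradient_vector = default_gradient_vector(),
                          ml_range = c(0.2, 1.0),
                          total_count_law = list(meanlog = log(2000),
                                                 sdlog = 0.4, floor = 200),
                          noise_sd = 0.15,
                          seed = 1L,
                          vocabulary = default_vocabulary()) {
  stopifnot(all(n_per_condition >= 2), total_count_law$floor >= 1,
            noise_sd >= 0, length(ml_range) == 2, ml_range[1] <= ml_range[2])
  if (any(!is.finite(base_logits)))
    stop_inputmap("base_logits must be finite", "inputmap_config_error")
  structure(list(n_per_condition = n_per_condition, conditions = conditions,
                 base_logits = base_logits, effect_vectors = effect_vectors,
                 gradient_vector = gradient_vector, ml_range = ml_range,
                 total_count_law = total_count_law, noise_sd = noise_sd,
                 seed = as.integer(seed), vocabulary = vocabulary),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_conditions <- function() {
  data.frame(
    genotype = "DAT-Cre",
    anesthesia = c(rep("isoflurane", 7), "KX"),
    treatment = c("saline", "fluoxetine", "cocaine", "methamphetamine",
                  "amphetamine", "nicotine", "morphine", "saline"),
    stringsAsFactors = FALSE
  )
}

# Baseline input fractions (percent) typical of tracing from midbrain
# dopamine cells: striatal and pallidal inputs dominate, cerebellar and
# brainstem inputs are sparse.
#' @rdname cohort_config
#' @export
default_base_logits <- function() {
  pct <- c(Cortex = 5, NAcMed = 9, NAcLat = 10, NAcCore = 7, DStr = 12,
           VP = 6, PO = 3, Septum = 4, BNST = 4, EAM = 3, EP = 2, GPe = 5,
           PVH = 2, LHb = 6, MHb = 2, CeA = 3, LH = 7, ZI = 3, DR = 4,
           LDT = 2, PBN = 1, DCN = 0.5)
  log(pct / sum(pct))
}

# Additive logit effects: addictive drugs raise GPe and depress DStr
# labeling; repeated K/X anesthesia favors medially/centrally projecting
# inputs (VP, PO, EAM, PVH, LH, PBN).
#' @rdname cohort_config
#' @export
default_effect_vectors <- function() {
  drug <- c(GPe = 0.5, DStr = -0.5)
  kx <- c(VP = 0.4, PO = 0.4, EAM = 0.3, PVH = 0.3, LH = 0.3, PBN = 0.3)
  list(cocaine = drug, methamphetamine = drug, amphetamine = drug,
       nicotine = drug, morphine = drug, KX = kx)
}

# ML gradient: more lateral starter populations pick up more accumbens
# input, more medial ones more VP/PO/LHb/DR input. Kept disjoint from the
# drug-effect regions (GPe, DStr) so treatment and injection-site variance
# load on different components.
#' @rdname cohort_config
#' @export
default_gradient_vector <- function() {
  c(NAcLat = 1.2, NAcCore = 1.2, VP = -1.2, PO = -1.2, LHb = -1.2, DR = -1.2)
}

expand_region_vector <- function(x, regions) {
  out <- stats::setNames(numeric(length(regions)), regions)
  if (length(x)) {
    if (is.null(names(x)))
      stop_inputmap("effect/gradient vectors must be named by region",
                    "inputmap_config_error")
    unknown <- setdiff(names(x), regions)
    if (length(unknown))
      stop_inputmap(paste0("unknown region(s) in effect/gradient vector: ",
                           paste(unknown, collapse = ", ")),
                    "inputmap_config_error")
    out[names(x)] <- x
  }
  out
}

condition_label <- function(cond) {
  if (cond$anesthesia == "KX") "KX" else cond$treatment
}

#' Generate a synthetic cohort with planted effects
#'
#' For brain i in condition c with starter ML coordinate x_i drawn uniformly
#' from `ml_range`, the expected input composition is
#' `softmax(base_logits + effect[c] + gradient * (x_i - mid) + noise)` and
#' counts are multinomial with a lognormal total (clipped at the floor).
#' The truth record stores every per-brain probability vector, ML coordinate
#' and effect assignment, which is sufficient for all downstream recovery
#' tests.
#'
#' @param config a `cohort_config`.
#' @return list with `table` (an `input_count_table`) and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  voc <- config$vocabulary
  regions <- voc$canonical
  base <- if (is.null(names(config$base_logits))) {
    stopifnot(length(config$base_logits) == length(regions))
    stats::setNames(config$base_logits, regions)
  } else expand_region_vector(config$base_logits, regions)
  grad <- expand_region_vector(config$gradient_vector, regions)
  n_cond <- nrow(config$conditions)
  n_per <- rep(config$n_per_condition, length.out = n_cond)
  ml_mid <- mean(config$ml_range)
  set.seed(config$seed)

  rows <- list(); metas <- list(); truth_pi <- list()
  truth <- data.frame(id = character(0), condition = character(0),
                      ml = numeric(0), total = numeric(0))
  k <- 0
  for (ci in seq_len(n_cond)) {
    cond <- as.list(config$conditions[ci, ])
    lab <- condition_label(cond)
    eff <- expand_region_vector(config$effect_vectors[[lab]], regions)
    for (bi in seq_len(n_per[ci])) {
      k <- k + 1
      id <- sprintf("brain%03d", k)
      x <- stats::runif(1, config$ml_range[1], config$ml_range[2])
      eps <- stats::rnorm(length(regions), 0, config$noise_sd)
      logits <- base + eff + grad * (x - ml_mid) + eps
      if (any(!is.finite(logits)))
        stop_inputmap("non-finite logits in cohort generation",
                      "inputmap_config_error")
      pi_i <- softmax(logits)
      total <- max(config$total_count_law$floor,
                   round(stats::rlnorm(1, config$total_count_law$meanlog,
                                       config$total_count_law$sdlog)))
      counts <- as.vector(stats::rmultinom(1, total, pi_i))
      rows[[k]] <- counts
      metas[[k]] <- data.frame(id = id, genotype = cond$genotype,
                               anesthesia = cond$anesthesia,
                               treatment = cond$treatment,
                               starter_ap = round(stats::runif(1, -3.5, -3.1), 3),
                               starter_ml = round(x, 3),
                               stringsAsFactors = FALSE)
      truth_pi[[id]] <- pi_i
      truth <- rbind(truth, data.frame(id = id, condition = lab, ml = x,
                                       total = total))
    }
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- regions
  meta <- do.call(rbind, metas)
  list(table = input_count_table(counts, meta, voc),
       truth = list(pi = do.call(rbind, truth_pi), brains = truth,
                    effect_vectors = config$effect_vectors,
                    gradient_vector = config$gradient_vector,
                    config = config))
}

#' Synthetic expression atlas configuration
#'
#' @param n_genes number of decoy genes.
#' @param n_experiments_per_gene replicate in-situ experiments per gene (1-4).
#' @param planted data frame with columns `gene` and `rho` (target Spearman
#'   correlation of the gene's regional profile with a supplied per-region
#'   delta vector; sign included, |rho| <= 1).
#' @param concordance cross-experiment Pearson correlation level in (0, 1].
#' @param coronal_fraction probability that an experiment is flagged coronal.
#' @param seed integer RNG seed.
#' @return An object of class `expression_atlas_config`.
#' @export
expression_atlas_config <- function(n_genes = 400,
                                    n_experiments_per_gene = 2,
                                    planted = NULL,
                                    concordance = 0.8,
                                    coronal_fraction = 0.5,
                                    seed = 1L) {
  stopifnot(n_experiments_per_gene >= 1, n_experiments_per_gene <= 4,
            coronal_fraction >= 0, coronal_fraction <= 1,
            concordance > 0, concordance <= 1)
  if (!is.null(planted)) {
    if (anyDuplicated(planted$gene))
      stop_inputmap("planted gene ids must be unique", "inputmap_config_error")
    if (any(abs(planted$rho) > 1))
      stop_inputmap("target |Spearman| must be <= 1", "inputmap_config_error")
  }
  structure(list(n_genes = n_genes,
                 n_experiments_per_gene = n_experiments_per_gene,
                 planted = planted, concordance = concordance,
                 coronal_fraction = coronal_fraction, seed = as.integer(seed)),
            class = "expression_atlas_config")
}

# Rank surgery: start from the delta ranks (or their reversal for negative
# targets) and repeatedly swap adjacent-valued position pairs -- each swap
# perturbs the rank agreement by a small quantum -- until the realized
# Spearman drops to the target, so the realized value is exactly computable
# and lands close to the target.
rank_surgery <- function(delta, target, tol = 0.02) {
  n <- length(delta)
  r <- rank(delta)
  prof <- if (target >= 0) r else (n + 1 - r)
  goal <- abs(target)
  ref <- if (target >= 0) delta else -delta
  reached <- stats::cor(prof, ref, method = "spearman")
  guard <- 0
  while (reached > goal + tol && guard < 10000) {
    ord <- order(prof)
    j <- sample.int(n - 1, 1)
    ij <- ord[c(j, j + 1)]  # positions holding adjacent profile values
    cand <- prof
    cand[ij] <- cand[rev(ij)]
    cand_rho <- stats::cor(cand, ref, method = "spearman")
    if (cand_rho < reached && cand_rho >= goal - tol) {
      prof <- cand
      reached <- cand_rho
    }
    guard <- guard + 1
  }
  list(profile = prof, realized = stats::cor(prof, delta, method = "spearman"))
}

#' Generate a synthetic regional expression atlas
#'
#' Produces long-format expression records (gene, experiment_id, plane,
#' region, expression) on the merged 20-region axis. Planted genes receive
#' region profiles rank-matched to `delta` with controlled disagreement so
#' the realized Spearman approximates the target (recorded in the truth
#' record); decoy genes are i.i.d. noise. Each gene gets
#' `n_experiments_per_gene` replicates whose cross-replicate Pearson
#' correlation is governed by `concordance`.
#'
#' @param config an `expression_atlas_config`.
#' @param delta named per-region numeric vector on the merged 20-region axis.
#' @return list with `records` (long-format data frame) and `truth`.
#' @export
generate_expression_atlas <- function(config, delta) {
  stopifnot(inherits(config, "expression_atlas_config"))
  if (is.null(names(delta))) stop("delta must be named by merged region")
  regions <- names(delta)
  n_reg <- length(regions)
  set.seed(config$seed)
  planted <- config$planted
  genes <- character(0); base_profiles <- list(); realized <- numeric(0)
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      rs <- rank_surgery(delta, planted$rho[i])
      g <- planted$gene[i]
      genes <- c(genes, g)
      base_profiles[[g]] <- 5 * rs$profile  # scale ranks into expression units
      realized <- c(realized, stats::setNames(rs$realized, g))
    }
  }
  for (i in seq_len(config$n_genes)) {
    g <- sprintf("decoy%04d", i)
    genes <- c(genes, g)
    base_profiles[[g]] <- stats::runif(n_reg, 0, 100)
  }
  conc <- config$concordance
  n_exp <- config$n_experiments_per_gene
  gene_col <- character(0); exp_col <- character(0); plane_col <- character(0)
  expr_rows <- vector("list", length(genes) * n_exp)
  i <- 0
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    base <- base_profiles[[g]]
    vb <- stats::var(base)
    noise_sd <- if (conc >= 1) 0 else sqrt(vb * (1 - conc) / conc)
    for (e in seq_len(n_exp)) {
      i <- i + 1
      expr_rows[[i]] <- pmax(0, base + stats::rnorm(n_reg, 0, noise_sd))
      gene_col[i] <- g
      exp_col[i] <- sprintf("%s_e%d", g, e)
      plane_col[i] <- if (stats::runif(1) < config$coronal_fraction)
        "coronal" else "sagittal"
    }
  }
  n_rows <- length(expr_rows)
  records <- data.frame(
    gene = rep(gene_col, each = n_reg),
    experiment_id = rep(exp_col, each = n_reg),
    plane = rep(plane_col, each = n_reg),
    region = rep(regions, times = n_rows),
    expression = unlist(expr_rows, use.names = FALSE),
    stringsAsFactors = FALSE)
  list(records = records,
       truth = list(planted = planted, realized_rho = realized,
                    base_profiles = base_profiles, config = config))
}

#' Generate synthetic projection-density grids
#'
#' Each experiment's grid is a sum of isotropic Gaussian bumps (the planted
#' innervation hotspots) plus nonnegative-clipped noise, clipped to `[0, 1]`.
#'
#' @param regions character vector of region codes.
#' @param grid_shape `(H, W)`, both at least 8.
#' @param hotspots named list (by region) of lists of bumps, each bump a list
#'   `(center = c(row, col), width, amplitude)`.
#' @param n_experiments experiments per region.
#' @param noise_sd Gaussian pixel noise SD before clipping.
#' @param seed integer RNG seed.
#' @param slice_label label shared by all grids.
#' @return Named list (by region) of lists of `projection_grid` objects.
#' @export
generate_projection_grids <- function(regions, grid_shape = c(32, 32),
                                      hotspots, n_experiments = 3,
                                      noise_sd = 0.05, seed = 1L,
                                      slice_label = "synthetic_vta_slice") {
  stopifnot(all(grid_shape >= 8))
  H <- grid_shape[1]; W <- grid_shape[2]
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  set.seed(seed)
  out <- list()
  for (region in regions) {
    bumps <- hotspots[[region]] %||% list()
    base <- matrix(0, H, W)
    for (b in bumps) {
      if (b$center[1] < 1 || b$center[1] > H || b$center[2] < 1 ||
          b$center[2] > W)
        stop_inputmap(paste0("hotspot center outside grid for region ", region),
                      "inputmap_config_error")
      base <- base + b$amplitude *
        exp(-((rr - b$center[1])^2 + (cc - b$center[2])^2) / (2 * b$width^2))
    }
    out[[region]] <- lapply(seq_len(n_experiments), function(e) {
      g <- base
      if (noise_sd > 0)
        g <- g + pmax(matrix(stats::rnorm(H * W, 0, noise_sd), H, W), 0)
      projection_grid(pmin(pmax(g, 0), 1), region = region,
                      experiment_id = sprintf("%s_exp%d", region, e),
                      slice_label = slice_label)
    })
  }
  out
}
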