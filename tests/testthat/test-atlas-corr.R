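records_for <- function(gene, profiles, planes) {
  do.call(rbind, lapply(seq_along(profiles), function(i) {
    data.frame(gene = gene, experiment_id = paste0(gene, "_e", i),
               plane = planes[i], region = voc$merged,
               expression = profiles[[i]], stringsAsFactors = FALSE)
  }))
}

test_that("gene filter keeps coronal or concordant experiments only", {
  prof <- runif(20, 0, 10)
  coronal1 <- records_for("g1", list(prof), "coronal")
  expect_true("g1" %in% filter_genes(coronal1)$kept)

  sag_identical <- records_for("g2", list(prof, prof),
                               c("sagittal", "sagittal"))
  expect_true("g2" %in% filter_genes(sag_identical)$kept)

  sag_single <- records_for("g3", list(prof), "sagittal")
  f3 <- filter_genes(sag_single)
  expect_false("g3" %in% f3$kept)
  expect_match(f3$log$reason[f3$log$gene == "g3"], "single sagittal")

  set.seed(15)
  drops <- 0
  for (i in 1:50) {
    noisy <- records_for("g4", list(runif(20), runif(20)),
                         c("sagittal", "sagittal"))
    if (!"g4" %in% filter_genes(noisy)$kept) drops <- drops + 1
  }
  expect_gt(drops, 40)  # independent profiles rarely reach r > 0.5 at n = 20
})

test_that("sigmoid normalization is affine-invariant, monotone and unit range", {
  set.seed(16)
  x <- stats::setNames(rlnorm(20, 2, 1), voc$merged)
  s <- normalize_expression(x)
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  expect_identical(order(s), order(x))

  s2 <- normalize_expression(3.7 * x + 11)
  expect_equal(s, s2, tolerance = 1e-12)

  inc <- normalize_expression(sort(x))
  expect_true(all(diff(inc) > 0))

  expect_error(normalize_expression(stats::setNames(rep(5, 20), voc$merged)),
               class = "inputmap_degenerate_profile")
  flat <- c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 9, 9, 9, 1)
  expect_error(normalize_expression(flat),
               class = "inputmap_degenerate_profile")

  lg <- normalize_expression(x, "log_unit")
  expect_equal(range(lg), c(0, 1))
  expect_identical(order(lg), order(x))
})

test_that("condition deltas and ratios follow their definitions", {
  mk <- function(vals) structure(
    list(values = matrix(vals, nrow = length(vals) / 20, ncol = 20,
                         byrow = TRUE,
                         dimnames = list(NULL, voc$merged))),
    class = "fraction_matrix")
  e <- mk(rep(4, 20)); c0 <- mk(rep(2, 20))
  d <- condition_delta(e, c0)
  expect_equal(unname(d$delta), rep(2, 20))
  expect_equal(unname(d$ratio), rep(2, 20))

  same <- condition_delta(e, e)
  expect_equal(unname(same$delta), rep(0, 20))
  expect_equal(unname(same$ratio), rep(1, 20))

  ctrl0 <- mk(c(0, rep(2, 19)))
  d0 <- condition_delta(e, ctrl0)
  expect_identical(d0$undefined_regions, voc$merged[1])
  expect_true(is.na(d0$ratio[1]))
  expect_equal(unname(d0$ratio[-1]), rep(2, 19))
})

test_that("delta of zero everywhere is equivalent to ratio of one", {
  sim <- generate_cohort(cohort_config(seed = 17))
  fr <- merge_fractions(to_percentages(sim$table))
  half <- seq_len(nrow(fr$values)) <= nrow(fr$values) / 2
  d <- condition_delta(subset_fractions(fr, half),
                       subset_fractions(fr, half))
  expect_true(all(abs(d$delta) < 1e-12))
  expect_true(all(abs(d$ratio[is.finite(d$ratio)] - 1) < 1e-12))
})

test_that("screen rho matches the brute-force rank-Pearson oracle", {
  expect_equal(spearman_brute(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)), 0.8)
  set.seed(18)
  for (i in 1:300) {
    n <- sample(5:30, 1)
    x <- sample(seq_len(5), n, replace = TRUE) + rnorm(n) * (i %% 2)
    y <- sample(seq_len(4), n, replace = TRUE) + rnorm(n) * (i %% 3 == 0)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(stats::cor(x, y, method = "spearman"), spearman_brute(x, y),
                 tolerance = 1e-12)
  }
})

test_that("spearman p-values: exact enumeration small n, t approximation large", {
  st <- inputmap:::spearman_test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(st$rho, 0.8)
  ct <- suppressWarnings(stats::cor.test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5),
                                         method = "spearman"))
  expect_equal(st$p, ct$p.value, tolerance = 1e-12)

  set.seed(19)
  x <- rnorm(20); y <- rnorm(20)
  st2 <- inputmap:::spearman_test(x, y)
  rho <- cor(x, y, method = "spearman")
  tstat <- rho * sqrt(18 / (1 - rho^2))
  expect_equal(st2$p, 2 * stats::pt(-abs(tstat), 18), tolerance = 1e-12)
})

test_that("spearman rho is invariant under increasing transforms", {
  set.seed(20)
  delta <- stats::setNames(rnorm(20), voc$merged)
  sim <- generate_expression_atlas(
    expression_atlas_config(n_genes = 30, n_experiments_per_gene = 1,
                            concordance = 1, coronal_fraction = 1, seed = 3),
    delta)
  atlas <- build_expression_atlas(sim$records)
  warped <- atlas
  warped$matrix <- exp(2 * atlas$matrix)
  s1 <- gene_screen(atlas, delta)
  s2 <- gene_screen(warped, delta)
  expect_equal(s1$table$rho, s2$table$rho, tolerance = 1e-12)
})

test_that("gene screen ranks planted genes and skips constant profiles", {
  delta <- stats::setNames(rnorm(20), voc$merged)
  planted <- data.frame(gene = c("POS", "NEG"), rho = c(1, -1))
  sim <- generate_expression_atlas(
    expression_atlas_config(n_genes = 50, n_experiments_per_gene = 1,
                            concordance = 1, coronal_fraction = 1, seed = 4),
    delta)
  atlas <- build_expression_atlas(sim$records)
  # splice in the planted extremes and a constant decoy
  atlas$matrix <- rbind(atlas$matrix,
                        POS = normalize_expression(rank(delta), "log_unit"),
                        NEG = normalize_expression(rank(-delta), "log_unit"),
                        FLAT = rep(0.5, 20))
  scr <- gene_screen(atlas, delta, k = 5)
  expect_identical(scr$top_positive[1], "POS")
  expect_identical(scr$top_negative[1], "NEG")
  expect_identical(scr$skipped, "FLAT")
  expect_length(intersect(scr$top_positive, scr$top_negative), 0)
  expect_equal(scr$table$rho[scr$table$gene == "POS"], 1)
})

test_that("hypergeometric enrichment matches pmf summation and Fisher", {
  set.seed(21)
  for (i in 1:200) {
    N <- sample(50:1000, 1)
    K <- sample(5:min(200, N - 1), 1)
    n <- sample(5:min(100, N - 1), 1)
    universe <- sprintf("g%04d", seq_len(N))
    set <- sample(universe, K)
    hits <- sample(universe, n)
    res <- enrich_hypergeom(hits, list(s = set), universe)
    ov <- length(intersect(hits, set))
    expect_identical(res$overlap, ov)
    expect_equal(res$p, hyper_tail_oracle(ov, K, N, n), tolerance = 1e-12)
    f <- stats::fisher.test(matrix(c(ov, n - ov, K - ov, N - K - n + ov),
                                   2, 2), alternative = "greater")
    expect_equal(res$p, f$p.value, tolerance = 1e-9)
  }
})

test_that("enrichment boundary cases behave as the tail convention dictates", {
  universe <- sprintf("g%02d", 1:40)
  hits <- universe[1:10]
  res0 <- enrich_hypergeom(hits, list(s = universe[31:35]), universe)
  expect_identical(res0$overlap, 0L)
  expect_equal(res0$p, 1)

  resF <- enrich_hypergeom(hits, list(s = hits), universe)
  expect_identical(resF$overlap, 10L)
  expect_equal(resF$p, 1 / choose(40, 10), tolerance = 1e-12)

  both <- enrich_hypergeom(hits, list(a = hits, b = universe[31:35]),
                           universe)
  expect_true(all(both$p_adj >= both$p - 1e-15))
  expect_error(enrich_hypergeom(character(0), list(s = hits), universe),
               class = "inputmap_argument_error")
  expect_error(enrich_hypergeom(c(hits, "zzz"), list(s = hits), universe),
               class = "inputmap_argument_error")
})

test_that("GMT files parse into named gene sets", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tother desc\tg9"), p)
  sets <- read_gmt(p)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, "g9")
  writeLines("broken\tonly-desc", p)
  expect_error(read_gmt(p), class = "inputmap_schema_error")
})

test_that("class regression recovers exact linear couplings", {
  set.seed(22)
  delta <- stats::setNames(rnorm(20), voc$merged)
  sim <- generate_expression_atlas(
    expression_atlas_config(n_genes = 40, n_experiments_per_gene = 1,
                            concordance = 1, coronal_fraction = 1, seed = 5),
    delta)
  atlas <- build_expression_atlas(sim$records)
  class_genes <- atlas$kept_genes[1:5]
  profs <- t(apply(atlas$raw[class_genes, ], 1, normalize_expression,
                   method = "log_unit"))
  score <- colMeans(profs)
  fake_delta <- structure(list(
    delta = stats::setNames(rep(0, 20), voc$merged),
    ratio = stats::setNames(2 - score, voc$merged),
    undefined_regions = character(0),
    experimental = "drug", control = "saline"),
    class = "condition_delta")
  cr <- class_regression(atlas, class_genes, fake_delta, "test")
  expect_equal(cr$r, -1, tolerance = 1e-9)
  expect_identical(cr$n, 20L)

  expect_error(class_regression(atlas, c("nope1", "nope2"), fake_delta,
                                "missing"),
               class = "inputmap_argument_error")
})

test_that("undefined-ratio regions are dropped from class regressions", {
  set.seed(23)
  delta <- stats::setNames(rnorm(20), voc$merged)
  sim <- generate_expression_atlas(
    expression_atlas_config(n_genes = 30, n_experiments_per_gene = 1,
                            concordance = 1, coronal_fraction = 1, seed = 6),
    delta)
  atlas <- build_expression_atlas(sim$records)
  ratio <- stats::setNames(runif(20, 0.5, 2), voc$merged)
  ratio[c(3, 7)] <- NA
  d <- structure(list(delta = delta, ratio = ratio,
                      undefined_regions = voc$merged[c(3, 7)],
                      experimental = "drug", control = "saline"),
                 class = "condition_delta")
  cr <- class_regression(atlas, atlas$kept_genes[1:4], d, "t")
  expect_identical(cr$n, 18L)
})
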