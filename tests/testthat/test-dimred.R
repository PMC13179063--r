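test_that("PCA matches the covariance eigendecomposition oracle", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- matrix(rnorm(n * 22), n, 22)
    k <- min(3, n - 1)
    p <- fit_pca(x, k)
    o <- pca_eigen_oracle(x, k)
    expect_lt(max(abs(unname(p$loadings) - o$loadings)), 1e-8)
    expect_lt(max(abs(unname(p$scores) - o$scores)), 1e-8)
    expect_lt(max(abs(p$explained_variance_ratio - o$evr)), 1e-8)
  }
})

test_that("PCA result satisfies its structural invariants", {
  set.seed(1)
  x <- matrix(rnorm(10 * 22), 10, 22)
  p <- fit_pca(x, 5)
  expect_lt(max(abs(crossprod(p$loadings) - diag(5))), 1e-8)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(p$explained_variance_ratio), 1 + 1e-9)
  xc <- sweep(x, 2, colMeans(x))
  expect_lt(max(abs(unname(p$scores) - xc %*% unname(p$loadings))), 1e-8)
  # sign convention: dominant loading positive
  for (j in 1:5) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("points on the y = x line load equally on a single component", {
  x <- cbind(c(-2, -1, 0, 1, 2), c(-2, -1, 0, 1, 2))
  p <- fit_pca(x, 1)
  expect_equal(unname(p$loadings[, 1]), c(sqrt(0.5), sqrt(0.5)),
               tolerance = 1e-12)
  expect_equal(p$explained_variance_ratio[1], 1, tolerance = 1e-12)
  expect_error(fit_pca(x, 3), class = "inputmap_argument_error")
})

test_that("two-group score test reduces to the classic t/F identity", {
  g <- rep(c("a", "b"), each = 3)
  r <- pc_group_test(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(r$omnibus$statistic, 0)
  expect_equal(r$omnibus$p, 1)

  set.seed(5)
  x <- rnorm(12)
  g3 <- rep(c("a", "b"), each = 6)
  t2 <- pc_group_test(x, g3)$omnibus$statistic^2
  f <- summary(stats::aov(x ~ factor(g3)))[[1]][["F value"]][1]
  expect_equal(t2, f, tolerance = 1e-9)
})

test_that("pairwise tests are gated on the omnibus and corrections order p", {
  set.seed(8)
  x_null <- rnorm(30, 0, 1e-3) + rep(0, 30)
  g <- rep(c("a", "b", "c"), each = 10)
  r_null <- pc_group_test(rnorm(30), g)
  if (r_null$omnibus$p >= 0.05) expect_null(r_null$pairwise)

  x_sig <- c(rnorm(10), rnorm(10, 3), rnorm(10, 6))
  for (corr in c("tukey", "sidak", "holm")) {
    r <- pc_group_test(x_sig, g, correction = corr)
    expect_false(is.null(r$pairwise))
    expect_true(all(r$pairwise$p_adj >= 0 & r$pairwise$p_adj <= 1))
    if (corr %in% c("sidak", "holm"))
      expect_true(all(r$pairwise$p_adj >= r$pairwise$p_raw - 1e-12))
  }
  rd <- pc_group_test(x_sig, g, correction = "dunnett", control_group = "a")
  expect_identical(unique(rd$pairwise$group2), "a")
  expect_identical(nrow(rd$pairwise), 2L)
  expect_error(pc_group_test(x_sig, g, correction = "dunnett"),
               class = "inputmap_argument_error")
  expect_error(pc_group_test(c(1, 2, 3), c("a", "a", "b")),
               class = "inputmap_insufficient_sample")
})

test_that("dunnett adjusted p-values are reproducible across calls", {
  set.seed(13)
  x <- c(rnorm(8), rnorm(8, 2), rnorm(8, 2.5))
  g <- rep(c("ctrl", "t1", "t2"), each = 8)
  r1 <- pc_group_test(x, g, correction = "dunnett", control_group = "ctrl")
  r2 <- pc_group_test(x, g, correction = "dunnett", control_group = "ctrl")
  expect_identical(r1$pairwise$p_adj, r2$pairwise$p_adj)
})

test_that("condition ellipsoids have hand-computed centers and radii", {
  pts <- rbind(c(0, 0), c(2, 0), c(0, 0), c(2, 0))
  e <- condition_ellipsoid(pts, rep("a", 4))[["a"]]
  expect_equal(unname(e$center), c(1, 0))
  expect_equal(e$radii, c(1, 0))
  expect_equal(abs(e$axes[, 1]), c(1, 0))

  shifted <- condition_ellipsoid(pts + 5, rep("a", 4))[["a"]]
  expect_equal(unname(shifted$center), c(6, 5))
  expect_equal(shifted$radii, e$radii)

  set.seed(2)
  iso <- condition_ellipsoid(matrix(rnorm(1000), 500, 2),
                             rep("a", 500))[["a"]]
  expect_gt(iso$radii[2] / iso$radii[1], 0.8)

  expect_warning(condition_ellipsoid(rbind(c(0, 0), c(1, 1), c(0, 1)),
                                     c("a", "a", "b")), "singleton")
})

test_that("ensemble distances reduce correctly for deterministic backends", {
  set.seed(3)
  x <- matrix(rnorm(12 * 22), 12, 22)

  constant_backend <- function(x, n_neighbors, metric, seed)
    unname(x[, 1:2])
  ed <- ensemble_embed(x, n_repeats = 5, backend = constant_backend)
  expect_identical(ed$mean_distance, ed$mean_distance)
  expect_equal(unname(ed$mean_distance),
               unname(as.matrix(stats::dist(x[, 1:2]))),
               tolerance = 1e-12)
  expect_true(isSymmetric(unname(ed$mean_distance)))
  expect_equal(diag(ed$mean_distance), stats::setNames(rep(0, 12), NULL))

  # averaging over seed-dependent repeats is order invariant
  scaled_backend <- function(x, n_neighbors, metric, seed)
    unname(x[, 1:2]) * seed
  e1 <- ensemble_embed(x, 3, backend = scaled_backend, seeds = c(1, 2, 3))
  e2 <- ensemble_embed(x, 3, backend = scaled_backend, seeds = c(3, 1, 2))
  expect_equal(e1$mean_distance, e2$mean_distance, tolerance = 1e-12)

  expect_error(ensemble_embed(x, 2, n_neighbors = 12),
               class = "inputmap_argument_error")
  bad_backend <- function(x, n_neighbors, metric, seed) stop("boom")
  expect_error(ensemble_embed(x, 2, backend = bad_backend), "repeat 1")
})

test_that("per-repeat unit-RMS rescaling removes arbitrary embedding scale", {
  set.seed(4)
  x <- matrix(rnorm(10 * 22), 10, 22)
  scaled_backend <- function(x, n_neighbors, metric, seed)
    unname(x[, 1:2]) * seed
  ed <- ensemble_embed(x, 3, backend = scaled_backend, seeds = c(1, 5, 50),
                       rescale = TRUE)
  one <- ensemble_embed(x, 1, backend = scaled_backend, seeds = 1,
                        rescale = TRUE)
  expect_equal(ed$mean_distance, one$mean_distance, tolerance = 1e-12)
  expect_equal(sqrt(mean(ed$mean_distance^2)), 1, tolerance = 1e-12)
})

test_that("default n_neighbors follows the one-third rule", {
  set.seed(6)
  x <- matrix(rnorm(24 * 5), 24, 5)
  ed <- ensemble_embed(x, 1, backend = pca_backend())
  expect_identical(ed$embed_params$n_neighbors, 8L)
})

test_that("the umap backend is deterministic given a seed", {
  set.seed(7)
  x <- matrix(rnorm(18 * 22), 18, 22)
  b <- umap_backend()
  a1 <- b(x, 6, "euclidean", 11)
  a2 <- b(x, 6, "euclidean", 11)
  expect_identical(a1, a2)
  expect_identical(dim(a1), c(18L, 2L))
})

test_that("correlogram clusters nearest rows first and is equivariant", {
  d3 <- matrix(c(0, 1, 10,
                 1, 0, 10,
                 10, 10, 0), 3, 3)
  cg <- correlogram(d3)
  expect_identical(cg$hclust$merge[1, ], c(-1L, -2L))

  blocks <- rbind(cbind(matrix(1, 3, 3), matrix(9, 3, 3)),
                  cbind(matrix(9, 3, 3), matrix(1, 3, 3)))
  diag(blocks) <- 0
  ord <- correlogram(blocks)$order
  first_block <- which(ord %in% 1:3)
  expect_true(all(diff(sort(first_block)) == 1))

  set.seed(9)
  x <- matrix(rnorm(8 * 4), 8, 4)
  d <- as.matrix(dist(x))
  perm <- sample(8)
  o1 <- correlogram(d)$order
  o2 <- correlogram(d[perm, perm])$order
  expect_identical(sort(perm[o2]), 1:8)
  # same partition under relabeling: leaves map back to the same sets
  expect_setequal(perm[o2], o1)

  asym <- d; asym[1, 2] <- asym[1, 2] + 1
  expect_error(correlogram(asym), class = "inputmap_contract_violation")
})

test_that("scramble null uses the add-one estimator and detects separation", {
  sim <- generate_cohort(two_condition_config(21, n = 8, effect = 2))
  fr <- to_percentages(sim$table)
  labs <- sim$table$meta$treatment
  sn <- scramble_null(fr, labs, n_perm = 100, seed = 1)
  expect_equal(sn$p, (1 + sum(sn$null >= sn$observed)) / 101)
  expect_lte(sn$p, 0.05)
  # strongest possible outcome equals the estimator floor
  if (all(sn$null < sn$observed)) expect_equal(sn$p, 1 / 101)

  expect_error(scramble_null(fr, rep("a", nrow(fr$values)), 100),
               class = "inputmap_argument_error")
  expect_error(scramble_null(fr, labs, 10),
               class = "inputmap_argument_error")
  both <- scramble_null(fr, labs, n_perm = 100,
                        statistic = "between_within_ratio", seed = 2)
  expect_lte(both$p, 0.05)
})
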