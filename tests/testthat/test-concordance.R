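# Pairwise PCA, confidence ellipses and the concordance statistic.

test_that("pairwise PCA pools, scales and centres; duplicate tables change nothing but n", {
  tab <- make_table(n_per = 40L, treatments = "A", p = 5L)
  tab2 <- tab; tab2$treatment <- "B"; tab2$cell_id <- paste0("b", 1:40)
  fit <- fit_pairwise_pca(tab, tab2)
  expect_equal(fit$scores_a, fit$scores_b, ignore_attr = TRUE)
  # eigen-decomposition oracle on the pooled correlation matrix
  pooled <- rbind(as.matrix(tab[paste0("p", 1:5)]),
                  as.matrix(tab2[paste0("p", 1:5)]))
  ev <- eigen(cor(pooled), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(unname(fit$model$explained_variance), ev, tolerance = 1e-8)
})

test_that("perfectly correlated parameters put all variance on PC1", {
  x <- rnorm(30)
  tab_a <- data.frame(cell_id = paste0("a", 1:15), treatment = "A",
                      replicate = "rep1", p1 = x[1:15], p2 = 2 * x[1:15] + 3)
  tab_b <- data.frame(cell_id = paste0("b", 1:15), treatment = "B",
                      replicate = "rep1", p1 = x[16:30], p2 = 2 * x[16:30] + 3)
  fit <- fit_pairwise_pca(tab_a, tab_b)
  ev <- fit$model$explained_variance
  expect_equal(ev[1L] / sum(ev), 1, tolerance = 1e-10)
})

test_that("a treatment shift drives PC1 and matches the correlation eigen-oracle", {
  # the shift spans p1 and p2, inducing a pooled correlation between them
  # that PC1 must pick up (a shift confined to a single parameter adds
  # variance but no correlation, so correlation PCA cannot see it)
  specs <- list(treatment_spec("q", 300, rep(0, 10), diag(10)),
                treatment_spec("r", 300, c(3, 3, rep(0, 8)), diag(10)))
  tab <- gen_feature_table(specs, paste0("p", 1:10), seed = 21)
  parts <- split(tab, tab$treatment)
  fit <- fit_pairwise_pca(parts$q, parts$r)
  l1 <- abs(fit$model$loadings[, 1L])
  expect_setequal(names(sort(l1, decreasing = TRUE))[1:2], c("p1", "p2"))
  # eigen-decomposition oracle on the pooled correlation matrix
  pooled <- rbind(as.matrix(parts$q[paste0("p", 1:10)]),
                  as.matrix(parts$r[paste0("p", 1:10)]))
  eo <- eigen(cor(pooled), symmetric = TRUE)
  expect_equal(unname(fit$model$explained_variance), eo$values,
               tolerance = 1e-8)
  expect_equal(abs(unname(fit$model$loadings[, 1L])),
               abs(eo$vectors[, 1L]), tolerance = 1e-6)
})

test_that("zero-variance parameters are dropped with a warning", {
  tab_a <- make_table(n_per = 20L, treatments = "A", p = 3L)
  tab_b <- make_table(n_per = 20L, treatments = "B", p = 3L, seed = 7L)
  tab_a$p3 <- 1; tab_b$p3 <- 1
  expect_warning(fit <- fit_pairwise_pca(tab_a, tab_b), "p3")
  expect_false("p3" %in% rownames(fit$model$loadings))
})

test_that("ellipse radius matches its distributional definition and membership is exact", {
  set.seed(4)
  scores <- MASS::mvrnorm(500, c(1, -2), matrix(c(2, 0.5, 0.5, 1), 2))
  for (method in c("t", "normal")) {
    e <- confidence_ellipse(scores, level = 0.95, method = method)
    expect_equal(e$center, colMeans(scores), ignore_attr = TRUE)
    expect_equal(e$shape, cov(scores), ignore_attr = TRUE)
    # membership equals the explicit quadratic form oracle
    expect_identical(unname(ellipse_contains(e, scores)),
                     unname(oracle_in_ellipse(scores, e$center, e$shape,
                                              e$radius2)))
    # the centre is always a member
    expect_true(ellipse_contains(e, matrix(e$center, 1)))
  }
  n <- nrow(scores)
  et <- confidence_ellipse(scores, method = "t")
  en <- confidence_ellipse(scores, method = "normal")
  expect_equal(et$radius2, 2 * (n - 1) / (n - 2) * qf(0.95, 2, n - 2))
  expect_equal(en$radius2, qchisq(0.95, 2))
  # t and normal agree as n grows
  expect_equal(et$radius2 / en$radius2, 1, tolerance = 0.02)
  # degenerate input
  line <- cbind(1:10, 2 * (1:10))
  expect_error(confidence_ellipse(line), "collinear")
  expect_error(confidence_ellipse(scores[1:2, ]), "at least 3")
})

test_that("normal-method ellipse covers its own points at the nominal level", {
  set.seed(8)
  scores <- matrix(rnorm(2 * 10000), ncol = 2)
  e <- confidence_ellipse(scores, level = 0.95, method = "normal")
  expect_lt(abs(mean(ellipse_contains(e, scores)) - 0.95), 0.01)
})

test_that("membership via the quadratic form equals exhaustive rasterization", {
  set.seed(12)
  scores <- MASS::mvrnorm(50, c(0, 0), matrix(c(1, 0.3, 0.3, 0.7), 2))
  e <- confidence_ellipse(scores, method = "normal")
  # rasterize the ellipse on a fine grid and test points by nearest pixel
  grid <- seq(-6, 6, by = 0.01)
  inside_grid <- outer(grid, grid, function(x, y)
    oracle_in_ellipse(cbind(x, y), e$center, e$shape, e$radius2))
  pts <- MASS::mvrnorm(200, c(0, 0), diag(2))
  ix <- findInterval(pts[, 1L], grid); iy <- findInterval(pts[, 2L], grid)
  raster_member <- inside_grid[cbind(ix, iy)]
  qf_member <- ellipse_contains(e, pts)
  # boundary pixels may disagree at raster resolution; interior must not
  mism <- which(raster_member != qf_member)
  d <- stats::mahalanobis(pts, e$center, e$shape)
  expect_true(all(abs(d[mism] - e$radius2) < 0.05))
})

test_that("concordance is exact in the self and disjoint limits and symmetric", {
  set.seed(31)
  sa <- MASS::mvrnorm(300, c(0, 0), diag(2))
  ea <- confidence_ellipse(sa)
  self <- concordance(ea, ea, sa, sa)
  expect_equal(self$proportion, 1)
  sb <- sweep(sa, 2L, c(100, 0), `+`)       # 100 SD away: disjoint
  eb <- confidence_ellipse(sb)
  far <- concordance(ea, eb, sa, sb)
  expect_equal(far$proportion, 0)
  # symmetry
  sc <- sweep(sa, 2L, c(1, 0), `+`)
  ec <- confidence_ellipse(sc)
  ab <- concordance(ea, ec, sa, sc)
  ba <- concordance(ec, ea, sc, sa)
  expect_equal(ab$proportion, ba$proportion)
  expect_lte(ab$n_both, ab$n_either)
})

test_that("concordance matches the analytic Monte-Carlo oracle over a distance grid", {
  level <- 0.95
  r2 <- qchisq(level, 2)
  oracle <- function(d, n = 100000L) {
    set.seed(999)
    pts <- rbind(MASS::mvrnorm(n, c(0, 0), diag(2)),
                 MASS::mvrnorm(n, c(d, 0), diag(2)))
    in_a <- rowSums(pts^2) <= r2
    in_b <- (pts[, 1L] - d)^2 + pts[, 2L]^2 <= r2
    sum(in_a & in_b) / sum(in_a | in_b)
  }
  pipeline <- function(d, seed) {
    set.seed(seed)
    sa <- MASS::mvrnorm(5000, c(0, 0), diag(2))
    sb <- MASS::mvrnorm(5000, c(d, 0), diag(2))
    ea <- confidence_ellipse(sa, level, "normal")
    eb <- confidence_ellipse(sb, level, "normal")
    concordance(ea, eb, sa, sb)$proportion
  }
  props <- vapply(c(0, 2, 4), pipeline, numeric(1L), seed = 77)
  oracles <- vapply(c(0, 2, 4), oracle, numeric(1L))
  expect_true(all(abs(props - oracles) < 0.02))
  expect_true(props[1L] > props[2L] && props[2L] > props[3L])
})

test_that("concordance is invariant to parameter rescaling and column order", {
  tab_a <- make_table(n_per = 60L, treatments = "A", p = 4L)
  tab_b <- make_table(n_per = 60L, treatments = "B", p = 4L, seed = 5L)
  run <- function(a, b) {
    fit <- fit_pairwise_pca(a, b)
    ea <- confidence_ellipse(fit$scores_a)
    eb <- confidence_ellipse(fit$scores_b)
    concordance(ea, eb, fit$scores_a, fit$scores_b)$proportion
  }
  base <- run(tab_a, tab_b)
  # affine rescaling of one parameter is absorbed by standardization
  ra <- tab_a; rb <- tab_b
  ra$p2 <- 1000 * ra$p2 - 5; rb$p2 <- 1000 * rb$p2 - 5
  expect_equal(run(ra, rb), base, tolerance = 1e-10)
  # permuting parameter columns changes nothing
  perm <- c("p3", "p1", "p4", "p2")
  pa <- tab_a[c(feature_metadata_cols(), perm)]
  pb <- tab_b[c(feature_metadata_cols(), perm)]
  expect_equal(run(pa, pb), base, tolerance = 1e-10)
})

test_that("expected concordance decreases with the distance between treatments", {
  pars <- paste0("p", 1:6)
  prop_at <- function(d, seed) {
    specs <- list(treatment_spec("q", 250, rep(0, 6), diag(6)),
                  treatment_spec("r", 250, c(d, rep(0, 5)), diag(6)))
    tab <- gen_feature_table(specs, pars, seed = seed)
    parts <- split(tab, tab$treatment)
    rank_references(parts$q, parts["r"], seed = seed)$table$proportion
  }
  grid <- c(0, 1.5, 3, 6)
  means <- vapply(grid, function(d)
    mean(vapply(1:5, function(s) prop_at(d, s), numeric(1L))), numeric(1L))
  expect_true(all(diff(means) < 0))
})

test_that("rank_references puts a duplicated treatment first and handles empty input", {
  pars <- paste0("p", 1:8)
  specs <- list(treatment_spec("query", 200, rep(0, 8), diag(8)),
                treatment_spec("twin", 200, rep(0, 8), diag(8)),
                treatment_spec("far1", 200, rep(3, 8), diag(8)),
                treatment_spec("far2", 200, c(rep(-3, 4), rep(3, 4)), diag(8)))
  tab <- gen_feature_table(specs, pars, seed = 2)
  parts <- split(tab, tab$treatment)
  rk <- rank_references(parts$query, parts[c("far1", "twin", "far2")],
                        seed = 10)
  expect_s3_class(rk, "bcp_ranking")
  expect_equal(rk$table$reference[1L], "twin")
  expect_gt(rk$table$proportion[1L], 0.8)
  expect_equal(rk$table$rank, 1:3)
  # provenance round-trip
  expect_equal(rk$seed, 10)
  # empty reference map
  empty <- rank_references(parts$query, list(), seed = 1)
  expect_equal(nrow(empty$table), 0L)
  # printing and summary do not error
  expect_output(print(rk), "concordance ranking")
  expect_output(summary(rk), "Top match: twin")
})
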