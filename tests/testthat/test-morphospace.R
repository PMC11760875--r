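# PCA, PC retention, landmark contributions, extremes, TPS, convex hulls.

test_that("PCA conserves variance and reconstructs the data", {
  set.seed(12)
  X <- matrix(rnorm(60 * 16), 60) %*% diag(c(4, 3, rep(0.5, 14)))
  pc <- shape_pca(X)
  expect_equal(sum(pc$eigenvalues), sum(apply(X, 2, stats::var)),
               tolerance = 1e-9)
  expect_equal(sum(pc$variance_pct), 100, tolerance = 1e-9)
  recon <- pc$scores %*% t(pc$loadings)
  expect_equal(sweep(recon, 2, -pc$center), X, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(crossprod(pc$loadings), diag(ncol(pc$loadings)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("collinear data load entirely on PC1", {
  t_ <- rnorm(30)
  dir <- rnorm(16)
  X <- outer(t_, dir)
  pc <- shape_pca(X)
  expect_equal(pc$variance_pct[1], 100, tolerance = 1e-9)
  expect_error(shape_pca(matrix(1, 10, 16)), "zero-variance")
})

test_that("the eigenvalue-ratio retention rule counts leading runs", {
  expect_identical(meaningful_pcs(c(10, 5, 1)), 2L)
  expect_identical(meaningful_pcs(c(10, 9, 1)), 0L)
  # hand application of the rule to the published leading shares
  expect_identical(meaningful_pcs(c(64.1, 18.7, 8.6, 4.7, 1.5, 1.1)), 5L)
  # scale invariance
  expect_identical(meaningful_pcs(c(64.1, 18.7, 8.6, 4.7, 1.5, 1.1) * 1e-3), 5L)
})

test_that("landmark contributions are normalized squared loadings", {
  pc <- list(loadings = cbind(c(1, rep(0, 15))), eigenvalues = 1,
             scores = matrix(0, 3, 1), variance_pct = 100, center = rep(0, 16))
  class(pc) <- "shape_pca"
  ctr <- landmark_contributions(pc, 1)
  expect_equal(unname(ctr), c(100, rep(0, 7)), ignore_attr = TRUE)
  pc$loadings <- cbind(rep(1 / 4, 16))
  ctr2 <- landmark_contributions(pc, 1)
  expect_equal(unname(ctr2), rep(12.5, 8), ignore_attr = TRUE)
  expect_equal(sum(ctr2), 100, tolerance = 1e-9)
})

test_that("PC1 contributions on the default cohort single out the angle landmarks", {
  ss <- small_cohort()
  ds <- digitize_replicates(ss)
  g <- gpa(average_replicates(ds))
  pc <- shape_pca(tangent_projection(g))
  ctr <- landmark_contributions(pc, 1)
  top3 <- as.integer(sub("L", "", names(sort(ctr, decreasing = TRUE)[1:3])))
  # the posterior-angle-defining landmarks: the tips (3, 7) and a suture pole
  expect_true(all(c(3L, 7L) %in% top3))
  expect_true(any(c(1L, 5L) %in% top3))
})

test_that("extreme shapes are linear displacements from the consensus", {
  ss <- small_cohort()
  g <- gpa(ss$true_landmarks)
  pc <- shape_pca(tangent_projection(g))
  hi <- extreme_shapes(pc, g$consensus, 1, "max")
  lo <- extreme_shapes(pc, g$consensus, 1, "min")
  smax <- max(pc$scores[, 1]); smin <- min(pc$scores[, 1])
  # +s and -s displacements average to the consensus (weighted)
  mid <- (hi * abs(smin) + lo * smax) / (smax + abs(smin))
  cons_shift <- g$consensus + ceratomorph:::unflatten_config(pc$center)
  expect_equal(mid, cons_shift, tolerance = 1e-9, ignore_attr = TRUE)
  # the PC1 extremes differ strongly in posterior angle (angle mode)
  da <- abs(measure_traditional(hi)$posterior_angle -
            measure_traditional(lo)$posterior_angle)
  expect_gt(da, 20)
})

test_that("TPS interpolates control points exactly and is affine-exact", {
  set.seed(5)
  src <- random_config()
  tgt <- src + matrix(rnorm(16, sd = 0.2), 8, 2)
  w <- tps_warp(src, tgt)
  expect_lt(max(abs(w$warp(src) - tgt)), 1e-9)
  # identity: zero bending energy
  w_id <- tps_warp(src, src)
  expect_lt(w_id$bending_energy, 1e-9)
  expect_lt(max(abs(w_id$warped_grid - w_id$source_grid)), 1e-8)
  # affine target: warp is that affine map with zero bending energy
  A <- matrix(c(1.2, 0.3, -0.2, 0.9), 2)
  tgt_aff <- src %*% A + matrix(c(1, -2), 8, 2, byrow = TRUE)
  w_aff <- tps_warp(src, tgt_aff)
  expect_lt(w_aff$bending_energy, 1e-8)
  pts <- matrix(rnorm(20), 10, 2)
  expect_equal(w_aff$warp(pts),
               pts %*% A + matrix(c(1, -2), 10, 2, byrow = TRUE),
               tolerance = 1e-6)
  # collinear source is rejected
  col <- cbind(1:8, 2 * (1:8))
  expect_error(tps_warp(col, col), "collinear")
})

test_that("convex hulls contain their points and ignore point order", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  h <- convex_hulls(sq, rep("a", 5))
  expect_identical(nrow(h$a$vertices), 4L)
  expect_false(h$a$degenerate)
  set.seed(8)
  pts <- matrix(rnorm(120), ncol = 2)
  h1 <- convex_hulls(pts, rep("g", 60))$g$vertices
  h2 <- convex_hulls(pts[sample(60), ], rep("g", 60))$g$vertices
  expect_equal(abs(ceratomorph:::polygon_area(h1)),
               abs(ceratomorph:::polygon_area(h2)), tolerance = 1e-12)
  # brute-force containment: every point inside or on the hull
  inside <- function(p, hull) {
    n <- nrow(hull)
    e <- hull[c(2:n, 1), ] - hull
    cr <- e[, 1] * (p[2] - hull[, 2]) - e[, 2] * (p[1] - hull[, 1])
    all(cr >= -1e-9)
  }
  expect_true(all(apply(pts, 1, inside, hull = h1)))
  # degenerate group
  h3 <- convex_hulls(rbind(c(0, 0), c(1, 1)), rep("g", 2))
  expect_true(h3$g$degenerate)
})
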