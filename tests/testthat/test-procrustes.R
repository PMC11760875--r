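# Centroid size, GPA, Procrustes distances and the tangent space.

test_that("centroid size has its closed form and scales linearly", {
  sq <- cbind(c(-.5, .5, .5, -.5), c(-.5, -.5, .5, .5))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  expect_equal(centroid_size(sq * 3.7), 3.7 * sqrt(2), tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 4, 2)), "coincide")
})

test_that("identical configurations up to similarity align exactly", {
  set.seed(1)
  base <- random_config()
  configs <- array(NA_real_, c(4, 8, 2))
  configs[1, , ] <- base
  configs[2, , ] <- rigid_motion(base, 0.8, c(2, 3)) * 1.5
  configs[3, , ] <- rigid_motion(base, -2.0, c(-1, 0)) * 0.3
  configs[4, , ] <- rigid_motion(base, 3.0, c(0, 9)) * 2.2
  g <- gpa(configs)
  expect_true(g$converged)
  for (i in 2:4)
    expect_lt(max(abs(g$aligned[i, , ] - g$aligned[1, , ])), 1e-8)
  # total Procrustes variance is zero
  dev <- sweep(matrix(g$aligned, 4, 16), 2, as.numeric(g$consensus))
  expect_lt(sum(dev^2), 1e-12)
})

test_that("aligned configurations are centred with unit centroid size", {
  ss <- small_cohort()
  g <- gpa(landmark_dataset(ss$true_landmarks, host_id = ss$host_id))
  m <- dim(g$aligned)[1]
  for (i in c(1L, 50L, m)) {
    cfg <- g$aligned[i, , ]
    expect_lt(max(abs(colMeans(cfg))), 1e-10)
    expect_equal(centroid_size(cfg), 1, tolerance = 1e-10)
  }
  # the consensus is the renormalized coordinate-wise mean of the aligned
  mn <- colMeans(matrix(g$aligned, m, 16))
  mn <- mn / sqrt(sum(mn^2))
  expect_equal(mn, c(g$consensus[, 1], g$consensus[, 2]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two-configuration GPA matches a rotation-grid brute force", {
  set.seed(7)
  for (rep in 1:3) {
    z1 <- ceratomorph:::as_cpx(random_config(3))
    z2 <- ceratomorph:::as_cpx(random_config(3))
    z1 <- z1 - mean(z1); z1 <- z1 / sqrt(sum(Mod(z1)^2))
    z2 <- z2 - mean(z2); z2 <- z2 / sqrt(sum(Mod(z2)^2))
    grid <- seq(0, 2 * pi, by = 1e-4)
    obj <- vapply(grid, function(th) {
      z2r <- z2 * exp(1i * th)
      cons <- (z1 + z2r) / 2
      cons <- cons / sqrt(sum(Mod(cons)^2))
      sum(Mod(z1 - cons)^2) + sum(Mod(z2r - cons)^2)
    }, numeric(1))
    best <- min(obj)
    configs <- array(NA_real_, c(2, 3, 2))
    configs[1, , ] <- cbind(Re(z1), Im(z1))
    configs[2, , ] <- cbind(Re(z2), Im(z2))
    g <- gpa(configs)
    cons_flat <- c(g$consensus[, 1], g$consensus[, 2])
    ss_pkg <- sum(sweep(matrix(g$aligned, 2, 6), 2, cons_flat)^2)
    expect_lt(abs(ss_pkg - best), 1e-6)
  }
})

test_that("GPA is invariant to the order of configurations", {
  ss <- small_cohort()
  configs <- ss$true_landmarks[1:20, , ]
  g1 <- gpa(configs)
  perm <- c(7, 3, 20, 1, 12, 5, 18, 2, 9, 15, 4, 11, 19, 6, 13, 8, 16, 10, 17, 14)
  g2 <- gpa(configs[perm, , ])
  expect_equal(g2$consensus, g1$consensus, tolerance = 1e-7)
  expect_equal(g2$aligned[order(perm)[1], , ], g1$aligned[1, , ],
               tolerance = 1e-7)
})

test_that("GPA objective never increases across iterations", {
  # re-run the iteration by hand and track the objective
  ss <- small_cohort()
  Z <- matrix(complex(real = ss$true_landmarks[1:30, , 1],
                      imaginary = ss$true_landmarks[1:30, , 2]), 30, 8)
  Z <- Z - rowMeans(Z)
  Z <- Z / sqrt(rowSums(Mod(Z)^2))
  cons <- Z[1, ] / sqrt(sum(Mod(Z[1, ])^2))
  obj <- numeric(0)
  for (it in 1:20) {
    ip <- Z %*% Conj(cons)
    Z <- Z * as.vector(Conj(ip) / Mod(ip))
    cons_new <- colMeans(Z); cons_new <- cons_new - mean(cons_new)
    cons_new <- cons_new / sqrt(sum(Mod(cons_new)^2))
    obj <- c(obj, sum(Mod(sweep(Z, 2, cons_new, "-"))^2))
    cons <- cons_new
  }
  expect_true(all(diff(obj) < 1e-12))
})

test_that("procrustes distance matches a rotation-grid brute force", {
  set.seed(3)
  a <- random_config(3); b <- random_config(3)
  za <- ceratomorph:::as_cpx(a); zb <- ceratomorph:::as_cpx(b)
  za <- za - mean(za); za <- za / sqrt(sum(Mod(za)^2))
  zb <- zb - mean(zb); zb <- zb / sqrt(sum(Mod(zb)^2))
  grid <- seq(0, 2 * pi, by = 1e-5)
  brute <- sqrt(min(vapply(grid, function(th)
    sum(Mod(za - zb * exp(1i * th))^2), numeric(1))))
  expect_equal(procrustes_distance(a, b)$chord, brute, tolerance = 1e-6)
  # invariances and the mirror case
  expect_lt(procrustes_distance(a, rigid_motion(a, 1.2, c(3, 4)) * 2)$chord, 1e-12)
  mirror <- cbind(-a[, 1], a[, 2])
  expect_gt(procrustes_distance(a, mirror)$chord, 1e-3)
})

test_that("tangent projection behaves like a local linearization", {
  ss <- small_cohort()
  g <- gpa(ss$true_landmarks)
  X <- tangent_projection(g)
  expect_lt(max(abs(colMeans(X))), 1e-3)
  # consensus itself maps to the zero tangent vector
  g2 <- g
  g2$aligned[1, , ] <- g$consensus
  X2 <- tangent_projection(g2)
  expect_lt(max(abs(X2[1, ])), 1e-12)
  # chord and geodesic distances agree to first order for tiny deviations
  eps <- 1e-5
  c1 <- g$consensus + eps * matrix(c(1, -1), 8, 2)
  c2 <- g$consensus - eps * matrix(c(1, -1), 8, 2)
  pd <- procrustes_distance(c1, c2)
  expect_equal(pd$chord / pd$rho, 1, tolerance = 1e-6)
})

test_that("tangent-space check reports near-perfect agreement for small variation", {
  spec <- plain_spec(seed = 9L, n = 30L, mode1_sd = 0.02, mode2_sd = 0.01,
                     digitization_sd = 0, size_cv = 0.05)
  ss <- sample_population(spec)
  g <- gpa(ss$true_landmarks)
  chk <- tangent_space_check(g)
  expect_gt(chk$correlation, 0.9999)
  expect_equal(chk$slope, 1, tolerance = 1e-3)
  # the default calibrated cohort still shows an adequate tangent space
  ss2 <- small_cohort()
  chk2 <- tangent_space_check(gpa(ss2$true_landmarks))
  expect_gt(chk2$correlation, 0.99)
})

test_that("total squared distance to consensus matches tangent SS to first order", {
  spec <- plain_spec(seed = 13L, n = 40L, mode1_sd = 0.02, mode2_sd = 0.01,
                     digitization_sd = 0, size_cv = 0.05)
  ss <- sample_population(spec)
  g <- gpa(ss$true_landmarks)
  X <- tangent_projection(g)
  rho2 <- vapply(seq_len(40), function(i)
    procrustes_distance(g$aligned[i, , ], g$consensus)$rho^2, numeric(1))
  expect_equal(sum(X^2) / sum(rho2), 1, tolerance = 1e-3)
})
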