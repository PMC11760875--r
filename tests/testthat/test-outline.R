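# Crescent outline construction and the synthetic population generator.

test_that("the mean outline is a simple, counterclockwise, symmetric polygon", {
  p <- crescent_params(10, pi / 2, 4, 1)
  o <- make_mean_outline(p, 400)
  expect_gte(nrow(o$vertices), 200)
  expect_gt(ceratomorph:::polygon_area(o$vertices), 0)
  expect_true(ceratomorph:::is_simple_polygon(o$vertices))
  # mirror symmetry about the suture (y) axis: reflected vertex set equals
  # the original vertex set
  v <- o$vertices
  refl <- cbind(-v[, 1], v[, 2])
  d <- vapply(seq_len(nrow(v)), function(i) {
    min(sqrt((refl[, 1] - v[i, 1])^2 + (refl[, 2] - v[i, 2])^2))
  }, numeric(1))
  expect_lt(max(d), 1e-9)
  # suture points lie on the polygon
  expect_true(any(abs(v[, 1] - o$suture_anterior[1]) +
                  abs(v[, 2] - o$suture_anterior[2]) < 1e-12))
  expect_true(any(abs(v[, 1] - o$suture_posterior[1]) +
                  abs(v[, 2] - o$suture_posterior[2]) < 1e-12))
})

test_that("degenerate crescent parameters are rejected with a diagnostic", {
  expect_error(crescent_params(5, 1, 6), "self-intersects")
  expect_error(crescent_params(5, 3.5, 1), "0, pi")
  expect_error(crescent_params(-1, 1, 0.5), "positive")
  expect_error(make_mean_outline(mean_crescent(), 50), "at least 200")
})

test_that("the calibrated mean outline reproduces the printed measurements", {
  o <- make_mean_outline(default_calibration()$mean_params, 512)
  m <- measure_traditional(construct_landmarks(o))
  expect_lt(abs(m$length - 8.6) / 8.6, 0.02)
  expect_lt(abs(m$thickness - 20.5) / 20.5, 0.02)
  expect_lt(abs(m$posterior_angle - 104.3) / 104.3, 0.02)
})

test_that("a zero-noise population collapses onto the scaled mean outline", {
  spec <- population_spec(mean_crescent(), host_count = 1L, host_sizes = 6L,
                          mean_size = 2, n_vertices = 256L, seed = 3L)
  ss <- sample_population(spec)
  ref <- ss$true_landmarks[1, , ]
  for (i in 2:6) expect_equal(ss$true_landmarks[i, , ], ref, tolerance = 1e-12)
  # scaled copy of the unit mean configuration
  o <- make_mean_outline(mean_crescent(), 256)
  base <- construct_landmarks(o)
  cs0 <- centroid_size(base)
  expect_equal(unname(centroid_size(ref) / cs0), 2, tolerance = 1e-9)
})

test_that("zero asymmetry gives exactly mirror-symmetric true landmarks", {
  spec <- plain_spec(seed = 21L, n = 12L, mode1_sd = 0.1, mode2_sd = 0.03,
                     asymmetry_sd = 0)
  ss <- sample_population(spec)
  for (i in c(1L, 5L, 12L)) {
    cfg <- ss$true_landmarks[i, , ]
    d <- procrustes_distance(cfg, reflect_relabel(cfg))$chord
    expect_lt(d, 1e-9)
  }
})

test_that("the generator is deterministic and seed-sensitive", {
  spec <- default_calibration(seed = 17L)
  a <- suppressWarnings(sample_population(spec))
  b <- suppressWarnings(sample_population(spec))
  expect_identical(a$true_landmarks, b$true_landmarks)
  expect_identical(a$true_sizes, b$true_sizes)
  c <- suppressWarnings(sample_population(default_calibration(seed = 18L)))
  expect_false(isTRUE(all.equal(a$true_landmarks, c$true_landmarks)))
})

test_that("replicate digitization noise has the stated variance structure", {
  spec <- plain_spec(seed = 8L, n = 400L, mode1_sd = 0, mode2_sd = 0,
                     size_cv = 0, digitization_sd = 0.1)
  ss <- sample_population(spec)
  ds <- digitize_replicates(ss, 2L)
  diffs <- ds$coords[, 1, , ] - ds$coords[, 2, , ]
  # difference of two independent noises: variance 2 * sd^2
  expect_equal(stats::var(as.numeric(diffs)), 2 * 0.1^2, tolerance = 0.08)
  ds0 <- digitize_replicates(ss, 3L, digitization_sd = 0)
  expect_equal(ds0$coords[, 1, , ], ds0$coords[, 3, , ], tolerance = 1e-15)
})

test_that("default calibration is frozen, pure, and has the published design", {
  s1 <- default_calibration(); s2 <- default_calibration()
  expect_identical(s1, s2)
  expect_identical(s1$host_sizes, c(20L, 16L, 19L, 17L, 35L))
  expect_identical(sum(s1$host_sizes), 107L)
  expect_identical(s1$n_replicates, 2L)
})

test_that("asymmetric variance share rises monotonically with asymmetry_sd", {
  pct <- vapply(c(0.3, 1.0, 2.5), function(a) {
    spec <- default_calibration(seed = 33L)
    spec$asymmetry_sd <- a
    ss <- suppressWarnings(sample_population(spec, size_multiplier = 4L))
    ds <- landmark_dataset(ss$true_landmarks, host_id = ss$host_id)
    decompose_symmetry(ds)$pct_asymmetric
  }, numeric(1))
  expect_true(all(diff(pct) > 0))
})
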