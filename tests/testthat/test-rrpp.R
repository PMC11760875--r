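# Sequential Procrustes ANOVA/ANCOVA, RRPP inference, dispersion test.

test_that("univariate pseudo-F equals the classical one-way ANOVA F", {
  set.seed(30)
  y <- rnorm(24) + rep(c(0, 1), each = 12)
  host <- factor(rep(1:2, each = 12))
  tab <- fit_sequential(model_spec(matrix(y), host = host, terms = "host"))
  fit <- stats::anova(stats::lm(y ~ host))
  expect_equal(tab["host", "F"], fit$`F value`[1], tolerance = 1e-9)
  expect_equal(tab["host", "SS"], fit$`Sum Sq`[1], tolerance = 1e-9)
  expect_equal(tab["Residuals", "SS"], fit$`Sum Sq`[2], tolerance = 1e-9)
})

test_that("noise-free responses are fully explained", {
  host <- factor(rep(1:3, each = 5))
  size <- rnorm(15)
  Y <- cbind(as.integer(host), 2 * size, as.integer(host) - size)
  tab <- fit_sequential(model_spec(Y, size = size, host = host,
                                   terms = c("size", "host")))
  expect_lt(tab["Residuals", "SS"] / tab["Total", "SS"], 1e-12)
  expect_equal(tab["size", "Rsq"] + tab["host", "Rsq"], 1, tolerance = 1e-9)
})

test_that("sequential SS depend on term order but their sum does not", {
  set.seed(31)
  n <- 40
  host <- factor(rep(1:4, each = 10))
  size <- rnorm(n) + as.integer(host) * 0.5
  Y <- matrix(rnorm(n * 6), n) + outer(size, rnorm(6))
  t1 <- fit_sequential(model_spec(Y, size = size, host = host,
                                  terms = c("size", "host")))
  t2 <- fit_sequential(model_spec(Y, size = size, host = host,
                                  terms = c("host", "size")))
  expect_false(isTRUE(all.equal(t1["size", "SS"], t2["size", "SS"])))
  expect_equal(t1["size", "SS"] + t1["host", "SS"],
               t2["size", "SS"] + t2["host", "SS"], tolerance = 1e-9)
  expect_equal(t1["Residuals", "SS"], t2["Residuals", "SS"], tolerance = 1e-9)
  expect_equal(t1["Total", "SS"], t2["Total", "SS"], tolerance = 1e-9)
})

test_that("SS additivity and df accounting hold on random designs", {
  set.seed(32)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    k <- sample(2:4, 1)
    host <- factor(sample(1:k, n, replace = TRUE))
    while (min(table(host)) < 3) host <- factor(sample(1:k, n, replace = TRUE))
    size <- rnorm(n)
    Y <- matrix(rnorm(n * 5), n)
    tab <- fit_sequential(model_spec(Y, size = size, host = host,
                                     terms = c("size", "host", "size:host")))
    terms <- setdiff(rownames(tab), c("Residuals", "Total"))
    expect_equal(sum(tab[terms, "SS"]) + tab["Residuals", "SS"],
                 tab["Total", "SS"], tolerance = 1e-9)
    expect_identical(sum(tab[terms, "Df"]) + tab["Residuals", "Df"],
                     tab["Total", "Df"])
  }
})

test_that("aliased designs are rejected with the term named", {
  host <- factor(rep(1:2, each = 6))
  size <- as.integer(host)  # size is the host indicator: aliased
  Y <- matrix(rnorm(24), 12)
  expect_error(fit_sequential(model_spec(Y, size = size, host = host,
                                         terms = c("size", "host"))),
               "aliased.*host|host.*aliased")
  expect_error(model_spec(Y, size = size, host = host, terms = "size:host"),
               "requires both")
})

test_that("RRPP with the identity permutation reproduces the observed F", {
  set.seed(33)
  y <- rnorm(15)
  host <- factor(rep(1:3, each = 5))
  tab <- suppressWarnings(rrpp_test(model_spec(matrix(y), host = host,
                                               terms = "host", n_perm = 1L)))
  fit <- fit_sequential(model_spec(matrix(y), host = host, terms = "host"))
  expect_equal(tab["host", "F"], fit["host", "F"], tolerance = 1e-12)
  expect_equal(tab["host", "p"], 1)  # only the observed arrangement
})

test_that("permutation p has minimum 1/n_perm and is deterministic by seed", {
  set.seed(34)
  y <- c(rnorm(6), rnorm(6) + 50)  # overwhelming effect
  host <- factor(rep(1:2, each = 6))
  tab <- size_anova(y, host, n_perm = 200L, seed = 9L)
  expect_equal(tab["host", "p"], 1 / 200)
  tab2 <- size_anova(y, host, n_perm = 200L, seed = 9L)
  expect_identical(tab$p, tab2$p)
  expect_identical(tab$Z, tab2$Z)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration for small m", {
  set.seed(35)
  m <- 6L
  y <- rnorm(m) + c(0, 0, 0, 1.5, 1.5, 1.5)
  host <- factor(rep(1:2, each = 3))
  # exhaustive oracle: for a one-term model the RRPP null permutes the
  # centred response rows; enumerate all m! arrangements
  f_of <- function(yy) {
    tab <- fit_sequential(model_spec(matrix(yy), host = host, terms = "host"))
    tab["host", "F"]
  }
  f_obs <- f_of(y)
  perms <- all_permutations(m)
  fs <- apply(perms, 1, function(p) f_of(y[p]))
  p_exact <- mean(fs >= f_obs - 1e-12)
  tab <- size_anova(y, host, n_perm = 4999L, seed = 2L)
  expect_lt(abs(tab["host", "p"] - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 4999) + 1e-3)
})

test_that("size ANOVA handles degenerate and near-deterministic cases", {
  host <- factor(rep(1:2, each = 3))
  tab0 <- fit_sequential(model_spec(matrix(rep(c(1, 1, 1, 1, 1, 1))),
                                    host = host, terms = "host"))
  expect_equal(tab0["host", "SS"], 0, tolerance = 1e-12)
  set.seed(36)
  y <- c(1, 1, 1, 2, 2, 2) + rnorm(6, sd = 1e-4)
  tab <- size_anova(y, host, n_perm = 500L, seed = 1L)
  expect_lte(tab["host", "p"], 0.12)  # best attainable with 6!/(3!3!2) ties
  expect_gt(tab["host", "Rsq"], 0.999)
})

test_that("dispersion test distances and permutation logic are sound", {
  set.seed(37)
  X <- matrix(rnorm(60 * 4), 60)
  g <- factor(rep(1:3, each = 20))
  res <- dispersion_test(X, g, n_perm = 499L, seed = 3L)
  expect_length(res$distances, 60)
  expect_length(res$per_group_mean_distance, 3)
  # duplicating every specimen leaves per-group mean distances unchanged
  X2 <- rbind(X, X); g2 <- factor(c(g, g))
  res2 <- dispersion_test(X2, g2, n_perm = 499L, seed = 3L)
  expect_equal(res2$per_group_mean_distance, res$per_group_mean_distance,
               tolerance = 1e-12)
  # a group with 3x scaled deviations is detected
  X3 <- X
  X3[g == 2, ] <- X3[g == 2, ] * 3
  res3 <- dispersion_test(X3, g, n_perm = 999L, seed = 4L)
  expect_lt(res3$p, 0.01)
  expect_error(dispersion_test(X[1:3, ], factor(c(1, 2, 2))), "ingleton")
})

test_that("dispersion distances match vegan's betadisper", {
  skip_if_not_installed("vegan")
  set.seed(38)
  X <- matrix(rnorm(45 * 6), 45)
  g <- factor(rep(1:3, each = 15))
  res <- dispersion_test(X, g, n_perm = 99L, seed = 1L)
  bd <- vegan::betadisper(stats::dist(X), g, type = "centroid")
  expect_equal(unname(res$distances), unname(bd$distances), tolerance = 1e-8)
  an <- stats::anova(bd)
  expect_equal(res$F, an$`F value`[1], tolerance = 1e-8)
})

test_that("planted allometry is detected and its absence is not", {
  # with a planted slope and small noise the size term is significant at
  # alpha = 0.01 in nearly every cohort; with slope 0 at the nominal rate
  base <- function(slope, seed) {
    spec <- population_spec(mean_crescent(), mode1_sd = 0.03, mode2_sd = 0.01,
                            host_count = 1L, host_sizes = 30L,
                            allometric_slope = slope, size_cv = 0.12,
                            digitization_sd = 0, seed = seed,
                            n_vertices = 256L, exact_moments = FALSE)
    ss <- sample_population(spec)
    g <- gpa(ss$true_landmarks)
    X <- tangent_projection(g)
    cs <- vapply(seq_len(30), function(i) centroid_size(ss$true_landmarks[i, , ]),
                 numeric(1))
    tab <- rrpp_test(model_spec(X, size = cs, terms = "size",
                                n_perm = 199L, seed = seed))
    tab["size", "p"]
  }
  p_alt <- vapply(1:25, function(i) base(0.01, 100L + i), numeric(1))
  expect_gte(mean(p_alt <= 0.01), 0.92)
  p_null <- vapply(1:25, function(i) base(0, 200L + i), numeric(1))
  expect_lte(mean(p_null <= 0.01), 0.12)
})
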