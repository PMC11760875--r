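# Morphospace analysis: covariance PCA of tangent-space shape coordinates,
# the eigenvalue-ratio retention rule, landmark contributions per PC,
# extreme-shape reconstruction, convex hulls of host groups, and thin-plate
# spline deformation grids.

#' Principal component analysis of shape coordinates
#'
#' Eigen-decomposition of the covariance matrix of tangent-space shape
#' coordinates. PC signs follow a deterministic convention: the
#' largest-magnitude loading of each PC is positive.
#'
#' @param coords m x 2k matrix of tangent coordinates (landmark-major), as
#'   from [tangent_projection()].
#' @return Object of class `shape_pca`: `eigenvalues` (descending),
#'   `loadings` (2k x m' orthonormal columns), `scores` (m x m'),
#'   `variance_pct`, `center` (the coordinate-wise mean).
#' @export
shape_pca <- function(coords) {
  coords <- as.matrix(coords)
  m <- nrow(coords)
  if (m < 3L) stop_cm("PCA needs at least 3 specimens")
  center <- colMeans(coords)
  Xc <- sweep(coords, 2L, center)
  if (sum(Xc^2) == 0) stop_cm("zero-variance input: PCA undefined")
  S <- stats::cov(Xc)
  ev <- eigen(S, symmetric = TRUE)
  keep <- seq_len(min(m - 1L, ncol(coords)))
  vals <- pmax(ev$values[keep], 0)
  vecs <- ev$vectors[, keep, drop = FALSE]
  # sign convention: largest-|loading| entry positive
  for (j in seq_along(keep)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  res <- list(eigenvalues = vals, loadings = vecs,
              scores = Xc %*% vecs,
              variance_pct = 100 * vals / sum(vals),
              center = center)
  class(res) <- "shape_pca"
  res
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("Shape PCA\n")
  for (j in seq_len(k))
    cat(sprintf("  PC%d: %6.2f %% of variance\n", j, x$variance_pct[j]))
  invisible(x)
}

#' Number of meaningful principal components
#'
#' Applies the eigenvalue-ratio retention rule: a PC is meaningful while its
#' eigenvalue is at least `ratio_threshold` times that of its successor,
#' counting the maximal leading run. The final eigenvalue, having no
#' successor, is never counted.
#'
#' @param eigenvalues Nonnegative eigenvalues in descending order.
#' @param ratio_threshold Ratio threshold (default 1.32, the log-likelihood
#'   based value used for shape data).
#' @return Integer count of meaningful PCs.
#' @export
#' @examples
#' meaningful_pcs(c(10, 5, 1))   # 2
#' meaningful_pcs(c(10, 9, 1))   # 0
meaningful_pcs <- function(eigenvalues, ratio_threshold = 1.32) {
  if (length(eigenvalues) < 2L) stop_cm("need at least 2 eigenvalues")
  lam <- as.numeric(eigenvalues)
  n <- length(lam)
  count <- 0L
  for (i in seq_len(n - 1L)) {
    ok <- if (lam[i + 1L] == 0) lam[i] > 0 else lam[i] >= ratio_threshold * lam[i + 1L]
    if (!ok) break
    count <- count + 1L
  }
  count
}

#' Proportional landmark contributions to a principal component
#'
#' The contribution of a landmark to a PC is the share of that PC's squared
#' loadings carried by the landmark's x and y entries. Landmarks above
#' 100/8 = 12.5% contribute more than average.
#'
#' @param pca A [shape_pca()] result.
#' @param pc_index Which PC.
#' @return Named numeric vector of 8 percentages (summing to 100), with
#'   attribute `above_average` (logical).
#' @export
landmark_contributions <- function(pca, pc_index = 1L) {
  stopifnot(inherits(pca, "shape_pca"))
  if (pc_index > ncol(pca$loadings)) stop_cm("pc_index exceeds retained PCs")
  v <- pca$loadings[, pc_index]
  k <- length(v) / 2L
  per_lm <- v[seq(1L, 2L * k, 2L)]^2 + v[seq(2L, 2L * k, 2L)]^2
  pct <- 100 * per_lm / sum(per_lm)
  names(pct) <- paste0("L", seq_len(k))
  attr(pct, "above_average") <- pct > 100 / k
  pct
}

#' Reconstruct an extreme shape along a principal component
#'
#' Returns the landmark configuration at the minimum or maximum observed
#' score of a PC: consensus plus that score times the loading vector.
#'
#' @param pca A [shape_pca()] result.
#' @param consensus 8 x 2 consensus configuration (Procrustes frame).
#' @param pc_index Which PC.
#' @param sign `"max"` or `"min"`: which end of the observed score range.
#' @return 8 x 2 landmark configuration.
#' @export
extreme_shapes <- function(pca, consensus, pc_index = 1L,
                           sign = c("max", "min")) {
  stopifnot(inherits(pca, "shape_pca"))
  sign <- match.arg(sign)
  s <- if (sign == "max") max(pca$scores[, pc_index]) else min(pca$scores[, pc_index])
  # tangent coordinates are deviations from the consensus (their mean is
  # pca$center, approximately zero), so the reconstruction displaces the
  # consensus by the scored loading vector
  unflatten_config(as.numeric(t(consensus)) + pca$center + s * pca$loadings[, pc_index])
}

#' Thin-plate-spline deformation grid
#'
#' Exact interpolating thin-plate spline (kernel `U(r) = r^2 log r^2`,
#' `U(0) = 0`) mapping a source landmark configuration onto a target, applied
#' to a regular lattice to visualize the deformation, with the bending
#' energy of the non-affine part.
#'
#' @param source,target k x 2 landmark matrices (source not collinear).
#' @param lattice Optional n x 2 matrix of lattice points; by default a
#'   `grid_n` x `grid_n` lattice spanning the source configuration with 15%
#'   margin.
#' @param grid_n Lattice resolution per side.
#' @return Object of class `deformation_grid`: `source_grid`, `warped_grid`,
#'   `control_source`, `control_target`, `bending_energy`, `grid_dim`.
#' @export
tps_warp <- function(source, target, lattice = NULL, grid_n = 24L) {
  check_config(source, "source"); check_config(target, "target")
  if (nrow(source) != nrow(target)) stop_cm("landmark counts differ")
  k <- nrow(source)
  if (qr(cbind(1, source))$rank < 3L)
    stop_cm("source landmarks are collinear: TPS undefined")
  U <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2))
  d2 <- as.matrix(stats::dist(source))^2
  K <- U(d2)
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  rhs <- rbind(target, matrix(0, 3L, 2L))
  coefs <- solve(L, rhs)
  W <- coefs[seq_len(k), , drop = FALSE]
  A <- coefs[k + 1:3, , drop = FALSE]
  if (is.null(lattice)) {
    rng_x <- range(source[, 1]); rng_y <- range(source[, 2])
    pad_x <- 0.15 * diff(rng_x); pad_y <- 0.15 * diff(rng_y)
    gx <- seq(rng_x[1] - pad_x, rng_x[2] + pad_x, length.out = grid_n)
    gy <- seq(rng_y[1] - pad_y, rng_y[2] + pad_y, length.out = grid_n)
    lattice <- as.matrix(expand.grid(x = gx, y = gy))
    grid_dim <- c(grid_n, grid_n)
  } else {
    lattice <- as.matrix(lattice)
    grid_dim <- attr(lattice, "grid_dim") %||% c(nrow(lattice), 1L)
  }
  warp_points <- function(pts) {
    dx <- outer(pts[, 1], source[, 1], "-")
    dy <- outer(pts[, 2], source[, 2], "-")
    B <- U(dx^2 + dy^2)
    cbind(1, pts) %*% A + B %*% W
  }
  bending <- sum(diag(t(W) %*% K %*% W))
  res <- list(source_grid = lattice, warped_grid = warp_points(lattice),
              control_source = source, control_target = target,
              bending_energy = max(bending, 0), grid_dim = grid_dim,
              warp = warp_points)
  class(res) <- "deformation_grid"
  res
}

#' @export
print.deformation_grid <- function(x, ...) {
  cat(sprintf("TPS deformation grid: %d control points, bending energy %.4g\n",
              nrow(x$control_source), x$bending_energy))
  invisible(x)
}

#' Per-group convex hulls in a 2-D ordination
#'
#' Convex hulls of the specimens of each group in a two-dimensional score
#' space, used to visualize the portion of morphospace occupied by spores
#' from different hosts.
#'
#' @param scores m x 2 matrix (e.g. PC1/PC2 scores).
#' @param groups Length-m group labels.
#' @return Named list, per group: `vertices` (hull polygon, counterclockwise),
#'   `degenerate` flag (fewer than 3 non-collinear points).
#' @export
convex_hulls <- function(scores, groups) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L) stop_cm("scores must have 2 columns")
  groups <- factor(groups)
  out <- lapply(levels(groups), function(g) {
    pts <- scores[groups == g, , drop = FALSE]
    if (nrow(pts) < 3L) return(list(vertices = pts, degenerate = TRUE))
    idx <- grDevices::chull(pts)                 # returned clockwise
    hull <- pts[rev(idx), , drop = FALSE]
    degen <- nrow(hull) < 3L || abs(polygon_area(hull)) < .Machine$double.eps
    list(vertices = hull, degenerate = degen)
  })
  names(out) <- levels(groups)
  out
}
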