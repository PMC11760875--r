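# Superimposition machinery. Two-dimensional configurations are handled as
# complex vectors: centering removes the mean, unit centroid size is unit
# Frobenius norm, and the optimal (reflection-free) rotation aligning z to c
# is multiplication by the phase of the complex inner product sum(Conj(z)*c).

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid - the standard geometric-morphometric size measure.
#'
#' @param config A k x 2 coordinate matrix.
#' @return Positive scalar (um).
#' @export
#' @examples
#' centroid_size(cbind(c(-.5, .5, .5, -.5), c(-.5, -.5, .5, .5)))  # sqrt(2)
centroid_size <- function(config) {
  check_config(config)
  if (nrow(config) < 2L) stop_cm("need at least 2 landmarks")
  centered <- sweep(config, 2L, colMeans(config))
  cs <- sqrt(sum(centered^2))
  if (cs == 0) stop_cm("all landmarks coincide: centroid size undefined")
  cs
}

# coerce supported inputs to an m x k complex matrix of configurations
configs_to_complex <- function(x) {
  if (inherits(x, "landmark_dataset")) {
    d <- dim(x$coords)
    m <- d[1] * d[2]
    Z <- matrix(NA_complex_, m, d[3])
    info <- data.frame(specimen = rep(seq_len(d[1]), each = d[2]),
                       replicate = rep(seq_len(d[2]), d[1]))
    r <- 1L
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      Z[r, ] <- complex(real = x$coords[i, j, , 1], imaginary = x$coords[i, j, , 2])
      r <- r + 1L
    }
    attr(Z, "info") <- info
    return(Z)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    Z <- matrix(complex(real = aperm(x, c(1, 2, 3))[, , 1],
                        imaginary = x[, , 2]), d[1], d[2])
    return(Z)
  }
  if (is.list(x)) {
    Z <- t(vapply(x, function(cfg) as_cpx(cfg), complex(nrow(x[[1]]))))
    return(Z)
  }
  stop_cm("unsupported input for GPA: expected landmark_dataset, ",
          "n x k x 2 array, or list of k x 2 matrices")
}

#' Generalized Procrustes analysis
#'
#' Iterative least-squares superimposition removing location, scale and
#' orientation: configurations are centred, scaled to unit centroid size and
#' rotated (reflections excluded) to the running consensus, which is
#' re-estimated until its root-mean-square change falls below `tol`. The
#' converged consensus is rotated to its principal axes for a deterministic
#' coordinate frame.
#'
#' @param x A `landmark_dataset` (replicates are flattened into the
#'   configuration list), an n x k x 2 array, or a list of k x 2 matrices.
#' @param tol Convergence tolerance on the consensus RMS change.
#' @param max_iter Maximum number of iterations.
#' @return Object of class `gpa_result`: `aligned` (n x k x 2 array of
#'   Procrustes coordinates, unit centroid size), `consensus` (k x 2, unit
#'   size), `centroid_sizes` (um), `iterations`, `converged`, and `info`
#'   (specimen/replicate bookkeeping when the input had replicates).
#' @export
gpa <- function(x, tol = 1e-10, max_iter = 100L) {
  Z <- configs_to_complex(x)
  info <- attr(Z, "info")
  m <- nrow(Z); k <- ncol(Z)
  if (m < 2L) stop_cm("GPA needs at least 2 configurations")
  Z <- Z - rowMeans(Z)
  cs <- sqrt(rowSums(Mod(Z)^2))
  if (any(cs == 0)) stop_cm("degenerate configuration (zero centroid size)")
  Z <- Z / cs
  consensus <- Z[1, ]
  consensus <- consensus / sqrt(sum(Mod(consensus)^2))
  iterations <- 0L; converged <- FALSE
  repeat {
    iterations <- iterations + 1L
    ip <- Z %*% Conj(consensus)              # m x 1 complex inner products
    phase <- Conj(ip) / Mod(ip)
    Z <- Z * as.vector(phase)
    new_cons <- colMeans(Z)
    new_cons <- new_cons - mean(new_cons)
    new_cons <- new_cons / sqrt(sum(Mod(new_cons)^2))
    delta <- sqrt(mean(Mod(new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations (last RMS change ",
            format(delta, digits = 3), ")")
  # deterministic frame: principal axes of the consensus, major axis on x,
  # with the first landmark in the upper half-plane
  cmat <- as_mat(consensus)
  ev <- eigen(stats::cov(cmat), symmetric = TRUE)
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  rot <- exp(complex(imaginary = -ang))
  consensus <- consensus * rot
  Z <- Z * rot
  if (Im(consensus[1]) < 0) { consensus <- -consensus; Z <- -Z }
  aligned <- array(NA_real_, c(m, k, 2L),
                   dimnames = list(NULL, paste0("L", seq_len(k)), c("x", "y")))
  aligned[, , 1] <- Re(Z); aligned[, , 2] <- Im(Z)
  res <- list(aligned = aligned, consensus = as_mat(consensus, paste0("L", seq_len(k))),
              centroid_sizes = cs, iterations = iterations,
              converged = converged, info = info)
  class(res) <- "gpa_result"
  res
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf("GPA: %d configurations x %d landmarks, %d iterations (%s)\n",
              dim(x$aligned)[1], dim(x$aligned)[2], x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  centroid size range %.3f - %.3f um\n",
              min(x$centroid_sizes), max(x$centroid_sizes)))
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Partial Procrustes chord distance between the centred, unit-size,
#' optimally rotated (reflections excluded) configurations, together with
#' the geodesic (Procrustes) distance `rho = 2 asin(d / 2)`.
#'
#' @param a,b k x 2 coordinate matrices with matching landmark count.
#' @return List with `chord` and `rho`.
#' @export
procrustes_distance <- function(a, b) {
  check_config(a, "a"); check_config(b, "b")
  if (nrow(a) != nrow(b)) stop_cm("configurations differ in landmark count")
  za <- as_cpx(a); zb <- as_cpx(b)
  za <- za - mean(za); zb <- zb - mean(zb)
  na <- sqrt(sum(Mod(za)^2)); nb <- sqrt(sum(Mod(zb)^2))
  if (na == 0 || nb == 0) stop_cm("degenerate configuration")
  za <- za / na; zb <- zb / nb
  cosr <- min(Mod(sum(Conj(za) * zb)), 1)
  chord <- sqrt(max(2 - 2 * cosr, 0))
  list(chord = chord, rho = 2 * asin(min(chord / 2, 1)))
}

#' Project aligned configurations into the tangent space at the consensus
#'
#' Orthogonal projection of the Procrustes coordinates onto the tangent
#' space at the consensus shape: the complex span of the consensus (its
#' scale and in-plane rotation directions) is projected out of each aligned
#' configuration.
#'
#' @param gpa_res A converged [gpa()] result.
#' @return m x 2k real matrix of tangent coordinates, landmark-major
#'   (x1, y1, x2, y2, ...), with attribute `consensus`.
#' @export
tangent_projection <- function(gpa_res) {
  stopifnot(inherits(gpa_res, "gpa_result"))
  k <- dim(gpa_res$aligned)[2]
  Z <- matrix(complex(real = gpa_res$aligned[, , 1],
                      imaginary = gpa_res$aligned[, , 2]),
              dim(gpa_res$aligned)[1], k)
  cz <- as_cpx(gpa_res$consensus)
  cz <- cz / sqrt(sum(Mod(cz)^2))
  coef <- Z %*% Conj(cz)                   # complex projection coefficient
  tang <- Z - as.vector(coef) %*% t(cz)
  out <- flatten_configs(tang)
  attr(out, "consensus") <- gpa_res$consensus
  out
}

#' Tangent-space adequacy check
#'
#' Over all specimen pairs, regresses (through the origin) the Euclidean
#' distance in tangent space on the Procrustes geodesic distance and
#' reports the least-squares slope and the uncentred correlation. Values
#' near 1 indicate that the tangent-space approximation to shape space is
#' adequate for subsequent multivariate analyses.
#'
#' @param gpa_res A converged [gpa()] result.
#' @return List with `slope` and `correlation`.
#' @export
tangent_space_check <- function(gpa_res) {
  stopifnot(inherits(gpa_res, "gpa_result"))
  m <- dim(gpa_res$aligned)[1]
  if (m < 3L) stop_cm("need at least 3 configurations")
  k <- dim(gpa_res$aligned)[2]
  Z <- matrix(complex(real = gpa_res$aligned[, , 1],
                      imaginary = gpa_res$aligned[, , 2]), m, k)
  # geodesic distances from pairwise complex inner products
  G <- Mod(Z %*% Conj(t(Z)))
  G <- pmin(G, 1)
  rho <- 2 * asin(pmin(sqrt(pmax(2 - 2 * G, 0)) / 2, 1))
  X <- tangent_projection(gpa_res)
  td <- as.matrix(stats::dist(X))
  up <- upper.tri(rho)
  x <- rho[up]; y <- td[up]
  if (sum(x^2) == 0) return(list(slope = 1, correlation = 1))
  list(slope = sum(x * y) / sum(x^2),
       correlation = sum(x * y) / sqrt(sum(x^2) * sum(y^2)))
}
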