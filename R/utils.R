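# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

# Landmark labels and the bilateral pairing of the eight-landmark scheme.
# L1 anterior suture point, L5 posterior suture point (midline, unpaired);
# (L2,L8), (L3,L7), (L4,L6) are left/right pairs across the suture axis.
LM_LABELS <- paste0("L", 1:8)

#' Bilateral pairing of the eight-landmark scheme
#'
#' The suture line is the bilateral symmetry axis of a ceratomyxid spore in
#' sutural view. Landmarks L1 (anterior suture point) and L5 (posterior
#' suture point) lie on the axis; (L2, L8), (L3, L7) and (L4, L6) are
#' left/right pairs.
#'
#' @return A list with `pairs` (3 x 2 integer matrix), `midline` (integer
#'   vector) and `relabel`, the length-8 permutation that swaps paired
#'   landmarks (an involution fixing L1 and L5).
#' @export
#' @examples
#' p <- landmark_pairing()
#' p$relabel[p$relabel]  # involution: identity
landmark_pairing <- function() {
  list(
    pairs = rbind(c(2L, 8L), c(3L, 7L), c(4L, 6L)),
    midline = c(1L, 5L),
    relabel = c(1L, 8L, 7L, 6L, 5L, 4L, 3L, 2L)
  )
}

stop_cm <- function(...) stop(..., call. = FALSE)

# k x 2 real matrix -> complex vector and back
as_cpx <- function(m) complex(real = m[, 1], imaginary = m[, 2])
as_mat <- function(z, labels = NULL) {
  m <- cbind(x = Re(z), y = Im(z))
  if (!is.null(labels)) rownames(m) <- labels
  m
}

# validate an 8 x 2 landmark configuration
check_config <- function(config, arg = "config") {
  if (!is.matrix(config) || ncol(config) != 2L)
    stop_cm(arg, " must be a k x 2 coordinate matrix")
  if (any(!is.finite(config)))
    stop_cm(arg, " contains non-finite coordinates")
  invisible(config)
}

# Flatten aligned k x 2 configurations (rows of a complex m x k matrix) to
# an m x 2k real matrix, landmark-major: x1, y1, x2, y2, ...
flatten_configs <- function(Z) {
  m <- nrow(Z); k <- ncol(Z)
  out <- matrix(0, m, 2L * k)
  out[, seq(1L, 2L * k, by = 2L)] <- Re(Z)
  out[, seq(2L, 2L * k, by = 2L)] <- Im(Z)
  colnames(out) <- paste0(rep(paste0("L", seq_len(k)), each = 2L), c("_x", "_y"))
  out
}

unflatten_config <- function(v, labels = LM_LABELS) {
  k <- length(v) / 2L
  m <- cbind(x = v[seq(1L, 2L * k, by = 2L)], y = v[seq(2L, 2L * k, by = 2L)])
  rownames(m) <- labels
  m
}

# signed area of a polygon given as an n x 2 matrix (no repeated last vertex)
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  i2 <- c(seq_len(nrow(v))[-1L], 1L)
  sum(x * y[i2] - x[i2] * y) / 2
}

# Naive O(n^2) segment-crossing test on a decimated copy of the polygon;
# used only on the error path when validating user-supplied parameters.
is_simple_polygon <- function(v, max_vertices = 160L) {
  n <- nrow(v)
  if (n > max_vertices) {
    keep <- unique(round(seq(1L, n, length.out = max_vertices)))
    v <- v[keep, , drop = FALSE]
    n <- nrow(v)
  }
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    j <- seq.int(i + 2L, n)
    if (i == 1L) j <- j[j != n]  # skip edges sharing a vertex with edge 1
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
    d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
    d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

# cubic smoothstep ramp used to blend one-valve perturbations to zero at the
# suture: 0 for s >= 0, 1 for s <= -width
left_ramp <- function(s, width = 0.5) {
  u <- pmin(pmax(-s / width, 0), 1)
  u * u * (3 - 2 * u)
}

# draw a derived stream seed (kept below 2^31) from a root seed and offset
stream_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(offset)
}
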