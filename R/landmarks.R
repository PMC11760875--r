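# The eight-landmark construction on spore outlines and the traditional
# spore measurements (length, thickness, posterior angle).
#
# L1 = anterior suture point, L5 = posterior suture point, L3/L7 = left/right
# valve tips (maximal boundary curvature). L2/L8 (anterior) and L4/L6
# (posterior) are constructed landmarks: for each tip T, a line perpendicular
# to the segment M-T at its midpoint (M being the midpoint of the suture
# chord L1-L5) is intersected with the outline; the intersection on the
# convex side gives the outer landmark, the one on the concave side the
# inner landmark.

#' Detect the valve tips of a spore outline
#'
#' Finds the two boundary points of maximal smoothed discrete curvature, one
#' on each lateral half of the outline (halves split by the oriented suture
#' axis). Curvature is estimated per vertex as the inverse circumradius of
#' the vertex and its two neighbours, then smoothed with a centred moving
#' average.
#'
#' @param outline A `spore_outline` (or any list with `vertices`,
#'   `suture_anterior`, `suture_posterior`).
#' @param smooth_window Odd width (vertices) of the curvature smoothing
#'   window.
#' @return List with `left` and `right` tip coordinates (length-2 vectors)
#'   and their vertex indices `left_index`, `right_index`.
#' @export
detect_tips <- function(outline, smooth_window = 7L) {
  v <- outline$vertices
  n <- nrow(v)
  if (n < 10L) stop_cm("outline has too few vertices")
  if (smooth_window %% 2L != 1L) stop_cm("smooth_window must be odd")
  prev <- v[c(n, 1:(n - 1L)), , drop = FALSE]
  nxt <- v[c(2:n, 1L), , drop = FALSE]
  # circumradius curvature: |cross| / (|a||b||c|), a,b,c triangle side vectors
  ax <- v[, 1] - prev[, 1]; ay <- v[, 2] - prev[, 2]
  bx <- nxt[, 1] - v[, 1]; by <- nxt[, 2] - v[, 2]
  cx <- nxt[, 1] - prev[, 1]; cy <- nxt[, 2] - prev[, 2]
  cross <- ax * by - ay * bx
  la <- sqrt(ax^2 + ay^2); lb <- sqrt(bx^2 + by^2); lc <- sqrt(cx^2 + cy^2)
  kappa <- abs(2 * cross / pmax(la * lb * lc, .Machine$double.eps))
  # centred moving average on the closed curve
  half <- (smooth_window - 1L) %/% 2L
  padded <- c(kappa[(n - half + 1L):n], kappa, kappa[1:half])
  sm <- stats::filter(padded, rep(1 / smooth_window, smooth_window), sides = 2L)
  kappa_s <- as.numeric(sm[(half + 1L):(half + n)])
  # lateral halves by sign of cross product with the oriented suture axis
  axis_dir <- outline$suture_anterior - outline$suture_posterior
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  mid <- (outline$suture_anterior + outline$suture_posterior) / 2
  side_val <- axis_dir[1] * (v[, 2] - mid[2]) - axis_dir[2] * (v[, 1] - mid[1])
  tol <- 1e-9 * max(abs(v))
  left <- side_val > tol
  right <- side_val < -tol
  if (!any(left) || !any(right)) stop_cm("tips not resolvable: outline does not straddle the suture axis")
  i_left <- which(left)[which.max(kappa_s[left])]
  i_right <- which(right)[which.max(kappa_s[right])]
  # a circle-like outline has no distinct curvature maxima
  spread <- stats::sd(kappa_s) / max(mean(kappa_s), .Machine$double.eps)
  if (spread < 1e-4)
    stop_cm("tips not resolvable: boundary curvature is uniform")
  list(left = v[i_left, ], right = v[i_right, ],
       left_index = i_left, right_index = i_right)
}

# Intersections of the line q + t * dir with polygon edges; returns a matrix
# of intersection points (possibly zero rows). Near-duplicate hits at shared
# vertices are merged.
line_polygon_intersections <- function(v, q, dir) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  # solve q + t*dir = a + s*e
  det <- dir[1] * (-ey) - dir[2] * (-ex)
  ok <- abs(det) > 1e-14
  rx <- a[, 1] - q[1]; ry <- a[, 2] - q[2]
  t <- (rx * (-ey) - ry * (-ex)) / det
  s <- (dir[1] * ry - dir[2] * rx) / det
  hit <- ok & s >= 0 & s < 1
  if (!any(hit)) return(matrix(0, 0, 2))
  pts <- cbind(q[1] + t[hit] * dir[1], q[2] + t[hit] * dir[2])
  tt <- t[hit]
  o <- order(tt)
  pts <- pts[o, , drop = FALSE]; tt <- tt[o]
  if (length(tt) > 1L) {
    scale <- max(abs(v))
    keep <- c(TRUE, diff(tt) > 1e-9 * scale)
    pts <- pts[keep, , drop = FALSE]
  }
  pts
}

#' Construct the eight-landmark configuration from a spore outline
#'
#' Places L1/L5 at the annotated suture points, L3/L7 at the detected valve
#' tips, and constructs L2/L8 (anterior margin) and L4/L6 (posterior margin)
#' by intersecting, for each tip, the perpendicular at the midpoint of the
#' segment from the suture-chord midpoint to that tip with the outline.
#'
#' @inheritParams detect_tips
#' @param tips Optional precomputed result of [detect_tips()].
#' @return An 8 x 2 landmark matrix (um) with rownames `L1..L8`, ordered
#'   L1 (anterior suture), L2, L3 (left tip), L4, L5 (posterior suture),
#'   L6, L7 (right tip), L8.
#' @export
#' @examples
#' o <- make_mean_outline(crescent_params(10.4, 1.75, 4.3), 400)
#' construct_landmarks(o)
construct_landmarks <- function(outline, tips = NULL, smooth_window = 7L) {
  v <- outline$vertices
  L1 <- as.numeric(outline$suture_anterior)
  L5 <- as.numeric(outline$suture_posterior)
  if (is.null(tips)) tips <- detect_tips(outline, smooth_window)
  M <- (L1 + L5) / 2
  axis_dir <- (L1 - L5) / sqrt(sum((L1 - L5)^2))
  scale <- max(abs(v))
  place <- function(Tp) {
    Q <- (M + Tp) / 2
    d <- Tp - M
    perp <- c(-d[2], d[1])
    pts <- line_polygon_intersections(v, Q, perp)
    if (nrow(pts) == 0L)
      stop_cm("landmark construction failed: perpendicular misses the outline")
    # keep intersections on the tip's lateral half
    side_of <- function(p) axis_dir[1] * (p[, 2] - M[2]) - axis_dir[2] * (p[, 1] - M[1])
    tip_side <- sign(side_of(rbind(Tp)))
    sv <- side_of(pts)
    pts <- pts[sign(sv) == as.numeric(tip_side) | abs(sv) < 1e-9 * scale, , drop = FALSE]
    if (nrow(pts) != 2L)
      stop_cm("landmark construction failed: expected 2 transversal ",
              "intersections on the tip side, found ", nrow(pts))
    # anterior (convex-side) intersection has the larger projection on the
    # oriented suture axis
    proj <- (pts[, 1] - Q[1]) * axis_dir[1] + (pts[, 2] - Q[2]) * axis_dir[2]
    list(outer = pts[which.max(proj), ], inner = pts[which.min(proj), ])
  }
  left <- place(as.numeric(tips$left))
  right <- place(as.numeric(tips$right))
  config <- rbind(L1, left$outer, tips$left, left$inner, L5,
                  right$inner, tips$right, right$outer)
  dimnames(config) <- list(LM_LABELS, c("x", "y"))
  config
}

#' Traditional spore measurements from a landmark configuration
#'
#' Computes the classical ceratomyxid descriptors: spore length as the
#' suture-axis diameter `|L1 - L5|`, thickness as the straight tip-to-tip
#' distance `|L3 - L7|`, and the posterior angle as the angle at L5 between
#' the rays to the two valve tips.
#'
#' @param config An 8 x 2 landmark matrix as from [construct_landmarks()].
#' @return List of class `traditional_measures` with `length` (um),
#'   `thickness` (um) and `posterior_angle` (degrees).
#' @export
#' @examples
#' cfg <- rbind(L1 = c(0, 1.5), L2 = c(-1, 1.2), L3 = c(-1, 1), L4 = c(-0.5, 0.4),
#'              L5 = c(0, 0), L6 = c(0.5, 0.4), L7 = c(1, 1), L8 = c(1, 1.2))
#' measure_traditional(cfg)
measure_traditional <- function(config) {
  check_config(config)
  if (nrow(config) != 8L) stop_cm("config must have exactly 8 landmarks")
  L1 <- config[1, ]; L3 <- config[3, ]; L5 <- config[5, ]; L7 <- config[7, ]
  len <- sqrt(sum((L1 - L5)^2))
  thick <- sqrt(sum((L3 - L7)^2))
  v1 <- L3 - L5; v2 <- L7 - L5
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (len == 0 || thick == 0 || n1 == 0 || n2 == 0)
    stop_cm("coincident landmarks: measurements undefined")
  ang <- acos(min(max(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
  out <- list(length = len, thickness = thick, posterior_angle = ang)
  class(out) <- "traditional_measures"
  out
}

#' @export
print.traditional_measures <- function(x, ...) {
  cat(sprintf("length %.3f um, thickness %.3f um, posterior angle %.2f deg\n",
              x$length, x$thickness, x$posterior_angle))
  invisible(x)
}
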