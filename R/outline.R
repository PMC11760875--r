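# Parametric crescent outlines for ceratomyxid spores in sutural view.
#
# The shape family is a circular-arc centerline of radius `centerline_radius`
# spanning +/- `centerline_half_angle` around the vertical suture axis, with a
# symmetric half-width profile w(t) = max_half_width * (1 - t^2)^taper_exponent
# offset along the centerline normals. The anterior (convex) margin is the
# outer offset, the posterior (concave) margin the inner offset; the two tips
# are where the width tapers to zero. All coordinates are continuous microns
# in a right-handed frame with the suture axis along +y.

#' Crescent shape parameters
#'
#' Parameters of the crescent shape family used to model ceratomyxid
#' myxospores: a circular-arc centerline with a polynomial width taper.
#'
#' @param centerline_radius Radius of the arc centerline (um), positive.
#' @param centerline_half_angle Half-angle spanned by the centerline arc
#'   (radians), in (0, pi). Larger values give more strongly arched spores
#'   and hence smaller posterior angles.
#' @param max_half_width Half-width of the spore at the suture axis (um);
#'   spore length in sutural view is twice this value.
#' @param taper_exponent Exponent of the width profile
#'   `(1 - t^2)^taper_exponent`, positive; values below 1 give blunt,
#'   rounded valve tips.
#' @return An object of class `crescent_params`.
#' @export
#' @examples
#' crescent_params(10.4, 1.75, 4.3, 0.5)
crescent_params <- function(centerline_radius, centerline_half_angle,
                            max_half_width, taper_exponent = 0.75) {
  p <- list(
    centerline_radius = as.numeric(centerline_radius),
    centerline_half_angle = as.numeric(centerline_half_angle),
    max_half_width = as.numeric(max_half_width),
    taper_exponent = as.numeric(taper_exponent)
  )
  class(p) <- "crescent_params"
  validate_crescent_params(p)
  p
}

validate_crescent_params <- function(p) {
  vals <- unlist(p[c("centerline_radius", "centerline_half_angle",
                     "max_half_width", "taper_exponent")])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_cm("crescent parameters must be positive and finite")
  if (p$centerline_half_angle >= pi)
    stop_cm("centerline_half_angle must lie in (0, pi)")
  if (p$max_half_width >= p$centerline_radius)
    stop_cm("max_half_width must be smaller than centerline_radius, ",
            "otherwise the posterior margin self-intersects")
  invisible(p)
}

#' @export
print.crescent_params <- function(x, ...) {
  cat("Crescent shape parameters\n")
  cat(sprintf("  centerline radius     %.4f um\n", x$centerline_radius))
  cat(sprintf("  centerline half-angle %.4f rad (%.1f deg)\n",
              x$centerline_half_angle, x$centerline_half_angle * 180 / pi))
  cat(sprintf("  max half-width        %.4f um\n", x$max_half_width))
  cat(sprintf("  taper exponent        %.3f\n", x$taper_exponent))
  invisible(x)
}

new_outline <- function(vertices, suture_anterior, suture_posterior,
                        tip_indices = NULL) {
  o <- list(vertices = vertices,
            suture_anterior = as.numeric(suture_anterior),
            suture_posterior = as.numeric(suture_posterior))
  if (!is.null(tip_indices)) attr(o, "tip_indices") <- tip_indices
  class(o) <- "spore_outline"
  o
}

#' @export
print.spore_outline <- function(x, ...) {
  cat(sprintf("Spore outline: %d vertices, suture axis length %.3f um\n",
              nrow(x$vertices),
              sqrt(sum((x$suture_anterior - x$suture_posterior)^2))))
  invisible(x)
}

# Evaluate crescent boundary vertices for (possibly per-vertex) parameter
# profiles. s is the centerline parameter in [-1, 1] (negative = left valve).
# phi_s, W_s, p_s are vectors matched to s. Returns outer and inner boundary
# point matrices ordered along s.
crescent_margins <- function(s, R, phi_s, W_s, p_s) {
  theta <- s * phi_s
  w <- W_s * (1 - s^2)^p_s
  outer <- cbind((R + w) * sin(theta), (R + w) * cos(theta))
  inner <- cbind((R - w) * sin(theta), (R - w) * cos(theta))
  list(outer = outer, inner = inner, w = w)
}

# Assemble a closed counterclockwise polygon from margin samples. The s grid
# must run from -1 to 1 and contain 0 and both endpoints.
assemble_outline <- function(s, margins) {
  n <- length(s)
  i0 <- which(s == 0)
  # counterclockwise: outer margin traversed right tip -> anterior apex ->
  # left tip, then inner margin left -> posterior -> right (tips shared once)
  outer_path <- margins$outer[n:1, , drop = FALSE]
  inner_path <- margins$inner[2:(n - 1L), , drop = FALSE]
  vertices <- rbind(outer_path, inner_path)
  anterior <- margins$outer[i0, ]
  posterior <- margins$inner[i0, ]
  tip_right <- 1L                    # s = 1 on outer path
  tip_left <- n                      # s = -1 on outer path
  new_outline(vertices, anterior, posterior,
              tip_indices = c(left = tip_left, right = tip_right))
}

#' Construct the mean crescent outline
#'
#' Builds a closed, counterclockwise, mirror-symmetric crescent outline from
#' shape parameters: a circular-arc centerline offset by a tapering
#' half-width profile. The two suture points (anterior apex of the convex
#' margin and posterior apex of the concave margin) are exact polygon
#' vertices and are annotated on the result.
#'
#' @param params A [crescent_params()] object.
#' @param n_vertices Target number of polygon vertices (at least 200).
#' @return A `spore_outline`: list with `vertices` (n x 2 matrix, um,
#'   counterclockwise, first vertex not repeated), `suture_anterior` and
#'   `suture_posterior` (length-2 points on the polygon).
#' @export
#' @examples
#' o <- make_mean_outline(crescent_params(10.4, 1.75, 4.3), 400)
#' nrow(o$vertices)
make_mean_outline <- function(params, n_vertices = 512L) {
  validate_crescent_params(params)
  if (n_vertices < 200L) stop_cm("n_vertices must be at least 200")
  s <- outline_s_grid(n_vertices)
  n <- length(s)
  margins <- crescent_margins(s, params$centerline_radius,
                              rep(params$centerline_half_angle, n),
                              rep(params$max_half_width, n),
                              rep(params$taper_exponent, n))
  out <- assemble_outline(s, margins)
  if (polygon_area(out$vertices) <= 0)
    stop_cm("internal error: outline orientation is not counterclockwise")
  out
}

# Symmetric s grid over [-1, 1] containing 0, sized so the closed polygon
# has ~n_vertices vertices (2 * nside - 2, tips shared between margins).
# Sine spacing concentrates vertices near s = +/-1, where the blunt valve
# tips need dense sampling for curvature-based tip detection.
outline_s_grid <- function(n_vertices) {
  nside <- ceiling((n_vertices + 2L) / 2)
  if (nside %% 2L == 0L) nside <- nside + 1L  # odd: include s = 0
  sin(pi / 2 * seq(-1, 1, length.out = nside))
}

# Specimen-level outline: symmetric modes shift the arc half-angle (mode 1,
# posterior-angle mode) and the log half-width (mode 2, length mode);
# left-valve-only perturbations of the same parameters plus the taper
# exponent inject bilateral asymmetry, blended to zero at the suture by a
# smooth ramp so the suture points stay on the axis. `size` scales the
# finished outline.
specimen_outline <- function(params, mode1 = 0, mode2 = 0,
                             asym = c(0, 0, 0), size = 1,
                             n_vertices = 512L, ramp_width = 0.5) {
  s <- outline_s_grid(n_vertices)
  n <- length(s)
  H <- left_ramp(s, ramp_width)
  phi0 <- params$centerline_half_angle + mode1
  phi0 <- min(max(phi0, 0.15), pi - 0.05)
  phi_s <- phi0 + asym[1] * H
  W_s <- params$max_half_width * exp(mode2 + asym[2] * H)
  p_s <- params$taper_exponent * exp(asym[3] * H)
  R <- params$centerline_radius
  W_s <- pmin(W_s, 0.97 * R)
  margins <- crescent_margins(s, R, phi_s, W_s, p_s)
  ok <- all(margins$w[-c(1L, n)] > 0) && all(R - margins$w > 0) &&
    all(diff(s * phi_s) > 0)
  out <- assemble_outline(s, margins)
  out$vertices <- out$vertices * size
  out$suture_anterior <- out$suture_anterior * size
  out$suture_posterior <- out$suture_posterior * size
  attr(out, "well_formed") <- ok && polygon_area(out$vertices) > 0
  out
}
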