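#' Simulate an 85-point hip shape annotation with known neck width
#'
#' Constructs a synthetic proximal-femur landmark set in which points 6-12
#' (inferior neck contour) and points 32-38 (superior contour) are two
#' circular arcs bowing away from each other, with the apex-to-apex
#' separation equal to \code{target_fnw_mm}: the neck is narrowest at the
#' arc apices and widens away from them, so at zero jitter the minimum
#' polyline distance recovers the target exactly. The remaining 71 points
#' form a closed elliptical femur/acetabulum outline (their geometry is
#' unconstrained and unused by width measurement). Annotation noise is
#' added as per-coordinate Gaussian jitter truncated at 1.5 standard
#' deviations — landmark placement error is bounded, so the recovered width
#' never exceeds the target by more than 3 \code{jitter_sd}. Coordinates
#' are returned in pixels (mm divided by the pixel spacing).
#'
#' @param target_fnw_mm designed minimum neck width in mm (> 0).
#' @param pixel_spacing mm per pixel; a scalar or c(x, y) for anisotropic
#'   spacing.
#' @param jitter_sd per-coordinate annotation noise in mm (>= 0).
#' @param seed integer seed.
#' @param arc_radius_mm radius of each neck contour arc (controls how fast
#'   the neck widens away from the apex).
#' @return a \linkS4class{ShapeAnnotation}.
#' @examples
#' ann <- simulateShapeAnnotation(31.7, pixel_spacing = 0.5, jitter_sd = 0,
#'                                seed = 7)
#' computeFNW(ann)$fnw_mm
#' @export
simulateShapeAnnotation <- function(target_fnw_mm, pixel_spacing = 0.5,
                                    jitter_sd = 0, seed = 1,
                                    arc_radius_mm = 16) {
  if (target_fnw_mm <= 0) stop("target_fnw_mm must be > 0")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(pixel_spacing <= 0)) stop("pixel_spacing must be > 0")
  set.seed(seed)
  R <- arc_radius_mm
  half <- target_fnw_mm / 2
  theta <- (-3:3) * (2 / R)                # 2 mm arc spacing, 7 points
  # inferior arc: apex at (0, -half), bows downward (image y grows downward)
  inf_arc <- cbind(R * sin(theta), -(R + half) + R * cos(theta))
  # superior arc: apex at (0, +half), bows upward
  sup_arc <- cbind(R * sin(theta), (R + half) - R * cos(theta))

  pts <- matrix(NA_real_, 85L, 2L)
  pts[6:12, ] <- inf_arc
  pts[32:38, ] <- sup_arc
  # remaining landmarks: a closed outline well clear of the neck gap
  rest <- setdiff(1:85, c(6:12, 32:38))
  ang <- seq(0, 2 * pi, length.out = length(rest) + 1L)[seq_along(rest)]
  pts[rest, ] <- cbind(60 * cos(ang), 70 * sin(ang))

  if (jitter_sd > 0) {
    jit <- matrix(stats::rnorm(85L * 2L, sd = jitter_sd), 85L, 2L)
    lim <- 1.5 * jitter_sd
    bad <- abs(jit) > lim
    while (any(bad)) {                     # bounded placement error
      jit[bad] <- stats::rnorm(sum(bad), sd = jitter_sd)
      bad <- abs(jit) > lim
    }
    pts <- pts + jit
  }
  # image coordinates: shift to positive quadrant, convert mm -> px
  pts[, 1] <- (pts[, 1] + 100) / pixel_spacing[1]
  pts[, 2] <- (pts[, 2] + 100) / pixel_spacing[2]
  new("ShapeAnnotation", points = pts,
      spacingX = pixel_spacing[1], spacingY = pixel_spacing[2])
}
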