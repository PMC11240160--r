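#' Minimum distance between two polylines
#'
#' Bidirectional point-to-segment minimization: the minimum over (i) the
#' distance from every vertex of \code{polyA} to every segment of
#' \code{polyB} and (ii) every vertex of \code{polyB} to every segment of
#' \code{polyA}. This is the exact minimum distance between two non-crossing
#' polylines and is symmetric in its arguments; it never exceeds the minimum
#' vertex-vertex distance. Crossing polylines return 0 with a warning.
#'
#' @param polyA,polyB numeric n x 2 matrices (n >= 2) of (x, y) vertices.
#' @return list with elements \code{distance}, and \code{argmin}: a list
#'   giving \code{side} ("A" or "B", the polyline contributing the vertex),
#'   \code{vertex} (its index), \code{segment} (index of the nearest segment
#'   on the other polyline) and \code{t} (parametric position in [0, 1]
#'   along that segment).
#' @examples
#' minPolylineDistance(rbind(c(0, 0), c(10, 0)), rbind(c(0, 5), c(10, 5)))
#' @export
minPolylineDistance <- function(polyA, polyB) {
  polyA <- as.matrix(polyA); polyB <- as.matrix(polyB)
  for (p in list(polyA, polyB)) {
    if (nrow(p) < 2L)
      stop("each polyline must have at least 2 points")
    if (!all(is.finite(p)))
      stop("polyline coordinates must be finite")
  }
  a <- .pointsToPolyline(polyA, polyB)
  b <- .pointsToPolyline(polyB, polyA)
  if (a$distance <= b$distance) {
    res <- list(distance = a$distance,
                argmin = list(side = "A", vertex = a$vertex,
                              segment = a$segment, t = a$t))
  } else {
    res <- list(distance = b$distance,
                argmin = list(side = "B", vertex = b$vertex,
                              segment = b$segment, t = b$t))
  }
  if (res$distance > 0 && .polylinesCross(polyA, polyB)) {
    warning("polylines cross; returning 0")
    res$distance <- 0
  }
  res
}

# min over vertices of `pts` of distance to polyline `poly`
.pointsToPolyline <- function(pts, poly) {
  n <- nrow(pts); m <- nrow(poly) - 1L
  p1 <- poly[-nrow(poly), , drop = FALSE]
  d  <- poly[-1L, , drop = FALSE] - p1          # segment direction vectors
  len2 <- rowSums(d * d)
  best <- list(distance = Inf, vertex = NA_integer_, segment = NA_integer_,
               t = NA_real_)
  for (i in seq_len(n)) {
    w <- sweep(p1, 2L, pts[i, ])                # p1 - point
    tt <- ifelse(len2 > 0, pmin(1, pmax(0, -rowSums(w * d) / len2)), 0)
    dx <- w[, 1] + tt * d[, 1]
    dy <- w[, 2] + tt * d[, 2]
    dist2 <- unname(dx * dx + dy * dy)
    j <- which.min(dist2)
    if (dist2[j] < best$distance^2)
      best <- list(distance = sqrt(dist2[j]), vertex = i, segment = j,
                   t = unname(tt[j]))
  }
  best
}

.polylinesCross <- function(polyA, polyB) {
  orient <- function(p, q, r)
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  for (i in seq_len(nrow(polyA) - 1L)) {
    for (j in seq_len(nrow(polyB) - 1L)) {
      p1 <- polyA[i, ]; p2 <- polyA[i + 1L, ]
      q1 <- polyB[j, ]; q2 <- polyB[j + 1L, ]
      if (orient(p1, p2, q1) * orient(p1, p2, q2) < 0 &&
          orient(q1, q2, p1) * orient(q1, q2, p2) < 0)
        return(TRUE)
    }
  }
  FALSE
}

#' Minimum femoral neck width from an 85-point annotation
#'
#' Extracts the inferior neck contour (points 6-12) and the superior contour
#' (points 32-38), converts pixel coordinates to millimetres (x scaled by
#' the column spacing, y by the row spacing; anisotropic spacing is
#' supported), and returns the minimum polyline-to-polyline distance — the
#' shortest distance between the superior and inferior femoral neck.
#'
#' @param annotation a \linkS4class{ShapeAnnotation}.
#' @return list with \code{fnw_mm} (minimum width, mm), \code{argmin} (the
#'   realizing vertex/segment pair as in \code{\link{minPolylineDistance}}),
#'   and \code{side_order} = c(inferior = "points 6-12",
#'   superior = "points 32-38").
#' @examples
#' ann <- simulateShapeAnnotation(30, pixel_spacing = 0.5, jitter_sd = 0,
#'                                seed = 1)
#' computeFNW(ann)$fnw_mm
#' @export
computeFNW <- function(annotation) {
  stopifnot(is(annotation, "ShapeAnnotation"))
  validObject(annotation)
  pts <- annotation@points
  inf_px <- pts[6:12, , drop = FALSE]
  sup_px <- pts[32:38, , drop = FALSE]
  if (!all(is.finite(inf_px)) || !all(is.finite(sup_px)))
    stop("non-finite coordinates among neck points 6-12 / 32-38")
  scale <- c(annotation@spacingX, annotation@spacingY)
  inf_mm <- sweep(inf_px, 2L, scale, `*`)
  sup_mm <- sweep(sup_px, 2L, scale, `*`)
  res <- minPolylineDistance(inf_mm, sup_mm)
  list(fnw_mm = res$distance, argmin = res$argmin,
       side_order = c(inferior = "points 6-12", superior = "points 32-38"))
}
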