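# Angular utilities and the four stimulus-to-wall metric operators.
#
# Coordinate convention throughout: x rightward, y downward (image
# convention, origin top-left). Angles are measured clockwise from
# horizontal, which with y-down is simply atan2(dy, dx). Wall orientations
# are undirected and reduced modulo 180 degrees.

DEG <- 180 / pi

#' Reduce an angle to the undirected-orientation range [0, 180)
#'
#' @param a Angle(s) in degrees.
#' @return Numeric vector in `[0, 180)`.
#' @export
deg_mod180 <- function(a) ((a %% 180) + 180) %% 180

#' Undirected orientation of a segment
#'
#' Orientation of the line through two endpoints, measured clockwise from
#' horizontal (x rightward, y downward) and reduced modulo 180 degrees, so
#' a segment and its reverse have the same orientation.
#'
#' @param x1,y1,x2,y2 Segment endpoint coordinates (vectorized).
#' @return Orientation(s) in degrees in `[0, 180)`.
#' @examples
#' wall_orientation(0, 0, 1, 0) # 0: horizontal
#' wall_orientation(0, 0, 0, 1) # 90: vertical
#' @export
wall_orientation <- function(x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  if (any(dx == 0 & dy == 0)) {
    abort("zero-length wall segment has no orientation",
          class = "combmetrics_degenerate")
  }
  deg_mod180(atan2(dy, dx) * DEG)
}

#' Angular divergence between two undirected orientations
#'
#' The smallest angle between two orientations under the 180-degree
#' periodic equivalence; symmetric in its arguments and bounded by 90.
#'
#' @param a,b Orientations in degrees (vectorized, recycled).
#' @return Divergence(s) in degrees in `[0, 90]`.
#' @examples
#' angular_divergence(10, 170) # 20, across the wrap
#' @export
angular_divergence <- function(a, b) {
  d <- abs(deg_mod180(a) - deg_mod180(b))
  pmin(d, 180 - d)
}

#' Orientation of the common tangent of a pit pair
#'
#' The common tangent is the line through the gap between two pits,
#' perpendicular to the line joining their centres: the orientation
#' predicted for a wall shared by the two cells the pits seed.
#'
#' @param ax,ay,bx,by Pit centre coordinates (mm; vectorized).
#' @return Orientation(s) in degrees in `[0, 180)`.
#' @export
common_tangent_orientation <- function(ax, ay, bx, by) {
  if (any(ax == bx & ay == by)) {
    abort("pit centres coincide; common tangent undefined",
          class = "combmetrics_degenerate")
  }
  deg_mod180(atan2(by - ay, bx - ax) * DEG + 90)
}

#' Orientation of the internal bisector of a V stimulus
#'
#' Direction of the internal-angle bisector ray at the apex (pointing into
#' the V opening), reduced modulo 180: the orientation predicted for the
#' wall conjoining the two cells seeded by the arms.
#'
#' @param eax,eay Coordinates of the end of the first arm (mm).
#' @param apx,apy Apex coordinates (mm).
#' @param ebx,eby Coordinates of the end of the second arm (mm).
#' @return Orientation in degrees in `[0, 180)`.
#' @export
bisection_orientation <- function(eax, eay, apx, apy, ebx, eby) {
  ua <- c(eax - apx, eay - apy)
  ub <- c(ebx - apx, eby - apy)
  na <- sqrt(sum(ua^2)); nb <- sqrt(sum(ub^2))
  if (na == 0 || nb == 0) {
    abort("V arm has zero length", class = "combmetrics_degenerate")
  }
  s <- ua / na + ub / nb
  if (sqrt(sum(s^2)) < 1e-12) {
    abort("V arms are anti-parallel (splay 180°); bisector undefined",
          class = "combmetrics_degenerate")
  }
  deg_mod180(atan2(s[2], s[1]) * DEG)
}

#' Direction (0-360) of the internal bisector ray, for generators
#' @inheritParams bisection_orientation
#' @return Direction in degrees in `[0, 360)`.
#' @keywords internal
bisection_direction <- function(eax, eay, apx, apy, ebx, eby) {
  ua <- c(eax - apx, eay - apy)
  ub <- c(ebx - apx, eby - apy)
  s <- ua / sqrt(sum(ua^2)) + ub / sqrt(sum(ub^2))
  (atan2(s[2], s[1]) * DEG) %% 360
}

#' Splay angle of a V stimulus
#'
#' Internal angle at the apex between the two arms, in degrees.
#'
#' @inheritParams bisection_orientation
#' @return Splay in degrees in `(0, 180)`.
#' @export
splay_angle <- function(eax, eay, apx, apy, ebx, eby) {
  ua <- c(eax - apx, eay - apy)
  ub <- c(ebx - apx, eby - apy)
  na <- sqrt(sum(ua^2)); nb <- sqrt(sum(ub^2))
  if (na == 0 || nb == 0) {
    abort("V arm has zero length", class = "combmetrics_degenerate")
  }
  cosang <- sum(ua * ub) / (na * nb)
  ang <- acos(pmin(1, pmax(-1, cosang))) * DEG
  if (ang <= 1e-9 || ang >= 180 - 1e-9) {
    abort("degenerate V: arms are collinear", class = "combmetrics_degenerate")
  }
  ang
}

#' Distance from points to a segment
#'
#' Euclidean distance from one or more points to a line segment,
#' vectorized over points (and recycled over segment coordinates).
#'
#' @param px,py Point coordinates.
#' @param x1,y1,x2,y2 Segment endpoints.
#' @return Numeric vector of distances.
#' @export
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx^2 + dy^2
  zero <- len2 == 0  # degenerate segment: distance to its single point
  t <- ((px - x1) * dx + (py - y1) * dy) / (len2 + zero)
  t <- pmin(1, pmax(0, t)) * !zero
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Does a wall lie between two pit centres?
#'
#' Decides the exclusion rule for pit-pair records: a measured wall counts
#' only if the infinite line through it crosses the open segment joining
#' the two pit centres. Walls whose line passes beyond either centre (or is
#' parallel and offset) are excluded from analysis.
#'
#' @param ax,ay,bx,by Pit centre coordinates (mm).
#' @param x1,y1,x2,y2 Wall endpoints (mm; vectorized over walls).
#' @return Logical vector, `TRUE` where the wall's line separates the two
#'   centres strictly.
#' @export
wall_between_centres <- function(ax, ay, bx, by, x1, y1, x2, y2) {
  if (any(x1 == x2 & y1 == y2)) {
    abort("zero-length wall segment", class = "combmetrics_degenerate")
  }
  # signed side of each centre w.r.t. the wall line
  sa <- (x2 - x1) * (ay - y1) - (y2 - y1) * (ax - x1)
  sb <- (x2 - x1) * (by - y1) - (y2 - y1) * (bx - x1)
  sa * sb < 0
}

#' Nearest and next-nearest wall corners to a point
#'
#' For each marked wall the "corner" is its endpoint nearer the apex. The
#' function returns the distance to the nearest wall's corner (`d1`), the
#' distance to the corner of the next-nearest *distinct* wall (`d2`), and
#' the wall ids involved. Ties are broken by wall order (first annotated
#' wins).
#'
#' @param px,py Apex coordinates (mm).
#' @param walls A data frame of walls with columns `wall_id`, `x1`, `y1`,
#'   `x2`, `y2` (mm).
#' @return A list with elements `d1`, `d2`, `wall_id1`, `wall_id2`.
#' @export
nearest_wall_corners <- function(px, py, walls) {
  if (nrow(walls) < 2) {
    abort("at least two walls are required to form d1 and d2",
          class = "combmetrics_precondition")
  }
  d1s <- sqrt((walls$x1 - px)^2 + (walls$y1 - py)^2)
  d2s <- sqrt((walls$x2 - px)^2 + (walls$y2 - py)^2)
  corner <- pmin(d1s, d2s)
  ord <- order(corner)  # stable: ties keep annotation order
  list(d1 = corner[ord[1]], d2 = corner[ord[2]],
       wall_id1 = walls$wall_id[ord[1]], wall_id2 = walls$wall_id[ord[2]])
}

#' Apex proximity ratio
#'
#' `P = d1 / (d1 + d2)` with `0 < d1 <= d2`, so `P` lies in `(0, 0.5]` and
#' equals 0.5 exactly when the two corners are equidistant. Small `P` means
#' the nearest wall sits at the apex.
#'
#' @param d1 Distance to the nearest wall corner (mm).
#' @param d2 Distance to the next-nearest distinct wall corner (mm).
#' @return The proximity ratio.
#' @export
proximity_ratio <- function(d1, d2) {
  if (any(d1 > d2)) {
    abort("d1 must not exceed d2", class = "combmetrics_precondition")
  }
  if (any(d1 < 0) || any(d2 <= 0)) {
    abort("corner distances must be positive", class = "combmetrics_precondition")
  }
  if (any(d1 == 0)) {
    warn("d1 = 0: wall corner exactly at the apex; proximity ratio is 0")
  }
  d1 / (d1 + d2)
}
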