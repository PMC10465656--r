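# Gauge-circle arc sets and the rim/wall angular-overlap operator.
#
# The rim-overlap metric formalizes the operator's visual judgement of
# rim-wall coincidence: a rim point counts as overlapped when it lies
# within tol_mm of any marked wall polyline. The overlapped set on the
# gauge circle is a union of arcs, computed analytically from circle/line
# and circle/circle intersections rather than by sampling.

#' Construct an arc set on a gauge circle
#'
#' An arc set is a collection of disjoint half-open angular intervals
#' `[start, end)` on a circle, in degrees, normalized so that arcs do not
#' wrap past 360 (a wrapping arc is split at 0/360) and overlapping arcs
#' are merged.
#'
#' @param start,end Numeric vectors of arc endpoints in degrees. `end` may
#'   be less than `start`, meaning the arc wraps through 0.
#' @return An object of class `comb_arcset`: a tibble with columns `start`
#'   and `end`, sorted and disjoint.
#' @export
arcset <- function(start = numeric(), end = numeric()) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0) {
    out <- qtb(start = numeric(), end = numeric())
    class(out) <- c("comb_arcset", class(out))
    return(out)
  }
  s <- start %% 360
  e <- end %% 360
  full <- (end - start) %% 360 == 0 & end != start
  # split wrapping arcs at 0/360
  wraps <- e < s & !full
  s2 <- c(s[!wraps], s[wraps], rep(0, sum(wraps)))
  e2 <- c(ifelse(full[!wraps], 360, e[!wraps]), rep(360, sum(wraps)), e[wraps])
  keep <- e2 > s2
  s2 <- s2[keep]; e2 <- e2[keep]
  ord <- order(s2)
  s2 <- s2[ord]; e2 <- e2[ord]
  # merge overlapping/adjacent intervals
  ms <- numeric(); me <- numeric()
  for (i in seq_along(s2)) {
    if (length(ms) > 0 && s2[i] <= me[length(me)] + 1e-12) {
      me[length(me)] <- max(me[length(me)], e2[i])
    } else {
      ms <- c(ms, s2[i]); me <- c(me, e2[i])
    }
  }
  out <- qtb(start = ms, end = me)
  class(out) <- c("comb_arcset", class(out))
  out
}

#' Total angular extent of an arc set
#'
#' @param arcs A `comb_arcset`.
#' @return Total degrees covered, in `[0, 360]`.
#' @export
arc_total <- function(arcs) {
  if (nrow(arcs) == 0) return(0)
  min(360, sum(arcs$end - arcs$start))
}

#' @export
print.comb_arcset <- function(x, ...) {
  cat(sprintf("<arc set: %d arc(s), %.2f degrees total>\n",
              nrow(x), arc_total(x)))
  if (nrow(x) > 0) print(as_tibble(x), ...)
  invisible(x)
}

# Solve A*cos(th) + B*sin(th) = C for th in radians; returns 0, 1 or 2 roots.
solve_trig <- function(A, B, C) {
  R <- sqrt(A^2 + B^2)
  if (R < 1e-15 || abs(C) > R) return(numeric())
  phi <- atan2(B, A)
  d <- acos(pmin(1, pmax(-1, C / R)))
  (c(phi + d, phi - d)) %% (2 * pi)
}

# Critical rim angles for one wall segment: angles where the distance from
# the rim point to the segment equals tol. These bound the overlapped arcs.
rim_critical_angles <- function(cx, cy, r, x1, y1, x2, y2, tol) {
  th <- numeric()
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  if (len > 0) {
    # offset lines parallel to the wall at distance +/- tol:
    # n . (p(th) - p1) = +/- tol with unit normal n
    nx <- -dy / len; ny <- dx / len
    h <- nx * (cx - x1) + ny * (cy - y1)
    A <- r * nx; B <- r * ny
    th <- c(th, solve_trig(A, B, tol - h), solve_trig(A, B, -tol - h))
  }
  # cap circles of radius tol at each endpoint:
  # |c + r e(th) - p|^2 = tol^2
  for (p in list(c(x1, y1), c(x2, y2))) {
    ddx <- cx - p[1]; ddy <- cy - p[2]
    A <- 2 * r * ddx; B <- 2 * r * ddy
    C <- tol^2 - (ddx^2 + ddy^2) - r^2
    th <- c(th, solve_trig(A, B, C))
  }
  th
}

#' Angular overlap between a pit rim and the built walls
#'
#' Computes the set of arcs of the gauge circle (the circle of
#' `gauge_diameter` mm drawn around the pit centre) whose points lie within
#' `tol_mm` of any wall segment, merged into a disjoint arc set. The total
#' of the arc set, in degrees, is the rim-overlap metric for the pit.
#'
#' The arcs are found analytically: for each wall the angles at which the
#' rim crosses the boundary of the wall's tolerance band (two offset lines
#' plus two endpoint cap circles) partition the circle into runs of
#' constant membership, and each run is classified by an exact point-to-
#' segment distance test at its midpoint.
#'
#' @param cx,cy Pit centre (mm).
#' @param walls Data frame of wall segments with columns `x1`, `y1`, `x2`,
#'   `y2` (mm). May have zero rows, giving an empty arc set.
#' @param gauge_diameter Diameter of the gauge circle in mm (default 4.0,
#'   the nominal nascent-cell size).
#' @param tol_mm Half-width of the coincidence band in mm (default 0.35,
#'   about half a natural wall thickness).
#' @return A `comb_arcset`; use [arc_total()] for the metric in degrees.
#' @examples
#' walls <- tibble::tibble(x1 = -10, y1 = 0, x2 = 10, y2 = 0)
#' arc_total(rim_wall_overlap(0, 0, walls)) # two antipodal arcs
#' @export
rim_wall_overlap <- function(cx, cy, walls, gauge_diameter = 4.0,
                             tol_mm = 0.35) {
  stopifnot(gauge_diameter > 0, tol_mm > 0)
  r <- gauge_diameter / 2
  if (is.null(walls) || nrow(walls) == 0) return(arcset())
  # only walls that can reach the annulus [r - tol, r + tol] matter
  dmin <- point_segment_distance(cx, cy, walls$x1, walls$y1,
                                 walls$x2, walls$y2)
  dmax <- pmax(sqrt((walls$x1 - cx)^2 + (walls$y1 - cy)^2),
               sqrt((walls$x2 - cx)^2 + (walls$y2 - cy)^2))
  walls <- walls[dmin <= r + tol_mm & dmax >= r - tol_mm, ]
  if (nrow(walls) == 0) return(arcset())
  starts <- numeric(); ends <- numeric()
  for (i in seq_len(nrow(walls))) {
    x1 <- walls$x1[i]; y1 <- walls$y1[i]
    x2 <- walls$x2[i]; y2 <- walls$y2[i]
    th <- rim_critical_angles(cx, cy, r, x1, y1, x2, y2, tol_mm)
    th <- sort(unique(c(0, th %% (2 * pi), 2 * pi)))
    mids <- (th[-length(th)] + th[-1]) / 2
    inside <- point_segment_distance(cx + r * cos(mids), cy + r * sin(mids),
                                     x1, y1, x2, y2) <= tol_mm
    if (any(inside)) {
      starts <- c(starts, th[-length(th)][inside] * DEG)
      ends <- c(ends, th[-1][inside] * DEG)
    }
  }
  arcset(starts, ends)
}
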