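# Raster rendering of synthetic tabs: grayscale before/after image pairs
# at the photographic calibration, for end-to-end visual checks and
# documentation. Pits render as dark discs, wax strips and built walls as
# bright ridges; the two images are related by the tab's stored
# before/after homography.

paint_disc <- function(img, cx, cy, r, value) {
  nr <- nrow(img); nc <- ncol(img)
  jlo <- max(1, floor(cx - r)); jhi <- min(nc, ceiling(cx + r))
  ilo <- max(1, floor(cy - r)); ihi <- min(nr, ceiling(cy + r))
  if (jhi < jlo || ihi < ilo) return(img)  # fully outside the image
  js <- jlo:jhi; is <- ilo:ihi
  px <- js - 0.5; py <- is - 0.5
  d2 <- outer(py, px, function(y, x) (x - cx)^2 + (y - cy)^2)
  img[is, js][d2 <= r^2] <- value
  img
}

paint_segment <- function(img, x1, y1, x2, y2, halfwidth, value) {
  nr <- nrow(img); nc <- ncol(img)
  jlo <- max(1, floor(min(x1, x2) - halfwidth))
  jhi <- min(nc, ceiling(max(x1, x2) + halfwidth))
  ilo <- max(1, floor(min(y1, y2) - halfwidth))
  ihi <- min(nr, ceiling(max(y1, y2) + halfwidth))
  if (jhi < jlo || ihi < ilo) return(img)  # fully outside the image
  js <- jlo:jhi; is <- ilo:ihi
  px <- js - 0.5; py <- is - 0.5
  d <- outer(py, px, function(y, x)
    point_segment_distance(x, y, x1, y1, x2, y2))
  img[is, js][d <= halfwidth] <- value
  img
}

clip_check <- function(xs, ys, nc, nr, what) {
  if (any(xs < 0 | xs > nc | ys < 0 | ys > nr)) {
    warn(sprintf("%s extends outside the tab image; clipped", what))
  }
}

render_stimuli <- function(img, stimuli, coords_fun, ppm) {
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(nrow(stimuli))) {
    s <- stimuli[i, ]
    if (s$is_control) next  # virtual stimuli are drawn, not physical
    lm <- coords_fun(s)
    clip_check(lm$x, lm$y, nc, nr, sprintf("stimulus %s", s$stimulus_id))
    gauge_px <- (if (is.na(s$gauge_diameter_mm)) 4 else
                   s$gauge_diameter_mm) / 2 * ppm
    get <- function(p) as.numeric(lm[lm$point == p, c("x", "y")])
    if (s$kind %in% c("pit")) {
      cc <- get("centre")
      img <- paint_disc(img, cc[1], cc[2], gauge_px, 0.35)
    }
    if (s$kind %in% c("pit_pair", "hybrid")) {
      for (p in c("centre_a", "centre_b")) {
        cc <- get(p)
        img <- paint_disc(img, cc[1], cc[2], gauge_px, 0.35)
      }
    }
    if (s$kind %in% c("v_form", "hybrid")) {
      ap <- get("apex")
      for (p in c("end_a", "end_b")) {
        e <- get(p)
        img <- paint_segment(img, ap[1], ap[2], e[1], e[2],
                             0.25 * ppm, 0.95)
      }
    }
  }
  img
}

#' Render a synthetic tab as a before/after grayscale image pair
#'
#' The before image shows the stimuli in the before-photograph pixel
#' frame; the after image shows the stimuli (mapped through the stored
#' alignment) plus the built walls in the after frame. Image dimensions
#' are the tab size times the calibration (a 25 x 40 mm tab at 9 px/mm
#' gives a 225 x 360 px image). Geometry outside the tab is clipped with
#' a warning.
#'
#' @param tab A `comb_tab` as produced by [generate_tab()] (stimuli in
#'   the before frame, walls in the after frame), or an already aligned
#'   tab, in which case only the after image carries content.
#' @param pixels_per_mm Calibration override; defaults to the tab's.
#' @return A list with matrices `before` and `after` (values in
#'   `[0, 1]`, rows = image height in px, columns = width).
#' @export
render_tab <- function(tab, pixels_per_mm = NULL) {
  stopifnot(inherits(tab, "comb_tab"))
  ppm <- pixels_per_mm %||% tab$pixels_per_mm
  nc <- round(tab$tab_size_mm[1] * ppm)
  nr <- round(tab$tab_size_mm[2] * ppm)
  bg <- 0.75
  before <- matrix(bg, nr, nc)
  after <- matrix(bg, nr, nc)
  aligned <- align_tab(tab)  # canonical after-frame geometry in mm
  to_after_px <- function(s) {
    lm <- s$landmarks[[1]]
    tibble(point = lm$point, x = lm$x * ppm, y = lm$y * ppm)
  }
  after <- render_stimuli(after, aligned$stimuli, to_after_px, ppm)
  if (nrow(aligned$walls) > 0) {
    w <- aligned$walls
    clip_check(c(w$x1, w$x2) * ppm, c(w$y1, w$y2) * ppm, nc, nr, "walls")
    for (i in seq_len(nrow(w))) {
      after <- paint_segment(after, w$x1[i] * ppm, w$y1[i] * ppm,
                             w$x2[i] * ppm, w$y2[i] * ppm, 0.25 * ppm, 1)
    }
  }
  if (any(tab$stimuli$frame == "image-before")) {
    to_before_px <- function(s) s$landmarks[[1]]
    before <- render_stimuli(before, tab$stimuli, to_before_px,
                             tab$pixels_per_mm)
  }
  list(before = before, after = after)
}

#' Write a rendered tab image pair to PNG files
#'
#' @param tab A `comb_tab`.
#' @param dir Output directory (created if missing).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_tab_images <- function(tab, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to write images",
          class = "combmetrics_io")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  imgs <- render_tab(tab)
  paths <- file.path(dir, paste0(tab$tab_id, c("_before.png", "_after.png")))
  png::writePNG(imgs$before, paths[1])
  png::writePNG(imgs$after, paths[2])
  invisible(paths)
}
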