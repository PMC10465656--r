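# Randomized virtual stimuli: the control populations.
#
# Each experiment's control set is built from computer-generated stimuli
# placed at random, measured exactly like the real ones: virtual pits are
# placed uniformly in a 10.0 mm disc around each real pit; virtual pit
# pairs get a uniform location and orientation with centre separation
# uniform on [5.0, 6.0] mm; virtual V forms get a uniform location and
# orientation with splay uniform on [90, 152.2] degrees.
#
# Randomness comes from R's global RNG so callers control reproducibility
# with set.seed() (or the `seed` arguments on the pipeline drivers, which
# scope the seed locally via withr).

in_bounds <- function(x, y, bounds) {
  x >= 0 & x <= bounds[1] & y >= 0 & y <= bounds[2]
}

#' Virtual pit control positions
#'
#' Draws centres uniformly in the disc of radius `radius_mm` (default
#' 10.0 mm) around a real pit centre, rejecting draws that fall outside
#' the tab rectangle.
#'
#' @param cx,cy Real pit centre (mm).
#' @param bounds Length-2 numeric: tab width and height in mm (the tab
#'   rectangle is `[0, w] x [0, h]`).
#' @param radius_mm Placement radius around the real pit (default 10.0).
#' @param n Number of virtual pits to draw.
#' @param max_rejections Abort after this many consecutive failed draws.
#' @return Tibble with columns `x`, `y` (one row per virtual pit).
#' @export
virtual_pit <- function(cx, cy, bounds, radius_mm = 10.0, n = 1,
                        max_rejections = 1000) {
  stopifnot(radius_mm > 0, n >= 1)
  if (!in_bounds(cx, cy, bounds)) {
    abort("real pit lies outside the tab bounds",
          class = "combmetrics_precondition")
  }
  out_x <- numeric(n); out_y <- numeric(n)
  todo <- seq_len(n)
  rejections <- 0
  while (length(todo) > 0) {
    m <- length(todo)
    r <- radius_mm * sqrt(runif(m))   # uniform in disc: density of r is 2r/R^2
    th <- runif(m, 0, 2 * pi)
    x <- cx + r * cos(th); y <- cy + r * sin(th)
    ok <- in_bounds(x, y, bounds)
    out_x[todo[ok]] <- x[ok]; out_y[todo[ok]] <- y[ok]
    rejections <- if (any(ok)) 0 else rejections + m
    if (rejections > max_rejections) {
      abort("tab bounds too small to place a virtual pit",
            class = "combmetrics_degenerate")
    }
    todo <- todo[!ok]
  }
  tibble(x = out_x, y = out_y)
}

#' Virtual pit-pair controls
#'
#' Draws pairs with midpoint uniform in the tab rectangle, orientation of
#' the centre-centre line uniform on `[0, 180)` degrees, and separation
#' uniform on `sep_range` mm (default `[5.0, 6.0]`). Draws whose centres
#' fall outside the tab are rejected.
#'
#' @inheritParams virtual_pit
#' @param sep_range Length-2 numeric range of centre-to-centre separation.
#' @return Tibble with pit centres `ax, ay, bx, by`, the midpoint
#'   `mid_x, mid_y`, `orientation_deg` of the centre line, and
#'   `separation_mm`.
#' @export
virtual_pit_pair <- function(bounds, sep_range = c(5.0, 6.0), n = 1,
                             max_rejections = 1000) {
  stopifnot(n >= 1, length(sep_range) == 2, all(sep_range > 0))
  out <- vector("list", n)
  todo <- seq_len(n)
  rejections <- 0
  while (length(todo) > 0) {
    m <- length(todo)
    mx <- runif(m, 0, bounds[1]); my <- runif(m, 0, bounds[2])
    ang <- runif(m, 0, 180)
    sep <- runif(m, sep_range[1], sep_range[2])
    ux <- cos(ang / DEG); uy <- sin(ang / DEG)
    ax <- mx - sep / 2 * ux; ay <- my - sep / 2 * uy
    bx <- mx + sep / 2 * ux; by <- my + sep / 2 * uy
    ok <- in_bounds(ax, ay, bounds) & in_bounds(bx, by, bounds)
    for (k in which(ok)) {
      out[[todo[k]]] <- tibble(ax = ax[k], ay = ay[k], bx = bx[k], by = by[k],
                               mid_x = mx[k], mid_y = my[k],
                               orientation_deg = ang[k],
                               separation_mm = sep[k])
    }
    rejections <- if (any(ok)) 0 else rejections + m
    if (rejections > max_rejections) {
      abort("tab bounds too small to place a virtual pit pair",
            class = "combmetrics_degenerate")
    }
    todo <- todo[!ok]
  }
  dplyr::bind_rows(out)
}

#' Virtual V-form controls
#'
#' Draws V stimuli with apex uniform in the tab rectangle, bisector
#' direction uniform on `[0, 360)` degrees, and splay uniform on
#' `splay_range` degrees (default `[90, 152.2]`). The arm length only
#' serves to define the arm directions for marking; it does not enter any
#' metric. Draws whose arm ends fall outside the tab are rejected.
#'
#' @inheritParams virtual_pit
#' @param splay_range Length-2 numeric range of the internal apex angle in
#'   degrees.
#' @param arm_length_mm Length of each arm in mm (default 6).
#' @return Tibble with `apex_x, apex_y`, arm ends `end_ax, end_ay,
#'   end_bx, end_by`, `bisector_dir_deg` (0-360) and `splay_deg`.
#' @export
virtual_v <- function(bounds, splay_range = c(90, 152.2),
                      arm_length_mm = 6, n = 1, max_rejections = 1000) {
  stopifnot(n >= 1, length(splay_range) == 2,
            splay_range[1] > 0, splay_range[2] < 180)
  out <- vector("list", n)
  todo <- seq_len(n)
  rejections <- 0
  while (length(todo) > 0) {
    m <- length(todo)
    px <- runif(m, 0, bounds[1]); py <- runif(m, 0, bounds[2])
    bis <- runif(m, 0, 360)
    splay <- runif(m, splay_range[1], splay_range[2])
    a1 <- (bis - splay / 2) / DEG
    a2 <- (bis + splay / 2) / DEG
    eax <- px + arm_length_mm * cos(a1); eay <- py + arm_length_mm * sin(a1)
    ebx <- px + arm_length_mm * cos(a2); eby <- py + arm_length_mm * sin(a2)
    ok <- in_bounds(eax, eay, bounds) & in_bounds(ebx, eby, bounds) &
      in_bounds(px, py, bounds)
    for (k in which(ok)) {
      out[[todo[k]]] <- tibble(apex_x = px[k], apex_y = py[k],
                               end_ax = eax[k], end_ay = eay[k],
                               end_bx = ebx[k], end_by = eby[k],
                               bisector_dir_deg = bis[k],
                               splay_deg = splay[k])
    }
    rejections <- if (any(ok)) 0 else rejections + m
    if (rejections > max_rejections) {
      abort("tab bounds too small to place a virtual V",
            class = "combmetrics_degenerate")
    }
    todo <- todo[!ok]
  }
  dplyr::bind_rows(out)
}

#' Add matched virtual controls to an aligned tab
#'
#' Appends one control stimulus per real stimulus, matched by kind: a
#' virtual pit within 10 mm of each real pit, a virtual pit pair per real
#' pair, and a virtual V per real V form. Hybrid stimuli receive no
#' randomized control (their comparison is paired within the stimulus).
#' Controls carry `is_control = TRUE` and ids prefixed `ctrl_`.
#'
#' @param tab An aligned `comb_tab` (all annotations in `world-mm`).
#' @param seed Optional integer seed, applied locally.
#' @return The tab with control stimuli appended.
#' @export
add_virtual_controls <- function(tab, seed = NULL) {
  stopifnot(inherits(tab, "comb_tab"))
  if (nrow(tab$stimuli) > 0 && any(tab$stimuli$frame != "world-mm")) {
    abort("tab must be aligned (world-mm) before adding controls",
          class = "combmetrics_precondition")
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  bounds <- tab$tab_size_mm
  real <- tab$stimuli[!tab$stimuli$is_control, ]
  ctrl <- vector("list", nrow(real))
  for (i in seq_len(nrow(real))) {
    s <- real[i, ]
    lm <- s$landmarks[[1]]
    cid <- paste0("ctrl_", s$stimulus_id)
    ctrl[[i]] <- switch(s$kind,
      pit = {
        cc <- lm[lm$point == "centre", ]
        v <- virtual_pit(cc$x, cc$y, bounds)
        make_stimulus(cid, "pit",
                      tibble(point = "centre", x = v$x, y = v$y),
                      frame = "world-mm",
                      gauge_diameter_mm = s$gauge_diameter_mm,
                      is_control = TRUE)
      },
      pit_pair = {
        v <- virtual_pit_pair(bounds)
        make_stimulus(cid, "pit_pair",
                      tibble(point = c("centre_a", "centre_b"),
                             x = c(v$ax, v$bx), y = c(v$ay, v$by)),
                      frame = "world-mm",
                      gauge_diameter_mm = s$gauge_diameter_mm,
                      is_control = TRUE)
      },
      v_form = {
        v <- virtual_v(bounds)
        make_stimulus(cid, "v_form",
                      tibble(point = c("end_a", "apex", "end_b"),
                             x = c(v$end_ax, v$apex_x, v$end_bx),
                             y = c(v$end_ay, v$apex_y, v$end_by)),
                      frame = "world-mm", is_control = TRUE)
      },
      hybrid = NULL)
  }
  tab$stimuli <- dplyr::bind_rows(tab$stimuli, dplyr::bind_rows(ctrl))
  tab
}
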