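# Synthetic annotated tabs with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# stimuli of the four kinds placed 10-15 mm apart on a 25 x 40 mm tab;
# one "response" wall per stimulus whose orientation follows the
# stimulus-predicted geometry with folded-normal angular noise (biased
# mode) or is entirely unrelated to the stimulus (null mode); distractor
# walls on a jittered hexagonal lattice at worker-cell pitch; and a mild
# projective before/after perturbation so the alignment stage is always
# exercised. It does not model the construction process itself - walls
# appear fully formed.

#' Specification for one synthetic tab
#'
#' @param kind Stimulus kind: `"pit"`, `"pit_pair"`, `"v_form"` or
#'   `"hybrid"`.
#' @param n_stimuli Stimuli per tab; defaults to 6 for pits and pit pairs,
#'   4 for V forms and hybrids (the densities used on real tabs).
#' @param tab_size_mm Tab width and height in mm (default `c(25, 40)`).
#' @param pixels_per_mm Photograph calibration (default 9).
#' @param sigma_deg Angular noise sd of response walls about the predicted
#'   orientation, degrees (default 5, the scale of the observed real-wall
#'   divergences).
#' @param offset_sd_mm Positional sd of the response-wall placement, mm
#'   (default 0.5).
#' @param bias `"biased"` (walls follow the stimulus geometry) or
#'   `"null"` (walls placed with uniform orientation and position,
#'   unrelated to the stimuli).
#' @param tangent_mix For hybrids: probability that a response wall
#'   follows the pit common tangent rather than the V bisection
#'   (default 2/3).
#' @param misalign_deg For hybrids: angle deliberately imposed between the
#'   tangent and the bisection (default 30).
#' @param sep_range_mm Pit-pair centre separation range (default
#'   `c(5, 6)`).
#' @param splay_range_deg V splay range in degrees (default
#'   `c(90, 152.2)`).
#' @param gauge_diameter_mm Pit gauge circle diameter (default 4).
#' @param wall_length_mm Length of response walls (default 4).
#' @param arm_length_mm V arm length (default 6).
#' @param pitch_mm Hexagonal distractor lattice pitch, centre to centre
#'   (default 5.2, worker-cell scale).
#' @param lattice_jitter_mm Vertex jitter sd of the distractor lattice
#'   (default 0.15).
#' @param clearance_mm Biased mode only: distractor walls closer than this
#'   to a stimulus anchor are removed so the response wall is the nearest
#'   (default 3).
#' @param spacing_mm Stimulus placement: minimum pairwise distance and
#'   maximum nearest-neighbour distance, mm (default `c(10, 15)`).
#' @param margin_mm Placement margin from the tab edge (default 4).
#' @param warp_px Maximum corner displacement of the synthetic
#'   before/after projective perturbation, in pixels (default 5,
#'   mirroring a fixed photographic jig).
#' @return A `synth_tab_spec` list.
#' @export
synth_tab_spec <- function(kind = c("pit", "pit_pair", "v_form", "hybrid"),
                           n_stimuli = NULL, tab_size_mm = c(25, 40),
                           pixels_per_mm = 9, sigma_deg = 5,
                           offset_sd_mm = 0.5,
                           bias = c("biased", "null"), tangent_mix = 2 / 3,
                           misalign_deg = 30, sep_range_mm = c(5, 6),
                           splay_range_deg = c(90, 152.2),
                           gauge_diameter_mm = 4, wall_length_mm = 4,
                           arm_length_mm = 6, pitch_mm = 5.2,
                           lattice_jitter_mm = 0.15, clearance_mm = 3,
                           spacing_mm = c(10, 15), margin_mm = 4,
                           warp_px = 5) {
  kind <- match.arg(kind)
  bias <- match.arg(bias)
  n_stimuli <- n_stimuli %||% switch(kind, pit = 6, pit_pair = 6,
                                     v_form = 4, hybrid = 4)
  stopifnot(n_stimuli >= 1, sigma_deg >= 0, offset_sd_mm >= 0,
            pitch_mm > 0, all(tab_size_mm > 0))
  structure(as.list(environment()), class = "synth_tab_spec")
}

fold90 <- function(eps) ((eps + 90) %% 180) - 90

# Place n anchor points: every pairwise distance >= spacing[1] and each
# point's nearest neighbour <= spacing[2] (stimuli sit 10-15 mm apart).
# Greedy sequential placement can dead-end on a tight tab, so the whole
# placement restarts when a point cannot be placed, up to a global budget.
place_anchors <- function(n, bounds, margin, spacing,
                          max_rejections = 10000) {
  lo <- c(margin, margin); hi <- bounds - margin
  if (any(hi <= lo)) {
    abort("tab too small for the placement margin",
          class = "combmetrics_degenerate")
  }
  total <- 0
  repeat {
    xs <- runif(1, lo[1], hi[1]); ys <- runif(1, lo[2], hi[2])
    stuck <- FALSE
    while (length(xs) < n && !stuck) {
      placed <- FALSE
      for (tries in seq_len(250)) {
        px <- runif(1, lo[1], hi[1]); py <- runif(1, lo[2], hi[2])
        d <- sqrt((xs - px)^2 + (ys - py)^2)
        if (min(d) >= spacing[1] && min(d) <= spacing[2]) {
          xs <- c(xs, px); ys <- c(ys, py)
          placed <- TRUE
          break
        }
        total <- total + 1
        if (total > max_rejections) {
          abort("infeasible stimulus spacing on this tab size",
                class = "combmetrics_degenerate")
        }
      }
      if (!placed) stuck <- TRUE
    }
    if (!stuck) return(qtb(x = xs, y = ys))
  }
}

# Distractor walls: edges of a jittered hexagonal tiling at worker-cell
# pitch. The field overhangs the tab edge by `overhang` mm so that gauge
# circles and nearest-wall searches near the boundary see the same wall
# density as the interior (comb does not stop abruptly at a stray mark).
hex_distractors <- function(bounds, pitch, jitter, avoid = NULL,
                            clearance = 0, overhang = 3) {
  rad <- pitch / sqrt(3)
  dy <- pitch * sqrt(3) / 2
  rows <- seq(-overhang - pitch, bounds[2] + overhang + pitch, by = dy)
  cxs0 <- seq(-pitch, bounds[1] + pitch, by = pitch)
  grid <- expand.grid(cx = cxs0, ri = seq_along(rows))
  cx <- grid$cx + ifelse(grid$ri %% 2 == 0, pitch / 2, 0)
  cy <- rows[grid$ri]
  ang <- (30 + 60 * (0:3)) / DEG
  vx <- outer(cx, rad * cos(ang), "+")
  vy <- outer(cy, rad * sin(ang), "+")
  # three edges per hexagon avoids duplicating shared edges
  w <- qtb(x1 = c(vx[, 1:3]), y1 = c(vy[, 1:3]),
              x2 = c(vx[, 2:4]), y2 = c(vy[, 2:4]))
  n <- nrow(w)
  w$x1 <- w$x1 + rnorm(n, 0, jitter)
  w$y1 <- w$y1 + rnorm(n, 0, jitter)
  w$x2 <- w$x2 + rnorm(n, 0, jitter)
  w$y2 <- w$y2 + rnorm(n, 0, jitter)
  ok <- function(x, y) {
    x >= -overhang & x <= bounds[1] + overhang &
      y >= -overhang & y <= bounds[2] + overhang
  }
  w <- w[ok(w$x1, w$y1) & ok(w$x2, w$y2), ]
  if (!is.null(avoid) && clearance > 0 && nrow(avoid) > 0 && nrow(w) > 0) {
    near <- rep(FALSE, nrow(w))
    for (i in seq_len(nrow(avoid))) {
      near <- near | point_segment_distance(avoid$x[i], avoid$y[i],
                                            w$x1, w$y1, w$x2, w$y2) < clearance
    }
    w <- w[!near, ]
  }
  w
}

segment_about <- function(mx, my, dir_deg, length) {
  ux <- cos(dir_deg / DEG); uy <- sin(dir_deg / DEG)
  c(mx - length / 2 * ux, my - length / 2 * uy,
    mx + length / 2 * ux, my + length / 2 * uy)
}

#' Generate one synthetic annotated tab with ground truth
#'
#' Places stimuli, draws one response wall per stimulus according to the
#' bias mode, fills the tab with hexagonal-lattice distractor walls,
#' applies a mild synthetic before/after projective perturbation, and
#' returns both the annotation (stimuli in the before-image pixel frame,
#' walls in the after-image pixel frame, four alignment corner landmarks)
#' and a truth table recording every predicted and realized orientation.
#'
#' @param spec A [synth_tab_spec()].
#' @param tab_id Identifier for the tab.
#' @param seed Optional integer seed, applied locally.
#' @return A list with elements `tab` (a `comb_tab`) and `truth` (a
#'   tibble with one row per stimulus: predicted and realized wall
#'   orientation, the drawn angular error, and for hybrids which guide
#'   was followed).
#' @export
generate_tab <- function(spec, tab_id = "synthetic_tab", seed = NULL) {
  stopifnot(inherits(spec, "synth_tab_spec"))
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  bounds <- spec$tab_size_mm
  anchors <- place_anchors(spec$n_stimuli, bounds, spec$margin_mm,
                           spec$spacing_mm)
  stimuli <- vector("list", spec$n_stimuli)
  walls <- list()
  truth <- vector("list", spec$n_stimuli)
  for (i in seq_len(spec$n_stimuli)) {
    ax <- anchors$x[i]; ay <- anchors$y[i]
    sid <- sprintf("s%02d", i)
    followed <- NA_character_
    if (spec$kind == "pit") {
      stimuli[[i]] <- make_stimulus(sid, "pit",
        qtb(point = "centre", x = ax, y = ay), frame = "world-mm",
        gauge_diameter_mm = spec$gauge_diameter_mm)
      phi <- runif(1, 0, 360)
      r <- spec$gauge_diameter_mm / 2
      contact <- c(ax + r * cos(phi / DEG), ay + r * sin(phi / DEG))
      predicted <- deg_mod180(phi + 90)  # rim tangent at the contact point
      anchor_wall <- contact
    } else if (spec$kind == "pit_pair") {
      ang <- runif(1, 0, 180)
      sep <- runif(1, spec$sep_range_mm[1], spec$sep_range_mm[2])
      ux <- cos(ang / DEG); uy <- sin(ang / DEG)
      stimuli[[i]] <- make_stimulus(sid, "pit_pair",
        qtb(point = c("centre_a", "centre_b"),
            x = c(ax - sep / 2 * ux, ax + sep / 2 * ux),
            y = c(ay - sep / 2 * uy, ay + sep / 2 * uy)),
        frame = "world-mm", gauge_diameter_mm = spec$gauge_diameter_mm)
      predicted <- deg_mod180(ang + 90)  # common tangent
      anchor_wall <- c(ax, ay)
    } else {
      bis <- runif(1, 0, 360)
      splay <- runif(1, spec$splay_range_deg[1], spec$splay_range_deg[2])
      a1 <- (bis - splay / 2) / DEG; a2 <- (bis + splay / 2) / DEG
      vpts <- qtb(point = c("end_a", "apex", "end_b"),
                     x = c(ax + spec$arm_length_mm * cos(a1), ax,
                           ax + spec$arm_length_mm * cos(a2)),
                     y = c(ay + spec$arm_length_mm * sin(a1), ay,
                           ay + spec$arm_length_mm * sin(a2)))
      if (spec$kind == "v_form") {
        stimuli[[i]] <- make_stimulus(sid, "v_form", vpts,
                                      frame = "world-mm")
        predicted <- deg_mod180(bis)
        # wall grows out of the apex along the bisector
        anchor_wall <- c(ax + 0.5 * cos(bis / DEG) +
                           spec$wall_length_mm / 2 * cos(bis / DEG),
                         ay + 0.5 * sin(bis / DEG) +
                           spec$wall_length_mm / 2 * sin(bis / DEG))
      } else { # hybrid: V plus a deliberately misaligned pit pair
        tangent <- deg_mod180(bis + spec$misalign_deg)
        pm <- c(ax + 1.5 * cos(bis / DEG), ay + 1.5 * sin(bis / DEG))
        cdir <- (tangent + 90) / DEG
        sep <- mean(spec$sep_range_mm)
        stimuli[[i]] <- make_stimulus(sid, "hybrid", dplyr::bind_rows(vpts,
          tibble(point = c("centre_a", "centre_b"),
                 x = pm[1] + c(-1, 1) * sep / 2 * cos(cdir),
                 y = pm[2] + c(-1, 1) * sep / 2 * sin(cdir))),
          frame = "world-mm", gauge_diameter_mm = spec$gauge_diameter_mm)
        followed <- if (runif(1) < spec$tangent_mix) "tangent" else "bisection"
        predicted <- if (followed == "tangent") tangent else deg_mod180(bis)
        anchor_wall <- c(ax + 1.0 * cos(bis / DEG),
                         ay + 1.0 * sin(bis / DEG))
      }
    }
    if (spec$bias == "biased") {
      eps <- fold90(rnorm(1, 0, spec$sigma_deg))
      realized <- deg_mod180(predicted + eps)
      mid <- anchor_wall + rnorm(2, 0, spec$offset_sd_mm)
      seg <- segment_about(mid[1], mid[2], realized, spec$wall_length_mm)
    } else {
      eps <- NA_real_
      realized <- runif(1, 0, 180)
      mid <- c(runif(1, 0, bounds[1]), runif(1, 0, bounds[2]))
      seg <- segment_about(mid[1], mid[2], realized, spec$wall_length_mm)
    }
    wid <- paste0("rw_", sid)
    walls[[i]] <- qtb(wall_id = wid, frame = "world-mm",
                      x1 = seg[1], y1 = seg[2], x2 = seg[3], y2 = seg[4])
    truth[[i]] <- qtb(tab_id = tab_id, stimulus_id = sid,
                      kind = spec$kind, predicted_deg = predicted,
                      realized_deg = realized, epsilon_deg = eps,
                      followed = followed, wall_id = wid,
                      anchor_x = ax, anchor_y = ay)
  }
  stimuli <- dplyr::bind_rows(stimuli)
  rwalls <- dplyr::bind_rows(walls)
  # Clearance keeps the response wall nearest for the nearest-wall metrics
  # (pairs, Vs, hybrids). Pit tabs keep the full field: rim overlap is
  # additive, and the response wall sits on top of the ambient comb.
  keep_clear <- spec$bias == "biased" && spec$kind != "pit"
  dwalls <- hex_distractors(bounds, spec$pitch_mm, spec$lattice_jitter_mm,
                            avoid = if (keep_clear) anchors,
                            clearance = spec$clearance_mm)
  if (nrow(dwalls) > 0) {
    dwalls <- qtb(wall_id = sprintf("dw_%03d", seq_len(nrow(dwalls))),
                  frame = rep("world-mm", nrow(dwalls)), x1 = dwalls$x1,
                  y1 = dwalls$y1, x2 = dwalls$x2, y2 = dwalls$y2)
  }
  allwalls <- dplyr::bind_rows(rwalls, dwalls)

  # before/after frames: a mild projective perturbation of the tab corners
  ppm <- spec$pixels_per_mm
  corners <- cbind(x = c(0, bounds[1], bounds[1], 0) * ppm,
                   y = c(0, 0, bounds[2], bounds[2]) * ppm)
  delta <- matrix(runif(8, -spec$warp_px, spec$warp_px), 4, 2)
  h_after_to_before <- estimate_homography(corners, corners + delta)
  stim_before <- dplyr::mutate(stimuli,
    landmarks = purrr::map(.data$landmarks, function(lm) {
      p <- apply_homography(h_after_to_before, lm$x * ppm, lm$y * ppm)
      qtb(point = lm$point, x = p$x, y = p$y)
    }),
    frame = "image-before")
  walls_px <- dplyr::mutate(allwalls, x1 = .data$x1 * ppm,
                            y1 = .data$y1 * ppm, x2 = .data$x2 * ppm,
                            y2 = .data$y2 * ppm, frame = "image-after")
  alignment <- tibble(x_before = corners[, 1] + delta[, 1],
                      y_before = corners[, 2] + delta[, 2],
                      x_after = corners[, 1], y_after = corners[, 2])
  tab <- comb_tab(tab_id = tab_id, pixels_per_mm = ppm,
                  tab_size_mm = bounds, alignment = alignment,
                  stimuli = stim_before, walls = walls_px)
  list(tab = tab, truth = dplyr::bind_rows(truth))
}

#' Simulate a multi-tab study of one experiment
#'
#' Generates enough tabs of the given kind to carry `n_stimuli_total`
#' stimuli (at the per-tab density of the spec), e.g. 63 pit pairs or 79 V
#' forms.
#'
#' @param spec A [synth_tab_spec()].
#' @param n_stimuli_total Total number of stimuli across tabs.
#' @param seed Optional integer seed, applied locally.
#' @return A list with `tabs` (list of `comb_tab`) and `truth` (combined
#'   truth tibble).
#' @export
simulate_study <- function(spec, n_stimuli_total, seed = NULL) {
  stopifnot(inherits(spec, "synth_tab_spec"), n_stimuli_total >= 1)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  per <- spec$n_stimuli
  counts <- rep(per, n_stimuli_total %/% per)
  if (n_stimuli_total %% per > 0) counts <- c(counts, n_stimuli_total %% per)
  tabs <- vector("list", length(counts))
  truths <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    sp <- spec
    sp$n_stimuli <- counts[i]
    g <- generate_tab(sp, tab_id = sprintf("synth_%s_%02d", spec$kind, i))
    tabs[[i]] <- g$tab
    truths[[i]] <- g$truth
  }
  list(tabs = tabs, truth = dplyr::bind_rows(truths))
}

#' Recover the angular-noise parameter from annotated tabs
#'
#' Runs the full pipeline (align, add matched controls, measure) on a set
#' of tabs, estimates the response-wall angular noise sd from the real
#' divergences (for a half-normal angular error, `E[d^2] = sigma^2`, so
#' `sigma_hat = sqrt(mean(d^2))`), and performs the real-versus-control
#' rank-sum test on the divergence metric.
#'
#' @param tabs List of `comb_tab` objects (pit-pair, V-form or hybrid
#'   kinds contribute divergences).
#' @param tol_mm Rim-overlap band half-width passed to [measure_tab()].
#' @param seed Optional integer seed for control generation.
#' @return A list with `sigma_hat_deg`, `comparison` (a
#'   `comb_comparison`, or `NULL` when no controls apply), and the
#'   combined `records` tibble.
#' @export
recover_bias <- function(tabs, tol_mm = 0.35, seed = NULL) {
  stopifnot(length(tabs) >= 1)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  records <- dplyr::bind_rows(lapply(tabs, function(tb) {
    tb |> align_tab() |> add_virtual_controls() |> measure_tab(tol_mm = tol_mm)
  }))
  div <- dplyr::filter(records,
    .data$metric %in% c("tangent_divergence_deg", "bisection_divergence_deg",
                        "hybrid_tangent_divergence_deg"),
    !.data$excluded, is.finite(.data$value))
  real <- div$value[!div$is_control]
  ctrl <- div$value[div$is_control]
  if (length(real) == 0) {
    abort("no divergence measurements found in these tabs",
          class = "combmetrics_precondition")
  }
  sigma_hat <- sqrt(mean(real^2))
  cmp <- if (length(ctrl) >= 1) {
    rank_sum_test(real, ctrl, metric = "divergence_deg")
  }
  list(sigma_hat_deg = sigma_hat, comparison = cmp, records = records)
}
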