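# Per-stimulus measurement: stimuli + walls -> metric records.
#
# Wall selection mirrors the marking procedure: for pit pairs, V forms and
# hybrids the measured wall is the one closest (segment distance) to the
# pair midpoint or V apex; for single pits every wall near the gauge
# circle contributes to the angular overlap.

stim_point <- function(stim_row, name) {
  lm <- stim_row$landmarks[[1]]
  as.numeric(lm[lm$point == name, c("x", "y")])
}

nearest_wall <- function(px, py, walls) {
  d <- point_segment_distance(px, py, walls$x1, walls$y1, walls$x2, walls$y2)
  walls[which.min(d), ]
}

record_row <- function(tab_id, s, metric, value, excluded = FALSE,
                       wall_id = NA_character_, built = NA_real_,
                       predicted = NA_real_) {
  qtb(tab_id = tab_id, stimulus_id = s$stimulus_id, kind = s$kind,
      metric = metric, value = value, is_control = s$is_control,
      excluded = excluded, wall_id = wall_id, built_deg = built,
      predicted_deg = predicted)
}

measure_pit <- function(tab_id, s, walls, tol_mm) {
  cc <- stim_point(s, "centre")
  gauge <- if (is.na(s$gauge_diameter_mm)) 4.0 else s$gauge_diameter_mm
  arcs <- rim_wall_overlap(cc[1], cc[2], walls, gauge_diameter = gauge,
                           tol_mm = tol_mm)
  record_row(tab_id, s, "rim_overlap_deg", arc_total(arcs))
}

measure_pit_pair <- function(tab_id, s, walls) {
  a <- stim_point(s, "centre_a"); b <- stim_point(s, "centre_b")
  predicted <- common_tangent_orientation(a[1], a[2], b[1], b[2])
  if (nrow(walls) == 0) {
    return(record_row(tab_id, s, "tangent_divergence_deg", NA_real_,
                      excluded = TRUE, predicted = predicted))
  }
  w <- nearest_wall((a[1] + b[1]) / 2, (a[2] + b[2]) / 2, walls)
  built <- wall_orientation(w$x1, w$y1, w$x2, w$y2)
  keep <- wall_between_centres(a[1], a[2], b[1], b[2],
                               w$x1, w$y1, w$x2, w$y2)
  record_row(tab_id, s, "tangent_divergence_deg",
             angular_divergence(built, predicted), excluded = !keep,
             wall_id = w$wall_id, built = built, predicted = predicted)
}

measure_v <- function(tab_id, s, walls) {
  ea <- stim_point(s, "end_a"); ap <- stim_point(s, "apex")
  eb <- stim_point(s, "end_b")
  predicted <- bisection_orientation(ea[1], ea[2], ap[1], ap[2],
                                     eb[1], eb[2])
  rows <- list()
  if (nrow(walls) >= 1) {
    w <- nearest_wall(ap[1], ap[2], walls)
    built <- wall_orientation(w$x1, w$y1, w$x2, w$y2)
    rows$div <- record_row(tab_id, s, "bisection_divergence_deg",
                           angular_divergence(built, predicted),
                           wall_id = w$wall_id, built = built,
                           predicted = predicted)
  }
  if (nrow(walls) >= 2) {
    nc <- nearest_wall_corners(ap[1], ap[2], walls)
    rows$prox <- record_row(tab_id, s, "proximity_ratio",
                            proximity_ratio(nc$d1, nc$d2),
                            wall_id = nc$wall_id1)
  }
  dplyr::bind_rows(rows)
}

measure_hybrid <- function(tab_id, s, walls) {
  ea <- stim_point(s, "end_a"); ap <- stim_point(s, "apex")
  eb <- stim_point(s, "end_b")
  a <- stim_point(s, "centre_a"); b <- stim_point(s, "centre_b")
  pred_bis <- bisection_orientation(ea[1], ea[2], ap[1], ap[2],
                                    eb[1], eb[2])
  pred_tan <- common_tangent_orientation(a[1], a[2], b[1], b[2])
  if (nrow(walls) == 0) return(empty_records())
  w <- nearest_wall(ap[1], ap[2], walls)
  built <- wall_orientation(w$x1, w$y1, w$x2, w$y2)
  dplyr::bind_rows(
    record_row(tab_id, s, "hybrid_tangent_divergence_deg",
               angular_divergence(built, pred_tan), wall_id = w$wall_id,
               built = built, predicted = pred_tan),
    record_row(tab_id, s, "hybrid_bisection_divergence_deg",
               angular_divergence(built, pred_bis), wall_id = w$wall_id,
               built = built, predicted = pred_bis))
}

empty_records <- function() {
  tibble(tab_id = character(), stimulus_id = character(), kind = character(),
         metric = character(), value = numeric(), is_control = logical(),
         excluded = logical(), wall_id = character(), built_deg = numeric(),
         predicted_deg = numeric())
}

#' Measure every stimulus on an aligned tab
#'
#' Computes the metric(s) appropriate to each stimulus kind, for real and
#' control stimuli alike: rim angular overlap for pits, divergence from
#' the common tangent (with the between-centres exclusion flag) for pit
#' pairs, divergence from the bisection plus the apex proximity ratio for
#' V forms, and both divergences for hybrids.
#'
#' @param tab An aligned `comb_tab` (see [align_tab()]), optionally with
#'   controls added by [add_virtual_controls()].
#' @param tol_mm Rim-overlap coincidence band half-width in mm
#'   (default 0.35).
#' @return A tibble of measurement records: `tab_id`, `stimulus_id`,
#'   `kind`, `metric`, `value`, `is_control`, `excluded`, `wall_id`,
#'   `built_deg`, `predicted_deg`.
#' @export
measure_tab <- function(tab, tol_mm = 0.35) {
  stopifnot(inherits(tab, "comb_tab"))
  if (nrow(tab$stimuli) == 0) return(empty_records())
  if (any(tab$stimuli$frame != "world-mm") ||
      (nrow(tab$walls) > 0 && any(tab$walls$frame != "world-mm"))) {
    abort("tab must be aligned to world-mm before measuring (align_tab)",
          class = "combmetrics_precondition")
  }
  walls <- tab$walls
  out <- vector("list", nrow(tab$stimuli))
  for (i in seq_len(nrow(tab$stimuli))) {
    s <- tab$stimuli[i, ]
    out[[i]] <- switch(s$kind,
      pit = measure_pit(tab$tab_id, s, walls, tol_mm),
      pit_pair = measure_pit_pair(tab$tab_id, s, walls),
      v_form = measure_v(tab$tab_id, s, walls),
      hybrid = measure_hybrid(tab$tab_id, s, walls))
  }
  dplyr::bind_rows(out)
}
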