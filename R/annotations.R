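# Data model and file I/O for tab annotations.
#
# A "tab" is one 25 x 40 mm wax sheet. Its annotation holds a calibration
# (pixels per mm), four alignment landmark pairs linking the before and
# after photographs, the stimuli marked on the before image, and the wall
# segments marked on the after image. Interactive marking is replaced by
# batch JSON files, one per tab, so analyses are reproducible.
#
# Frames: "image-before" and "image-after" are pixel frames of the two
# photographs; "world-mm" is the calibrated metric frame (after-image
# frame divided by pixels per mm). All geometry is computed in world-mm.

STIMULUS_KINDS <- c("pit", "pit_pair", "v_form", "hybrid")

landmark_names <- function(kind) {
  switch(kind,
    pit      = "centre",
    pit_pair = c("centre_a", "centre_b"),
    v_form   = c("end_a", "apex", "end_b"),
    hybrid   = c("end_a", "apex", "end_b", "centre_a", "centre_b"),
    abort(sprintf("unknown stimulus kind '%s'", kind),
          class = "combmetrics_parse")
  )
}

make_stimulus <- function(stimulus_id, kind, landmarks, frame,
                          gauge_diameter_mm = NA_real_, is_control = FALSE) {
  kind <- match.arg(kind, STIMULUS_KINDS)
  need <- landmark_names(kind)
  if (!all(need %in% landmarks$point)) {
    abort(sprintf("stimulus '%s' (%s) is missing landmark(s): %s",
                  stimulus_id, kind,
                  paste(setdiff(need, landmarks$point), collapse = ", ")),
          class = "combmetrics_parse")
  }
  if (!all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y))) {
    abort(sprintf("stimulus '%s' has non-finite coordinates", stimulus_id),
          class = "combmetrics_parse")
  }
  qtb(stimulus_id = stimulus_id, kind = kind, is_control = is_control,
      frame = frame, gauge_diameter_mm = gauge_diameter_mm,
      landmarks = list(landmarks[match(need, landmarks$point), ]))
}

empty_stimuli <- function() {
  tibble(stimulus_id = character(), kind = character(),
         is_control = logical(), frame = character(),
         gauge_diameter_mm = numeric(), landmarks = list())
}

empty_walls <- function() {
  tibble(wall_id = character(), frame = character(),
         x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric())
}

#' Construct a tab annotation
#'
#' @param tab_id Character identifier of the tab.
#' @param pixels_per_mm Positive calibration of the photographs (the
#'   photographic rig gives about 9 px/mm).
#' @param tab_size_mm Length-2 numeric, tab width and height in mm
#'   (default `c(25, 40)`).
#' @param alignment A data frame of exactly four landmark pairs with
#'   columns `x_before`, `y_before`, `x_after`, `y_after` (pixels), or
#'   `NULL` when only one frame exists.
#' @param stimuli Stimulus tibble as built by the annotation readers or
#'   generators (columns `stimulus_id`, `kind`, `is_control`, `frame`,
#'   `gauge_diameter_mm`, list-column `landmarks`).
#' @param walls Wall tibble with columns `wall_id`, `frame`, `x1`, `y1`,
#'   `x2`, `y2`.
#' @return An object of class `comb_tab`.
#' @export
comb_tab <- function(tab_id, pixels_per_mm, tab_size_mm = c(25, 40),
                     alignment = NULL, stimuli = empty_stimuli(),
                     walls = empty_walls()) {
  if (is.null(pixels_per_mm) || !is.finite(pixels_per_mm) ||
      pixels_per_mm <= 0) {
    abort("calibration missing or invalid: pixels_per_mm must be > 0",
          class = "combmetrics_parse")
  }
  if (!is.null(alignment)) {
    alignment <- as_tibble(alignment)
    if (nrow(alignment) != 4) {
      abort("4 alignment points required", class = "combmetrics_parse")
    }
  }
  stopifnot(length(tab_size_mm) == 2, all(tab_size_mm > 0))
  if (!all(stimuli$kind %in% STIMULUS_KINDS)) {
    abort("unknown stimulus kind in tab", class = "combmetrics_parse")
  }
  structure(list(tab_id = as.character(tab_id),
                 pixels_per_mm = pixels_per_mm,
                 tab_size_mm = as.numeric(tab_size_mm),
                 alignment = alignment,
                 stimuli = as_tibble(stimuli),
                 walls = as_tibble(walls),
                 homography = NULL),
            class = "comb_tab")
}

#' @export
print.comb_tab <- function(x, ...) {
  cat(sprintf("<comb_tab '%s': %g x %g mm, %.3g px/mm>\n", x$tab_id,
              x$tab_size_mm[1], x$tab_size_mm[2], x$pixels_per_mm))
  kinds <- table(x$stimuli$kind)
  cat(sprintf("  stimuli: %d (%s); controls: %d\n", nrow(x$stimuli),
              paste(sprintf("%s=%d", names(kinds), kinds), collapse = ", "),
              sum(x$stimuli$is_control)))
  cat(sprintf("  walls: %d; frames: %s\n", nrow(x$walls),
              paste(unique(c(x$stimuli$frame, x$walls$frame)),
                    collapse = ", ")))
  invisible(x)
}

#' Convert pixel coordinates to calibrated mm
#'
#' Divides coordinates by the pixels-per-mm calibration and retags the
#' frame as `world-mm`. Refuses to convert points already in mm (double
#' conversion).
#'
#' @param points Data frame with columns `x`, `y`, `frame`.
#' @param pixels_per_mm Positive calibration.
#' @return The points tibble in mm with `frame = "world-mm"`.
#' @export
px_to_mm <- function(points, pixels_per_mm) {
  stopifnot(pixels_per_mm > 0)
  points <- as_tibble(points)
  if (any(points$frame == "world-mm")) {
    abort("points are already in world-mm; refusing double conversion",
          class = "combmetrics_precondition")
  }
  dplyr::mutate(points, x = .data$x / pixels_per_mm,
                y = .data$y / pixels_per_mm, frame = "world-mm")
}

#' Convert calibrated mm coordinates back to pixels
#'
#' @inheritParams px_to_mm
#' @param frame Target image frame tag (default `"image-after"`).
#' @return The points tibble in pixels.
#' @export
mm_to_px <- function(points, pixels_per_mm, frame = "image-after") {
  stopifnot(pixels_per_mm > 0)
  points <- as_tibble(points)
  if (any(points$frame != "world-mm")) {
    abort("points are not in world-mm", class = "combmetrics_precondition")
  }
  dplyr::mutate(points, x = .data$x * pixels_per_mm,
                y = .data$y * pixels_per_mm, frame = frame)
}

#' Register a tab into the calibrated after-image frame
#'
#' Estimates the before-to-after homography from the tab's four alignment
#' landmark pairs, maps every before-frame stimulus landmark into the
#' after frame, and converts all coordinates to mm. The after frame is
#' canonical: walls are annotated there and stimuli are mapped forward
#' onto them.
#'
#' @param tab A `comb_tab`.
#' @return The tab with all stimuli and walls in the `world-mm` frame and
#'   the estimated homography stored in `$homography`.
#' @export
align_tab <- function(tab) {
  stopifnot(inherits(tab, "comb_tab"))
  ppm <- tab$pixels_per_mm
  h <- NULL
  if (any(tab$stimuli$frame == "image-before") ||
      any(tab$walls$frame == "image-before")) {
    if (is.null(tab$alignment)) {
      abort("tab has before-frame annotations but no alignment landmarks",
            class = "combmetrics_precondition")
    }
    h <- estimate_homography(
      cbind(x = tab$alignment$x_before, y = tab$alignment$y_before),
      cbind(x = tab$alignment$x_after, y = tab$alignment$y_after))
  }
  map_points <- function(df) {
    if (nrow(df) == 0 || df$frame[1] == "world-mm") return(df)
    if (df$frame[1] == "image-before") {
      mapped <- apply_homography(h, df$x, df$y)
      df$x <- mapped$x; df$y <- mapped$y
    }
    df$x <- df$x / ppm; df$y <- df$y / ppm
    df$frame <- "world-mm"
    df
  }
  tab$stimuli <- dplyr::mutate(tab$stimuli,
    landmarks = purrr::map2(.data$landmarks, .data$frame, function(lm, fr) {
      lm$frame <- fr
      out <- map_points(lm)
      out$frame <- NULL
      out
    }),
    frame = "world-mm")
  if (nrow(tab$walls) > 0) {
    for (fr in setdiff(unique(tab$walls$frame), "world-mm")) {
      sel <- tab$walls$frame == fr
      p <- map_points(tibble(x = c(tab$walls$x1[sel], tab$walls$x2[sel]),
                             y = c(tab$walls$y1[sel], tab$walls$y2[sel]),
                             frame = fr))
      k <- sum(sel)
      tab$walls$x1[sel] <- p$x[1:k]; tab$walls$y1[sel] <- p$y[1:k]
      tab$walls$x2[sel] <- p$x[k + 1:k]; tab$walls$y2[sel] <- p$y[k + 1:k]
      tab$walls$frame[sel] <- "world-mm"
    }
  }
  tab$homography <- h
  tab
}

# ---- JSON annotation files ------------------------------------------------

tab_to_list <- function(tab) {
  list(
    schema = "combmetrics-tab/1",
    tab_id = tab$tab_id,
    pixels_per_mm = tab$pixels_per_mm,
    tab_size_mm = tab$tab_size_mm,
    alignment = if (is.null(tab$alignment)) NULL else
      lapply(seq_len(nrow(tab$alignment)), function(i) list(
        before = c(tab$alignment$x_before[i], tab$alignment$y_before[i]),
        after = c(tab$alignment$x_after[i], tab$alignment$y_after[i]))),
    stimuli = lapply(seq_len(nrow(tab$stimuli)), function(i) {
      s <- tab$stimuli[i, ]
      lm <- s$landmarks[[1]]
      list(stimulus_id = s$stimulus_id, kind = s$kind,
           is_control = s$is_control, frame = s$frame,
           gauge_diameter_mm = if (is.na(s$gauge_diameter_mm)) NULL else
             s$gauge_diameter_mm,
           landmarks = setNames(
             lapply(seq_len(nrow(lm)), function(j) c(lm$x[j], lm$y[j])),
             lm$point))
    }),
    walls = lapply(seq_len(nrow(tab$walls)), function(i) {
      w <- tab$walls[i, ]
      list(wall_id = w$wall_id, frame = w$frame,
           p1 = c(w$x1, w$y1), p2 = c(w$x2, w$y2))
    }))
}

#' Save a tab annotation to a JSON file
#'
#' @param tab A `comb_tab`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_tab <- function(tab, path) {
  stopifnot(inherits(tab, "comb_tab"))
  jsonlite::write_json(tab_to_list(tab), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a tab annotation from a JSON file
#'
#' Reads the documented one-file-per-tab JSON schema, validating the
#' calibration, the four alignment pairs, the per-kind landmark sets and
#' coordinate finiteness. Parse failures name the offending record.
#'
#' @param path Path to a tab annotation JSON file.
#' @param quiet Suppress the summary message (default `FALSE`).
#' @return A `comb_tab`.
#' @export
load_tab <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("annotation file not found: %s", path),
          class = "combmetrics_io")
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$pixels_per_mm)) {
    abort(sprintf("%s: calibration missing (pixels_per_mm)", path),
          class = "combmetrics_parse")
  }
  alignment <- NULL
  if (!is.null(raw$alignment)) {
    if (length(raw$alignment) != 4) {
      abort(sprintf("%s: 4 alignment points required (found %d)",
                    path, length(raw$alignment)),
            class = "combmetrics_parse")
    }
    alignment <- purrr::map_dfr(raw$alignment, function(p) tibble(
      x_before = as.numeric(p$before[[1]]), y_before = as.numeric(p$before[[2]]),
      x_after = as.numeric(p$after[[1]]), y_after = as.numeric(p$after[[2]])))
  }
  stimuli <- empty_stimuli()
  for (i in seq_along(raw$stimuli)) {
    s <- raw$stimuli[[i]]
    if (is.null(s$kind) || is.null(s$landmarks)) {
      abort(sprintf("%s: stimulus %d is missing 'kind' or 'landmarks'",
                    path, i), class = "combmetrics_parse")
    }
    lm <- tibble(point = names(s$landmarks),
                 x = unname(purrr::map_dbl(s$landmarks,
                                           function(q) as.numeric(q[[1]]))),
                 y = unname(purrr::map_dbl(s$landmarks,
                                           function(q) as.numeric(q[[2]]))))
    stimuli <- dplyr::bind_rows(stimuli, make_stimulus(
      stimulus_id = s$stimulus_id %||% sprintf("s%02d", i), kind = s$kind,
      landmarks = lm, frame = s$frame %||% "image-before",
      gauge_diameter_mm = as.numeric(s$gauge_diameter_mm %||% NA_real_),
      is_control = isTRUE(s$is_control)))
  }
  walls <- empty_walls()
  for (i in seq_along(raw$walls)) {
    w <- raw$walls[[i]]
    if (is.null(w$p1) || is.null(w$p2)) {
      abort(sprintf("%s: wall %d is missing endpoint p1/p2", path, i),
            class = "combmetrics_parse")
    }
    walls <- dplyr::bind_rows(walls, tibble(
      wall_id = w$wall_id %||% sprintf("w%03d", i),
      frame = w$frame %||% "image-after",
      x1 = as.numeric(w$p1[[1]]), y1 = as.numeric(w$p1[[2]]),
      x2 = as.numeric(w$p2[[1]]), y2 = as.numeric(w$p2[[2]])))
  }
  tab <- comb_tab(tab_id = raw$tab_id %||% basename(path),
                  pixels_per_mm = as.numeric(raw$pixels_per_mm),
                  tab_size_mm = as.numeric(unlist(raw$tab_size_mm %||%
                                                    list(25, 40))),
                  alignment = alignment, stimuli = stimuli, walls = walls)
  if (!quiet) {
    message(sprintf("loaded tab '%s': %d stimuli, %d walls", tab$tab_id,
                    nrow(stimuli), nrow(walls)))
  }
  tab
}

# ---- measurement record tables --------------------------------------------

RECORD_COLUMNS <- c("tab_id", "stimulus_id", "kind", "metric", "value",
                    "is_control", "excluded", "wall_id", "built_deg",
                    "predicted_deg")

#' Write measurement records to CSV
#'
#' One row per record, stable column order, with a comment header carrying
#' the package version and the seed used for control generation (when
#' known).
#'
#' @param records Non-empty tibble of measurement records (as produced by
#'   [measure_tab()]).
#' @param path Output CSV path.
#' @param seed Optional integer recorded in the header.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, seed = NULL) {
  if (is.null(records) || nrow(records) == 0) {
    abort("refusing to write an empty record table",
          class = "combmetrics_precondition")
  }
  cols <- intersect(RECORD_COLUMNS, names(records))
  records <- records[, c(cols, setdiff(names(records), cols))]
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot open '%s' for writing", path),
          class = "combmetrics_io")
  })
  on.exit(close(con))
  writeLines(sprintf("# combmetrics records v1 (package %s)",
                     as.character(utils::packageVersion("combmetrics"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' Read a measurement record CSV written by [write_records()]
#'
#' @param path Path to the CSV file.
#' @return A tibble of records.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("record file not found: %s", path),
          class = "combmetrics_io")
  }
  as_tibble(utils::read.csv(path, comment.char = "#",
                            stringsAsFactors = FALSE))
}
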