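# End-to-end drivers for the four experiments: align each tab, generate
# matched virtual controls, measure every stimulus, and run the
# experiment's statistical comparison(s).

prepare_records <- function(tabs, seed, tol_mm) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  dplyr::bind_rows(lapply(tabs, function(tb) {
    tb |> align_tab() |> add_virtual_controls() |> measure_tab(tol_mm = tol_mm)
  }))
}

new_experiment <- function(experiment, records, comparisons, seed = NULL,
                           extras = list()) {
  structure(list(experiment = experiment, records = records,
                 comparisons = comparisons, seed = seed, extras = extras),
            class = "comb_experiment")
}

#' @export
print.comb_experiment <- function(x, ...) {
  cat(sprintf("<%s: %d measurement records>\n", x$experiment,
              nrow(x$records)))
  for (cmp in x$comparisons) print(cmp)
  for (nm in names(x$extras)) {
    v <- x$extras[[nm]]
    if (is.numeric(v) && length(v) == 1) cat(sprintf("  %s = %.4g\n", nm, v))
  }
  invisible(x)
}

metric_values <- function(records, metric, control) {
  r <- dplyr::filter(records, .data$metric == !!metric,
                     .data$is_control == control, !.data$excluded,
                     is.finite(.data$value))
  r
}

#' Experiment 1: rim overlap of walls with single pits
#'
#' Measures the angular overlap between each pit's gauge circle and the
#' built walls, for the real pits and for matched virtual pits placed at
#' random within 10 mm of each, and compares the two populations with an
#' unpaired two-tailed t test.
#'
#' @param tabs List of `comb_tab` objects carrying pit stimuli.
#' @param seed Optional integer seed for control generation.
#' @param tol_mm Rim coincidence band half-width (default 0.35 mm).
#' @param variant t-test variant, `"welch"` (default) or `"pooled"`.
#' @return A `comb_experiment` with the record table and the t-test
#'   comparison.
#' @export
run_experiment1 <- function(tabs, seed = NULL, tol_mm = 0.35,
                            variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (!any(vapply(tabs, function(tb) any(tb$stimuli$kind == "pit"),
                  logical(1)))) {
    abort("experiment 1 requires pit stimuli", class = "combmetrics_precondition")
  }
  records <- prepare_records(tabs, seed, tol_mm)
  real <- metric_values(records, "rim_overlap_deg", FALSE)$value
  ctrl <- metric_values(records, "rim_overlap_deg", TRUE)$value
  cmp <- t_test_unpaired(real, ctrl, variant = variant,
                         metric = "rim_overlap_deg", experiment = "exp1")
  new_experiment("experiment 1 (pit rim overlap)", records,
                 list(overlap = cmp), seed)
}

#' Experiment 2: wall divergence from the pit-pair common tangent
#'
#' For each real and virtual pit pair, measures the angular divergence of
#' the nearest wall from the common tangent, excluding records whose wall
#' line does not pass between the pit centres. Compares real and control
#' divergences with a rank-sum test, and reports the Spearman correlation
#' and the through-origin orientation ratio between built and predicted
#' orientations on the real, included records.
#'
#' @inheritParams run_experiment1
#' @return A `comb_experiment`; extras hold exclusion counts, Spearman r
#'   and p, and the orientation ratio.
#' @export
run_experiment2 <- function(tabs, seed = NULL, tol_mm = 0.35) {
  if (!any(vapply(tabs, function(tb) any(tb$stimuli$kind == "pit_pair"),
                  logical(1)))) {
    abort("experiment 2 requires pit-pair stimuli",
          class = "combmetrics_precondition")
  }
  records <- prepare_records(tabs, seed, tol_mm)
  realr <- metric_values(records, "tangent_divergence_deg", FALSE)
  ctrlr <- metric_values(records, "tangent_divergence_deg", TRUE)
  all2 <- dplyr::filter(records, .data$metric == "tangent_divergence_deg")
  cmp <- rank_sum_test(realr$value, ctrlr$value,
                       metric = "tangent_divergence_deg",
                       experiment = "exp2")
  sp <- spearman_correlation(realr$predicted_deg, realr$built_deg)
  ratio <- orientation_ratio(realr$built_deg, realr$predicted_deg)
  new_experiment("experiment 2 (pit-pair tangent divergence)", records,
                 list(divergence = cmp), seed,
                 extras = list(
                   n_excluded_real = sum(all2$excluded & !all2$is_control),
                   n_excluded_control = sum(all2$excluded & all2$is_control),
                   spearman_r = sp$r, spearman_p = sp$p_value,
                   orientation_ratio = ratio))
}

#' Experiment 3: wall divergence from the V bisection and apex proximity
#'
#' Measures, for real and virtual V forms, the divergence of the nearest
#' wall from the V bisection and the apex proximity ratio
#' `P = d1/(d1 + d2)`, comparing each metric's real and control
#' populations with rank-sum tests.
#'
#' @inheritParams run_experiment1
#' @return A `comb_experiment` with `divergence` and `proximity`
#'   comparisons.
#' @export
run_experiment3 <- function(tabs, seed = NULL, tol_mm = 0.35) {
  if (!any(vapply(tabs, function(tb) any(tb$stimuli$kind == "v_form"),
                  logical(1)))) {
    abort("experiment 3 requires V-form stimuli",
          class = "combmetrics_precondition")
  }
  records <- prepare_records(tabs, seed, tol_mm)
  cmp_div <- rank_sum_test(
    metric_values(records, "bisection_divergence_deg", FALSE)$value,
    metric_values(records, "bisection_divergence_deg", TRUE)$value,
    metric = "bisection_divergence_deg", experiment = "exp3")
  cmp_prox <- rank_sum_test(
    metric_values(records, "proximity_ratio", FALSE)$value,
    metric_values(records, "proximity_ratio", TRUE)$value,
    metric = "proximity_ratio", experiment = "exp3")
  new_experiment("experiment 3 (V bisection divergence and proximity)",
                 records, list(divergence = cmp_div, proximity = cmp_prox),
                 seed)
}

#' Experiment 4: hybrid stimuli - tangent versus bisection preference
#'
#' For each hybrid stimulus (a V form with a deliberately misaligned pit
#' pair at its apex) the nearest wall is measured against both guides.
#' Reports the count of walls closer in angle to the pit common tangent
#' than to the V bisection, a paired signed-rank test between the two
#' divergence sets (the same walls measured twice; an unpaired variant is
#' available), and, when experiment 2/3 results are supplied, unpaired
#' cross-experiment comparisons of the hybrid tangent divergences against
#' the experiment-2 real divergences and the hybrid bisection divergences
#' against the experiment-3 real divergences.
#'
#' @inheritParams run_experiment1
#' @param paired Use the paired signed-rank test (default) or an unpaired
#'   rank-sum test between the two divergence sets.
#' @param exp2,exp3 Optional `comb_experiment` results from
#'   [run_experiment2()] / [run_experiment3()] for the cross-experiment
#'   comparisons.
#' @return A `comb_experiment`; extras hold `preference_count` (walls
#'   closer to the tangent), `n_walls`, and `preference_fraction`.
#' @export
run_experiment4 <- function(tabs, seed = NULL, tol_mm = 0.35, paired = TRUE,
                            exp2 = NULL, exp3 = NULL) {
  if (!any(vapply(tabs, function(tb) any(tb$stimuli$kind == "hybrid"),
                  logical(1)))) {
    abort("experiment 4 requires hybrid stimuli",
          class = "combmetrics_precondition")
  }
  records <- prepare_records(tabs, seed, tol_mm)
  wide <- records |>
    dplyr::filter(.data$metric %in% c("hybrid_tangent_divergence_deg",
                                      "hybrid_bisection_divergence_deg"),
                  is.finite(.data$value)) |>
    dplyr::select("tab_id", "stimulus_id", "metric", "value") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "value") |>
    dplyr::filter(is.finite(.data$hybrid_tangent_divergence_deg),
                  is.finite(.data$hybrid_bisection_divergence_deg))
  dt <- wide$hybrid_tangent_divergence_deg
  db <- wide$hybrid_bisection_divergence_deg
  cmp <- rank_sum_test(dt, db, paired = paired,
                       metric = "tangent vs bisection divergence",
                       experiment = "exp4")
  comparisons <- list(tangent_vs_bisection = cmp)
  if (!is.null(exp2)) {
    comparisons$tangent_vs_exp2 <- rank_sum_test(
      dt, metric_values(exp2$records, "tangent_divergence_deg", FALSE)$value,
      metric = "hybrid tangent divergence vs experiment 2",
      experiment = "exp4")
  }
  if (!is.null(exp3)) {
    comparisons$bisection_vs_exp3 <- rank_sum_test(
      db, metric_values(exp3$records, "bisection_divergence_deg", FALSE)$value,
      metric = "hybrid bisection divergence vs experiment 3",
      experiment = "exp4")
  }
  new_experiment("experiment 4 (hybrid preference)", records, comparisons,
                 seed, extras = list(preference_count = sum(dt < db),
                                     n_walls = length(dt),
                                     preference_fraction = mean(dt < db)))
}
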