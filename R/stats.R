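# Real-versus-control statistical comparisons.
#
# The comparisons wrap the standard R tests (t.test, wilcox.test,
# cor.test) and package their output, together with group summaries, into
# a `comb_comparison` object with broom-style tidy()/glance() methods.
# Conventions worth noting: the rank-sum statistic is R's W, the
# Mann-Whitney U of the first sample (so W = 0 when every first-group
# value precedes every second-group value); the exact distribution is used
# for small untied samples, a tie-corrected normal approximation
# otherwise.

new_comparison <- function(method, statistic, p_value, x, y,
                           variant = NA_character_, metric = NA_character_,
                           experiment = NA_character_, extras = list()) {
  structure(list(method = method, variant = variant, metric = metric,
                 experiment = experiment,
                 statistic = unname(statistic), p_value = unname(p_value),
                 n_real = length(x), n_control = length(y),
                 mean_real = mean(x), sd_real = sd(x),
                 mean_control = if (length(y)) mean(y) else NA_real_,
                 sd_control = if (length(y)) sd(y) else NA_real_,
                 extras = extras),
            class = "comb_comparison")
}

#' @export
print.comb_comparison <- function(x, ...) {
  cat(sprintf("<%s%s%s>\n", x$method,
              if (!is.na(x$variant)) paste0(" [", x$variant, "]") else "",
              if (!is.na(x$metric)) paste0(" on ", x$metric) else ""))
  cat(sprintf("  real:    n = %d, %.3f +/- %.3f\n", x$n_real, x$mean_real,
              x$sd_real))
  if (!is.na(x$mean_control)) {
    cat(sprintf("  control: n = %d, %.3f +/- %.3f\n", x$n_control,
                x$mean_control, x$sd_control))
  }
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  for (nm in names(x$extras)) {
    cat(sprintf("  %s = %.4g\n", nm, x$extras[[nm]]))
  }
  invisible(x)
}

#' Unpaired two-tailed t test between real and control values
#'
#' @param x,y Numeric vectors (real and control measurements), each with
#'   at least two values.
#' @param variant `"welch"` (default; unequal variances) or `"pooled"`
#'   (classical Student).
#' @param metric,experiment Optional labels carried into the result.
#' @return A `comb_comparison`.
#' @export
t_test_unpaired <- function(x, y, variant = c("welch", "pooled"),
                            metric = NA_character_,
                            experiment = NA_character_) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least two values",
          class = "combmetrics_precondition")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    abort("zero variance in both groups; t test undefined",
          class = "combmetrics_degenerate")
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "pooled"),
                      alternative = "two.sided")
  new_comparison("t test (unpaired, two-tailed)", tt$statistic, tt$p.value,
                 x, y, variant = variant, metric = metric,
                 experiment = experiment,
                 extras = list(df = unname(tt$parameter)))
}

#' Rank-sum (Mann-Whitney / Wilcoxon) test
#'
#' Two-sided unpaired rank-sum test by default; set `paired = TRUE` for
#' the signed-rank test on matched values (used when the same walls are
#' measured against two guides). Exact p-values are used for small
#' untied samples, the tie-corrected normal approximation otherwise.
#'
#' @inheritParams t_test_unpaired
#' @param paired Use the paired signed-rank variant.
#' @return A `comb_comparison`.
#' @export
rank_sum_test <- function(x, y, paired = FALSE, metric = NA_character_,
                          experiment = NA_character_) {
  if (length(x) < 1 || length(y) < 1) {
    abort("both groups must be non-empty", class = "combmetrics_precondition")
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                            alternative = "two.sided"))
  new_comparison(if (paired) "Wilcoxon signed-rank test (paired)"
                 else "Wilcoxon rank-sum test (unpaired)",
                 wt$statistic, wt$p.value, x, y,
                 metric = metric, experiment = experiment)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, plus its p-value
#' (asymptotic t approximation, matching `cor.test(exact = FALSE)`).
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return A list with `r`, `p_value`, and `n`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need paired vectors with n >= 3", class = "combmetrics_precondition")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant input: ranks undefined", class = "combmetrics_degenerate")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Ratio of built-wall to predicted orientations
#'
#' Through-origin least-squares slope of built orientation against
#' predicted orientation. Because orientations are 180-degree periodic,
#' each built value is first unwrapped to the representative (built plus a
#' multiple of 180) closest to its predicted partner, so that e.g. a 1 or
#' 179 degree pair does not register as a gross disagreement.
#'
#' @param built,predicted Paired orientations in degrees in `[0, 180)`.
#' @return The slope (a ratio near 1 indicates walls track the predicted
#'   orientation one-to-one).
#' @export
orientation_ratio <- function(built, predicted) {
  if (length(built) != length(predicted) || length(built) == 0) {
    abort("need paired orientation vectors", class = "combmetrics_precondition")
  }
  if (all(predicted == 0)) {
    abort("all predicted orientations are zero; slope undefined",
          class = "combmetrics_degenerate")
  }
  cand <- outer(built, c(-180, 0, 180), "+")
  pick <- apply(abs(cand - predicted), 1, which.min)
  b <- cand[cbind(seq_along(built), pick)]
  sum(b * predicted) / sum(predicted^2)
}
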