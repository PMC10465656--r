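# broom-style tidiers for comparison and experiment objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a real-versus-control comparison
#'
#' @param x A `comb_comparison`.
#' @param ... Unused.
#' @return A tibble with one row per group (`real`, `control`) holding
#'   `n`, `mean`, and `sd`.
#' @method tidy comb_comparison
#' @export
tidy.comb_comparison <- function(x, ...) {
  tibble(group = c("real", "control"),
         n = c(x$n_real, x$n_control),
         mean = c(x$mean_real, x$mean_control),
         sd = c(x$sd_real, x$sd_control))
}

#' One-row summary of a comparison
#'
#' @param x A `comb_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with the test name, statistic, p-value, group
#'   sizes and any auxiliary quantities (Spearman r, orientation ratio,
#'   degrees of freedom).
#' @method glance comb_comparison
#' @export
glance.comb_comparison <- function(x, ...) {
  out <- tibble(method = x$method, variant = x$variant, metric = x$metric,
                statistic = x$statistic, p_value = x$p_value,
                n_real = x$n_real, n_control = x$n_control,
                mean_real = x$mean_real, sd_real = x$sd_real,
                mean_control = x$mean_control, sd_control = x$sd_control)
  for (nm in names(x$extras)) out[[nm]] <- x$extras[[nm]]
  out
}

#' Tidy an experiment result
#'
#' @param x A `comb_experiment`.
#' @param ... Unused.
#' @return A tibble with one row per comparison in the experiment.
#' @method tidy comb_experiment
#' @export
tidy.comb_experiment <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$comparisons), function(nm) {
    dplyr::bind_cols(tibble(comparison = nm),
                     glance(x$comparisons[[nm]]))
  }))
}

#' One-row summary of an experiment
#'
#' @param x A `comb_experiment`.
#' @param ... Unused.
#' @return A one-row tibble: experiment label, record count, one
#'   `p_<comparison>` column per comparison, and scalar extras
#'   (exclusion counts, Spearman r, preference counts, ...).
#' @method glance comb_experiment
#' @export
glance.comb_experiment <- function(x, ...) {
  out <- tibble(experiment = x$experiment, n_records = nrow(x$records))
  for (nm in names(x$comparisons)) {
    out[[paste0("p_", nm)]] <- x$comparisons[[nm]]$p_value
  }
  for (nm in names(x$extras)) {
    v <- x$extras[[nm]]
    if (is.numeric(v) && length(v) == 1) out[[nm]] <- v
  }
  out
}
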