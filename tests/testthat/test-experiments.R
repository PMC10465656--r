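test_that("experiment 1 separates rim-following walls from chance", {
  set.seed(429)
  s <- simulate_study(synth_tab_spec("pit", sigma_deg = 0,
                                     offset_sd_mm = 0), 24)
  e1 <- run_experiment1(s$tabs, seed = 31)
  cmp <- e1$comparisons$overlap
  expect_gt(cmp$mean_real, cmp$mean_control)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$n_real, 24)
  expect_equal(cmp$n_control, 24)
  expect_error(run_experiment1(simulate_study(
    synth_tab_spec("v_form"), 4)$tabs), class = "combmetrics_precondition")
})

test_that("an empty wall field surfaces the degenerate t test cleanly", {
  set.seed(430)
  g <- generate_tab(synth_tab_spec("pit", n_stimuli = 4))
  g$tab$walls <- g$tab$walls[0, ]
  expect_error(run_experiment1(list(g$tab), seed = 1),
               class = "combmetrics_degenerate")
})

test_that("experiment 2 recovers noiseless tangents perfectly", {
  set.seed(431)
  s <- simulate_study(synth_tab_spec("pit_pair", sigma_deg = 0,
                                     offset_sd_mm = 0), 18)
  e2 <- run_experiment2(s$tabs, seed = 32)
  cmp <- e2$comparisons$divergence
  expect_lt(cmp$mean_real, 1e-6)
  expect_equal(e2$extras$spearman_r, 1, tolerance = 1e-9)
  expect_equal(e2$extras$orientation_ratio, 1, tolerance = 1e-9)
  expect_lt(cmp$p_value, 1e-6)
})

test_that("the between-centres exclusion removes planted offset walls", {
  set.seed(432)
  g <- generate_tab(synth_tab_spec("pit_pair", sigma_deg = 0,
                                   offset_sd_mm = 0, n_stimuli = 4))
  tab <- align_tab(g$tab)
  # slide two response walls along their own axis until their line no
  # longer crosses between the centres (the excluded configuration)
  planted <- c("rw_s01", "rw_s03")
  for (wid in planted) {
    i <- which(tab$walls$wall_id == wid)
    tr <- g$truth[g$truth$wall_id == wid, ]
    # response wall is parallel to the tangent; shift it along the
    # centre-centre direction by a full separation so it sits beyond a pit
    shift_dir <- (tr$predicted_deg + 90) / 180 * pi
    dx <- 7 * cos(shift_dir); dy <- 7 * sin(shift_dir)
    tab$walls$x1[i] <- tab$walls$x1[i] + dx
    tab$walls$x2[i] <- tab$walls$x2[i] + dx
    tab$walls$y1[i] <- tab$walls$y1[i] + dy
    tab$walls$y2[i] <- tab$walls$y2[i] + dy
  }
  m <- measure_tab(tab)
  real <- dplyr::filter(m, !is_control, metric == "tangent_divergence_deg")
  expect_equal(sum(real$excluded), length(planted))
  expect_setequal(real$stimulus_id[real$excluded], c("s01", "s03"))
})

test_that("experiment 3 finds apex walls near and aligned", {
  set.seed(433)
  s <- simulate_study(synth_tab_spec("v_form", sigma_deg = 0,
                                     offset_sd_mm = 0), 16)
  e3 <- run_experiment3(s$tabs, seed = 33)
  expect_lt(e3$comparisons$divergence$mean_real, 1e-6)
  # planted apex walls give small P; random virtual Vs sit farther out
  expect_lt(e3$comparisons$proximity$mean_real,
            e3$comparisons$proximity$mean_control)
  expect_lt(e3$comparisons$proximity$p_value, 0.01)
  expect_true(all(dplyr::filter(e3$records,
                                metric == "proximity_ratio")$value <= 0.5))
})

test_that("experiment 4 preference follows the generator mixture", {
  set.seed(434)
  pure_t <- simulate_study(synth_tab_spec("hybrid", tangent_mix = 1), 16)
  e4t <- run_experiment4(pure_t$tabs, seed = 34)
  expect_equal(e4t$extras$preference_count, 16)
  pure_b <- simulate_study(synth_tab_spec("hybrid", tangent_mix = 0), 16)
  e4b <- run_experiment4(pure_b$tabs, seed = 35)
  expect_equal(e4b$extras$preference_count, 0)
  # cross-experiment comparisons accept experiment 2/3 results
  s2 <- simulate_study(synth_tab_spec("pit_pair"), 12)
  s3 <- simulate_study(synth_tab_spec("v_form"), 8)
  e2 <- run_experiment2(s2$tabs, seed = 36)
  e3 <- run_experiment3(s3$tabs, seed = 37)
  e4 <- run_experiment4(pure_t$tabs, seed = 38, exp2 = e2, exp3 = e3)
  expect_named(e4$comparisons,
               c("tangent_vs_bisection", "tangent_vs_exp2",
                 "bisection_vs_exp3"))
})

test_that("experiments are reproducible from their seeds", {
  set.seed(435)
  s <- simulate_study(synth_tab_spec("pit_pair"), 12, seed = 77)
  a <- run_experiment2(s$tabs, seed = 55)
  b <- run_experiment2(s$tabs, seed = 55)
  expect_identical(glance(a), glance(b))
  expect_identical(a$records, b$records)
})

test_that("tidy and glance expose the comparison tables", {
  set.seed(436)
  s <- simulate_study(synth_tab_spec("v_form"), 8)
  e3 <- run_experiment3(s$tabs, seed = 39)
  td <- tidy(e3)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$comparison, c("divergence", "proximity"))
  gl <- glance(e3)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("p_divergence", "p_proximity") %in% names(gl)))
  cmp_td <- tidy(e3$comparisons$divergence)
  expect_equal(cmp_td$group, c("real", "control"))
  # autoplot builds without evaluation errors
  pl <- ggplot2::ggplot_build(autoplot(e3))
  expect_s3_class(pl$plot, "ggplot")
  pt <- ggplot2::ggplot_build(autoplot(s$tabs[[1]]))
  expect_s3_class(pt$plot, "ggplot")
})
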