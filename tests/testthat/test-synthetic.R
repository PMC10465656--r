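test_that("generated tabs satisfy the annotation contracts", {
  set.seed(421)
  for (kind in c("pit", "pit_pair", "v_form", "hybrid")) {
    g <- generate_tab(synth_tab_spec(kind))
    expect_s3_class(g$tab, "comb_tab")
    expect_equal(nrow(g$tab$alignment), 4)
    expect_true(all(g$tab$stimuli$frame == "image-before"))
    expect_true(all(g$tab$walls$frame == "image-after"))
    expect_equal(nrow(g$truth), nrow(g$tab$stimuli))
    # stimulus spacing respects the 10-15 mm placement rule
    if (nrow(g$truth) > 1) {
      d <- as.matrix(stats::dist(cbind(g$truth$anchor_x, g$truth$anchor_y)))
      diag(d) <- Inf
      expect_true(all(d[d < Inf] >= 10 - 1e-9))
      expect_true(all(apply(d, 1, min) <= 15 + 1e-9))
    }
    # save/load round trip of generated annotations
    f <- withr::local_tempfile(fileext = ".json")
    save_tab(g$tab, f)
    tab2 <- load_tab(f, quiet = TRUE)
    expect_equal(tab2$walls$x1, g$tab$walls$x1, tolerance = 1e-9)
    expect_equal(tab2$stimuli$landmarks[[1]], g$tab$stimuli$landmarks[[1]],
                 tolerance = 1e-9)
  }
})

test_that("identical seeds reproduce identical tabs", {
  sp <- synth_tab_spec("pit_pair")
  g1 <- generate_tab(sp, seed = 1234)
  g2 <- generate_tab(sp, seed = 1234)
  expect_identical(g1$tab$walls, g2$tab$walls)
  expect_identical(g1$truth, g2$truth)
})

test_that("noiseless pit pairs are recovered with zero divergence", {
  set.seed(422)
  sp <- synth_tab_spec("pit_pair", sigma_deg = 0, offset_sd_mm = 0)
  g <- generate_tab(sp)
  m <- g$tab |> align_tab() |> measure_tab()
  real <- dplyr::filter(m, !is_control, metric == "tangent_divergence_deg")
  expect_equal(nrow(real), sp$n_stimuli)
  expect_true(all(real$value < 1e-6))
  expect_true(all(!real$excluded))
})

test_that("divergences follow the folded-normal mean at sigma = 5", {
  set.seed(423)
  sp <- synth_tab_spec("pit_pair", sigma_deg = 5)
  vals <- unlist(lapply(1:12, function(i) {
    g <- generate_tab(sp)
    m <- align_tab(g$tab) |> measure_tab()
    dplyr::filter(m, !is_control, metric == "tangent_divergence_deg")$value
  }))
  # E|N(0, sigma)| = sigma * sqrt(2/pi) ~ 3.99 for sigma = 5
  expect_equal(mean(vals), 5 * sqrt(2 / pi), tolerance = 3 / 4)
})

test_that("bias-mode angular errors converge to the folded normal", {
  set.seed(424)
  sp <- synth_tab_spec("v_form", sigma_deg = 8)
  eps <- unlist(lapply(1:40, function(i) generate_tab(sp)$truth$epsilon_deg))
  expect_gt(stats::ks.test(eps, function(q) stats::pnorm(q, 0, 8))$p.value,
            0.01)
})

test_that("measured divergence is non-decreasing in sigma", {
  set.seed(425)
  means <- vapply(c(0, 5, 15, 45), function(sg) {
    sp <- synth_tab_spec("pit_pair", sigma_deg = sg)
    mean(unlist(lapply(1:10, function(i) {
      m <- align_tab(generate_tab(sp)$tab) |> measure_tab()
      dplyr::filter(m, !is_control, metric == "tangent_divergence_deg")$value
    })))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the stored before/after warp is recovered by the alignment stage", {
  set.seed(426)
  g <- generate_tab(synth_tab_spec("pit"))
  al <- align_tab(g$tab)
  # mapping the before-frame alignment landmarks must land on the after ones
  mapped <- apply_homography(al$homography, g$tab$alignment$x_before,
                             g$tab$alignment$y_before)
  expect_lt(max(abs(mapped$x - g$tab$alignment$x_after),
                abs(mapped$y - g$tab$alignment$y_after)), 1e-6)
  # measured stimuli land on their true anchors (exact 4-point recovery)
  pit1 <- al$stimuli$landmarks[[1]]
  expect_equal(pit1$x, g$truth$anchor_x[1], tolerance = 1e-6)
  expect_equal(pit1$y, g$truth$anchor_y[1], tolerance = 1e-6)
})

test_that("rendering produces calibrated image pairs and clips politely", {
  set.seed(427)
  g <- generate_tab(synth_tab_spec("pit"))
  imgs <- suppressWarnings(render_tab(g$tab))
  expect_equal(dim(imgs$after), c(40 * 9, 25 * 9))   # 360 x 225 px
  expect_equal(dim(imgs$before), c(360, 225))
  expect_true(all(imgs$after >= 0 & imgs$after <= 1))
  # walls brighten the after image relative to background
  expect_gt(max(imgs$after), max(imgs$before))
  # a blank tab renders as a uniform background
  blank <- comb_tab("blank", 9, c(25, 40))
  bi <- render_tab(blank)
  expect_equal(length(unique(c(bi$before, bi$after))), 1)
})

test_that("recover_bias estimates sigma and flags the bias", {
  set.seed(428)
  s0 <- simulate_study(synth_tab_spec("pit_pair", sigma_deg = 0,
                                      offset_sd_mm = 0), 18)
  rb0 <- recover_bias(s0$tabs, seed = 5)
  expect_lt(rb0$sigma_hat_deg, 1)
  expect_lt(rb0$comparison$p_value, 0.01)
})
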