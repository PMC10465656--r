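test_that("pixel/mm conversion scales, tags frames and refuses double conversion", {
  cal <- 9
  p <- tibble::tibble(x = c(9, 0), y = c(18, 0), frame = "image-after")
  mm <- px_to_mm(p, cal)
  expect_equal(mm$x, c(1, 0))
  expect_equal(mm$y, c(2, 0))
  expect_true(all(mm$frame == "world-mm"))
  expect_error(px_to_mm(mm, cal), class = "combmetrics_precondition")
  back <- mm_to_px(mm, cal)
  expect_equal(back$x, p$x, tolerance = 1e-9)
  expect_equal(back$y, p$y, tolerance = 1e-9)
})

test_that("tab save/load round-trips losslessly", {
  tab <- tiny_tab()
  f <- withr::local_tempfile(fileext = ".json")
  expect_message(save_tab(tab, f), NA)
  tab2 <- load_tab(f, quiet = TRUE)
  expect_equal(tab2$tab_id, tab$tab_id)
  expect_equal(tab2$pixels_per_mm, tab$pixels_per_mm)
  expect_equal(nrow(tab2$stimuli), 2)
  expect_equal(nrow(tab2$walls), 2)
  expect_equal(tab2$alignment, tab$alignment, tolerance = 1e-9)
  expect_equal(tab2$stimuli$landmarks[[1]], tab$stimuli$landmarks[[1]],
               tolerance = 1e-9)
  expect_equal(tab2$walls$x2, tab$walls$x2, tolerance = 1e-9)
  # frame tags survive the round trip
  expect_true(all(tab2$stimuli$frame == "image-before"))
  expect_true(all(tab2$walls$frame == "image-after"))
})

test_that("malformed annotation files fail with informative errors", {
  tab <- tiny_tab()
  f <- withr::local_tempfile(fileext = ".json")
  save_tab(tab, f)
  raw <- jsonlite::read_json(f)
  # three alignment pairs: the four-point requirement is enforced
  raw3 <- raw; raw3$alignment <- raw3$alignment[1:3]
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw3, f3, auto_unbox = TRUE, null = "null")
  expect_error(load_tab(f3, quiet = TRUE), "4 alignment points required")
  # missing calibration
  rawc <- raw; rawc$pixels_per_mm <- NULL
  fc <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(rawc, fc, auto_unbox = TRUE, null = "null")
  expect_error(load_tab(fc, quiet = TRUE), "calibration")
  # stimulus with a missing landmark names the record
  rawl <- raw; rawl$stimuli[[2]]$landmarks$centre_b <- NULL
  fl <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(rawl, fl, auto_unbox = TRUE, null = "null")
  expect_error(load_tab(fl, quiet = TRUE), "centre_b")
  expect_error(load_tab("no/such/file.json"), class = "combmetrics_io")
})

test_that("alignment maps stimuli into the after frame in mm", {
  tab <- tiny_tab(ppm = 10)
  al <- align_tab(tab)
  expect_true(all(al$stimuli$frame == "world-mm"))
  expect_true(all(al$walls$frame == "world-mm"))
  # identity alignment: stimuli coordinates are just divided by ppm
  expect_equal(al$stimuli$landmarks[[1]]$x, 5)
  expect_equal(al$stimuli$landmarks[[1]]$y, 6)
  expect_equal(al$walls$x1, c(4, 12))
  # aligning twice is a no-op
  expect_equal(align_tab(al)$stimuli, al$stimuli)
})

test_that("record tables round-trip through CSV with a metadata header", {
  recs <- tibble::tibble(tab_id = "t", stimulus_id = c("a", "b", "c"),
                         kind = "pit", metric = "rim_overlap_deg",
                         value = c(10.123456789, 0, 359.5),
                         is_control = c(FALSE, TRUE, FALSE),
                         excluded = FALSE, wall_id = NA_character_,
                         built_deg = NA_real_, predicted_deg = NA_real_)
  f <- withr::local_tempfile(fileext = ".csv")
  write_records(recs, f, seed = 17)
  lines <- readLines(f)
  expect_match(lines[1], "^# combmetrics records")
  expect_match(lines[2], "^# seed: 17$")
  back <- read_records(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$value, recs$value, tolerance = 1e-9)
  expect_error(write_records(recs[0, ], f),
               class = "combmetrics_precondition")
})
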