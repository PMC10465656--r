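test_that("wall orientation follows the clockwise-from-horizontal convention", {
  expect_equal(wall_orientation(0, 0, 1, 0), 0)
  expect_equal(wall_orientation(0, 0, 0, 1), 90)
  # undirected: a segment and its reverse share an orientation
  expect_equal(wall_orientation(0, 0, -1, 1), wall_orientation(0, 0, 1, -1))
  expect_error(wall_orientation(2, 3, 2, 3), class = "combmetrics_degenerate")
})

test_that("angular divergence is symmetric, bounded and wrap-aware", {
  expect_equal(angular_divergence(10, 10), 0)
  expect_equal(angular_divergence(0, 90), 90)
  expect_equal(angular_divergence(10, 170), 20)
  set.seed(401)
  a <- runif(200, -720, 720); b <- runif(200, -720, 720)
  expect_equal(angular_divergence(a, b), angular_divergence(b, a))
  expect_equal(angular_divergence(a + 180, b), angular_divergence(a, b))
  expect_true(all(angular_divergence(a, b) >= 0 &
                    angular_divergence(a, b) <= 90))
})

test_that("common tangent is perpendicular to the centre line", {
  expect_equal(common_tangent_orientation(0, 0, 2, 0), 90)
  expect_equal(common_tangent_orientation(0, 0, 0, 2), 0)
  set.seed(402)
  for (i in 1:50) {
    a <- runif(2, -10, 10); b <- runif(2, -10, 10)
    if (all(a == b)) next
    tang <- common_tangent_orientation(a[1], a[2], b[1], b[2])
    u <- c(cos(tang * pi / 180), sin(tang * pi / 180))
    v <- b - a
    expect_lt(abs(sum(u * v / sqrt(sum(v^2)))), 1e-9)
  }
  expect_error(common_tangent_orientation(1, 1, 1, 1),
               class = "combmetrics_degenerate")
})

test_that("V bisector is equi-angular to both arms", {
  expect_equal(bisection_orientation(1, 0, 0, 0, 0, 1), 45)
  # symmetric V about the vertical axis has a vertical bisector
  expect_equal(bisection_orientation(-1, 1, 0, 0, 1, 1), 90)
  set.seed(403)
  for (i in 1:50) {
    ap <- runif(2, -5, 5)
    a1 <- runif(1, 0, 2 * pi)
    splay <- runif(1, 10, 170) * pi / 180
    ea <- ap + runif(1, 1, 4) * c(cos(a1), sin(a1))
    eb <- ap + runif(1, 1, 4) * c(cos(a1 + splay), sin(a1 + splay))
    bis <- bisection_orientation(ea[1], ea[2], ap[1], ap[2], eb[1], eb[2])
    da <- angular_divergence(bis, wall_orientation(ap[1], ap[2], ea[1], ea[2]))
    db <- angular_divergence(bis, wall_orientation(ap[1], ap[2], eb[1], eb[2]))
    expect_lt(abs(da - db), 1e-9)
  }
  expect_error(bisection_orientation(1, 0, 0, 0, -1, 0),
               class = "combmetrics_degenerate")
})

test_that("splay angle matches the law of cosines and rejects degenerate Vs", {
  expect_equal(splay_angle(1, 0, 0, 0, 0, 1), 90)
  expect_error(splay_angle(1, 0, 0, 0, 2, 0),
               class = "combmetrics_degenerate")  # zero splay
  expect_error(splay_angle(1, 0, 0, 0, -1, 0),
               class = "combmetrics_degenerate")  # straight arms
  set.seed(404)
  for (i in 1:50) {
    ap <- runif(2, -5, 5); ea <- runif(2, -5, 5); eb <- runif(2, -5, 5)
    la <- sqrt(sum((ea - ap)^2)); lb <- sqrt(sum((eb - ap)^2))
    lc <- sqrt(sum((ea - eb)^2))
    expected <- acos((la^2 + lb^2 - lc^2) / (2 * la * lb)) * 180 / pi
    if (expected <= 1e-6 || expected >= 180 - 1e-6) next
    expect_equal(splay_angle(ea[1], ea[2], ap[1], ap[2], eb[1], eb[2]),
                 expected, tolerance = 1e-9)
  }
})

test_that("between-centres exclusion agrees with a parametric oracle", {
  expect_true(wall_between_centres(0, 0, 6, 0, 3, -5, 3, 5))
  expect_false(wall_between_centres(0, 0, 6, 0, 8, -5, 8, 5))
  # parallel offset wall never separates the centres
  expect_false(wall_between_centres(0, 0, 6, 0, 0, 2, 6, 2))
  set.seed(405)
  for (i in 1:1000) {
    ca <- runif(2, -5, 5); cb <- runif(2, -5, 5)
    w1 <- runif(2, -5, 5); w2 <- runif(2, -5, 5)
    if (all(ca == cb) || all(w1 == w2)) next
    # oracle: solve ca + t (cb - ca) on the infinite wall line, 0 < t < 1
    A <- cbind(cb - ca, -(w2 - w1))
    ans <- if (abs(det(A)) < 1e-12) FALSE else {
      t <- solve(A, w1 - ca)[1]
      t > 0 && t < 1
    }
    expect_identical(
      wall_between_centres(ca[1], ca[2], cb[1], cb[2],
                           w1[1], w1[2], w2[1], w2[2]), ans)
  }
})

test_that("nearest corners match an exhaustive scan and break ties stably", {
  walls <- tibble::tibble(wall_id = c("a", "b"),
                          x1 = c(1, 3), y1 = c(0, 0),
                          x2 = c(10, 10), y2 = c(10, -10))
  nc <- nearest_wall_corners(0, 0, walls)
  expect_equal(nc$d1, 1)
  expect_equal(nc$d2, 3)
  # tie: equidistant corners resolved by annotation order
  tie <- tibble::tibble(wall_id = c("first", "second"),
                        x1 = c(2, -2), y1 = c(0, 0),
                        x2 = c(9, -9), y2 = c(0, 0))
  expect_identical(nearest_wall_corners(0, 0, tie)$wall_id1, "first")
  expect_error(nearest_wall_corners(0, 0, walls[1, ]),
               class = "combmetrics_precondition")
  set.seed(406)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    w <- tibble::tibble(wall_id = as.character(seq_len(n)),
                        x1 = runif(n, -5, 5), y1 = runif(n, -5, 5),
                        x2 = runif(n, -5, 5), y2 = runif(n, -5, 5))
    p <- runif(2, -5, 5)
    corner <- pmin(sqrt((w$x1 - p[1])^2 + (w$y1 - p[2])^2),
                   sqrt((w$x2 - p[1])^2 + (w$y2 - p[2])^2))
    nc <- nearest_wall_corners(p[1], p[2], w)
    expect_equal(nc$d1, sort(corner)[1])
    expect_equal(nc$d2, sort(corner)[2])
  }
})

test_that("proximity ratio follows P = d1/(d1+d2) on (0, 0.5]", {
  expect_equal(proximity_ratio(2, 2), 0.5)
  expect_equal(proximity_ratio(1, 3), 0.25)
  expect_error(proximity_ratio(3, 1), class = "combmetrics_precondition")
  expect_warning(p0 <- proximity_ratio(0, 2), "apex")
  expect_equal(p0, 0)
  # strictly increasing in d1 at fixed total
  d1 <- seq(0.1, 1, by = 0.1)
  p <- proximity_ratio(d1, 2 - d1)
  expect_true(all(diff(p) > 0))
})

test_that("all metrics are invariant under rigid motions", {
  set.seed(407)
  walls0 <- tibble::tibble(wall_id = c("a", "b", "c"),
                           x1 = c(-3, 1, 4), y1 = c(0.5, -2, 3),
                           x2 = c(3, 2, 6), y2 = c(1, 4, 3))
  for (i in 1:20) {
    mv <- rigid_motion()
    ca <- c(-1, 0); cb <- c(4, 1); ap <- c(0.5, 0.5)
    ea <- c(3, 2); eb <- c(-2, 3)
    w <- walls0
    m1 <- mv(w$x1, w$y1); m2 <- mv(w$x2, w$y2)
    w$x1 <- m1$x; w$y1 <- m1$y; w$x2 <- m2$x; w$y2 <- m2$y
    mca <- mv(ca[1], ca[2]); mcb <- mv(cb[1], cb[2])
    map <- mv(ap[1], ap[2]); mea <- mv(ea[1], ea[2]); meb <- mv(eb[1], eb[2])
    # divergence of a wall from the tangent
    expect_equal(
      angular_divergence(wall_orientation(w$x1[1], w$y1[1], w$x2[1], w$y2[1]),
                         common_tangent_orientation(mca$x, mca$y, mcb$x, mcb$y)),
      angular_divergence(wall_orientation(-3, 0.5, 3, 1),
                         common_tangent_orientation(ca[1], ca[2], cb[1], cb[2])),
      tolerance = 1e-6)
    # splay, overlap, corner distances
    expect_equal(splay_angle(mea$x, mea$y, map$x, map$y, meb$x, meb$y),
                 splay_angle(ea[1], ea[2], ap[1], ap[2], eb[1], eb[2]),
                 tolerance = 1e-6)
    expect_equal(arc_total(rim_wall_overlap(map$x, map$y, w)),
                 arc_total(rim_wall_overlap(ap[1], ap[2], walls0)),
                 tolerance = 1e-6)
    nc0 <- nearest_wall_corners(ap[1], ap[2], walls0)
    nc1 <- nearest_wall_corners(map$x, map$y, w)
    expect_equal(c(nc1$d1, nc1$d2), c(nc0$d1, nc0$d2), tolerance = 1e-6)
  }
})
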