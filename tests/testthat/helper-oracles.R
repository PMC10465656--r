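# Independent oracles used across tests. These deliberately use brute
# force (dense sampling, exhaustive enumeration, textbook formulas) and
# never call the implementation paths they check.

# Dense angular sampling of the rim-overlap metric: fraction of gauge-rim
# points within tol of any wall, at `step`-degree resolution.
sampled_overlap <- function(cx, cy, walls, gauge_diameter = 4,
                            tol_mm = 0.35, step = 0.1) {
  th <- seq(0, 360 - step, by = step) * pi / 180
  r <- gauge_diameter / 2
  px <- cx + r * cos(th)
  py <- cy + r * sin(th)
  dmin <- rep(Inf, length(th))
  for (i in seq_len(nrow(walls))) {
    dmin <- pmin(dmin, point_segment_distance(
      px, py, walls$x1[i], walls$y1[i], walls$x2[i], walls$y2[i]))
  }
  mean(dmin <= tol_mm) * 360
}

# A random well-conditioned projective map: unit-square corners moved by
# small perturbations.
random_homography <- function(scale = 100, jitter = 8) {
  src <- cbind(x = c(0, 1, 1, 0) * scale, y = c(0, 0, 1, 1) * scale)
  dst <- src + matrix(runif(8, -jitter, jitter), 4, 2)
  estimate_homography(src, dst)
}

# Exhaustive-permutation two-sided p-value for the rank-sum test,
# reproducing the min-tail-doubling convention from the U statistic's
# exact null distribution.
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(ix) sum(rk[ix])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Textbook two-sample t statistics (both variants), written out in full.
textbook_t <- function(x, y, variant = "welch") {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(statistic = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# Random rigid motion (rotation + translation) applied to xy coordinates.
rigid_motion <- function() {
  phi <- runif(1, 0, 2 * pi)
  tx <- runif(1, -50, 50); ty <- runif(1, -50, 50)
  function(x, y) {
    list(x = cos(phi) * x - sin(phi) * y + tx,
         y = sin(phi) * x + cos(phi) * y + ty)
  }
}

# A small hand-built tab: one pit, one pit pair, identity-style alignment.
tiny_tab <- function(ppm = 10) {
  stim <- dplyr::bind_rows(
    combmetrics:::make_stimulus("p1", "pit",
      tibble::tibble(point = "centre", x = 50, y = 60), "image-before",
      gauge_diameter_mm = 4),
    combmetrics:::make_stimulus("q1", "pit_pair",
      tibble::tibble(point = c("centre_a", "centre_b"),
                     x = c(100, 150), y = c(80, 80)), "image-before",
      gauge_diameter_mm = 4))
  walls <- tibble::tibble(wall_id = c("w1", "w2"), frame = "image-after",
                          x1 = c(40, 120), y1 = c(40, 20),
                          x2 = c(90, 130), y2 = c(45, 140))
  comb_tab("tiny", pixels_per_mm = ppm, tab_size_mm = c(25, 40),
           alignment = tibble::tibble(x_before = c(0, 250, 250, 0),
                                      y_before = c(0, 0, 400, 400),
                                      x_after = c(0, 250, 250, 0),
                                      y_after = c(0, 0, 400, 400)),
           stimuli = stim, walls = walls)
}
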