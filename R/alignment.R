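# Four-point projective registration between before/after photograph frames.
#
# Exactly four landmark correspondences determine a plane projective map
# (8 degrees of freedom), which removes the scale, displacement, rotation
# and perspective differences between the two photographs of a tab. With
# the count fixed at four the map interpolates its landmarks exactly, so a
# direct 8x8 linear solve is used rather than a least-squares estimator.

new_homography <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  if (abs(m[3, 3]) < 1e-14) {
    abort("homography cannot be normalized: H[3,3] is zero",
          class = "combmetrics_degenerate")
  }
  m <- m / m[3, 3]
  structure(m, class = "comb_homography")
}

collinear_triple <- function(x, y) {
  idx <- utils::combn(length(x), 3)
  for (j in seq_len(ncol(idx))) {
    i <- idx[, j]
    cr <- (x[i[2]] - x[i[1]]) * (y[i[3]] - y[i[1]]) -
          (y[i[2]] - y[i[1]]) * (x[i[3]] - x[i[1]])
    scale <- max(abs(c(x[i] - mean(x[i]), y[i] - mean(y[i]))), 1e-12)
    if (abs(cr) < 1e-9 * scale^2) return(TRUE)
  }
  FALSE
}

#' Estimate a homography from four point correspondences
#'
#' Solves the 8-equation linear system that maps each source landmark
#' exactly onto its target. The four defining correspondences are
#' reproduced to machine precision; no robust estimation is involved.
#'
#' @param src,dst Data frames or matrices with columns/cols `x`, `y` (4
#'   rows): source and target landmark coordinates.
#' @return A `comb_homography`: a 3x3 matrix normalized to `H[3,3] = 1`.
#' @examples
#' src <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' h <- estimate_homography(src, src + 2) # pure translation
#' @export
estimate_homography <- function(src, dst) {
  src <- as.data.frame(src); dst <- as.data.frame(dst)
  names(src)[1:2] <- names(dst)[1:2] <- c("x", "y")
  if (nrow(src) != 4 || nrow(dst) != 4) {
    abort("4 alignment points required", class = "combmetrics_precondition")
  }
  if (anyDuplicated(src[, c("x", "y")]) || anyDuplicated(dst[, c("x", "y")])) {
    abort("duplicate alignment points", class = "combmetrics_degenerate")
  }
  if (collinear_triple(src$x, src$y) || collinear_triple(dst$x, dst$y)) {
    abort("degenerate configuration: three alignment points are collinear",
          class = "combmetrics_degenerate")
  }
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src$x[i]; y <- src$y[i]; u <- dst$x[i]; v <- dst$y[i]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  kap <- kappa(A, exact = FALSE)
  if (kap > 1e8) {
    warn(sprintf("ill-conditioned alignment (condition number %.2e)", kap))
  }
  h <- tryCatch(solve(A, b), error = function(e) {
    abort("degenerate configuration: alignment system is singular",
          class = "combmetrics_degenerate")
  })
  new_homography(matrix(c(h, 1), 3, 3, byrow = TRUE))
}

#' Apply a homography to points
#'
#' Standard projective action with perspective division, vectorized over
#' points.
#'
#' @param h A `comb_homography`.
#' @param x,y Point coordinates.
#' @return A tibble with columns `x`, `y` of mapped coordinates.
#' @export
apply_homography <- function(h, x, y) {
  stopifnot(inherits(h, "comb_homography"))
  w <- h[3, 1] * x + h[3, 2] * y + h[3, 3]
  if (any(abs(w) < 1e-12)) {
    abort("point maps to infinity under this homography",
          class = "combmetrics_degenerate")
  }
  qtb(x = (h[1, 1] * x + h[1, 2] * y + h[1, 3]) / w,
      y = (h[2, 1] * x + h[2, 2] * y + h[2, 3]) / w)
}

#' Invert a homography
#'
#' @param h A `comb_homography`.
#' @return The inverse map, normalized; composing with `h` is the identity.
#' @export
invert_homography <- function(h) {
  stopifnot(inherits(h, "comb_homography"))
  inv <- tryCatch(solve(unclass(h)), error = function(e) {
    abort("homography is singular", class = "combmetrics_degenerate")
  })
  new_homography(inv)
}

#' Compose two homographies
#'
#' @param h1,h2 `comb_homography` objects; the result applies `h2` first,
#'   then `h1`.
#' @return A `comb_homography`.
#' @export
compose_homography <- function(h1, h2) {
  stopifnot(inherits(h1, "comb_homography"), inherits(h2, "comb_homography"))
  new_homography(unclass(h1) %*% unclass(h2))
}

#' @export
print.comb_homography <- function(x, ...) {
  cat("<homography (before -> after)>\n")
  print(unclass(x), ...)
  invisible(x)
}
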