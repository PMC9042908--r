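# Deterministic fractal fixtures with closed-form box-counting dimensions,
# used as oracles for the fractal-dimension and lacunarity estimators.

#' Rasterize a fractal fixture with known dimension
#'
#' Supported fixtures and their closed-form box-counting dimensions:
#' \itemize{
#'   \item `line` — 1-pixel horizontal segment, dimension 1.
#'   \item `filled_square` — solid block, dimension 2.
#'   \item `sierpinski` — Sierpinski triangle on a 2^depth grid,
#'     dimension log(3)/log(2) ~ 1.585.
#'   \item `koch` — Koch-curve approximation on a ternary grid,
#'     dimension log(4)/log(3) ~ 1.262.
#' }
#'
#' @param kind fixture name.
#' @param depth recursion depth (sierpinski/koch); `sierpinski` uses a
#'   2^depth x 2^depth grid, so depth is capped by memory, not resolution.
#' @param size raster side for `line` and `filled_square`.
#' @return logical matrix with attribute `"known_dimension"`.
#' @export
make_fractal <- function(kind = c("line", "filled_square", "sierpinski",
                                  "koch"),
                         depth = 7L, size = 128L) {
  kind <- match.arg(kind)
  depth <- as.integer(depth)
  if (kind %in% c("sierpinski", "koch")) {
    if (depth < 1L) stop("depth must be >= 1", call. = FALSE)
    if (kind == "sierpinski" && depth > 12L)
      stop("depth too deep to rasterize (max 12)", call. = FALSE)
    if (kind == "koch" && depth > 7L)
      stop("depth too deep to rasterize (max 7)", call. = FALSE)
  }
  m <- switch(kind,
    line = {
      m <- matrix(FALSE, size, size)
      m[size %/% 2, ] <- TRUE
      m
    },
    filled_square = matrix(TRUE, size, size),
    sierpinski = {
      n <- 2L^depth
      # Pascal-parity construction: cell (i, j) occupied iff
      # bitwAnd(i, j) == 0 over 0-based indices
      i <- matrix(0:(n - 1L), n, n)
      j <- t(i)
      occ <- matrix(bitwAnd(as.vector(i), as.vector(j)) == 0L, n, n)
      occ
    },
    koch = koch_mask(depth))
  dimv <- switch(kind, line = 1, filled_square = 2,
                 sierpinski = log(3) / log(2), koch = log(4) / log(3))
  structure(m, known_dimension = dimv)
}

koch_mask <- function(depth) {
  # Rasterize the standard Koch curve by subdividing segments and painting
  # the supporting pixels on a 3^depth-wide grid.
  p0 <- c(0, 0); p1 <- c(1, 0)
  segs <- list(rbind(p0, p1))
  rot60 <- function(v, s) {
    a <- s * pi / 3
    c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
  }
  for (d in seq_len(depth)) {
    segs <- unlist(lapply(segs, function(sg) {
      a <- sg[1, ]; b <- sg[2, ]
      v <- (b - a) / 3
      q1 <- a + v; q3 <- a + 2 * v
      q2 <- q1 + rot60(v, 1)
      list(rbind(a, q1), rbind(q1, q2), rbind(q2, q3), rbind(q3, b))
    }), recursive = FALSE)
  }
  n <- 3L^depth
  h <- ceiling(n * sqrt(3) / 6) + 2L
  m <- matrix(FALSE, h, n)
  for (sg in segs) {
    a <- sg[1, ]; b <- sg[2, ]
    steps <- max(2L, ceiling(max(abs(b - a)) * n * 2))
    t <- seq(0, 1, length.out = steps)
    x <- pmin(pmax(floor((a[1] + t * (b[1] - a[1])) * (n - 1)) + 1L, 1L), n)
    y <- pmin(pmax(floor((a[2] + t * (b[2] - a[2])) * (n - 1)) + 1L, 1L), h)
    m[cbind(y, x)] <- TRUE
  }
  m
}
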