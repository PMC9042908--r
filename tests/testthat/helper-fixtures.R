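# Shared fixtures built in code: tiny images, count-expanded cohorts,
# rasterized curves.

# cohort whose rows expand a 2x2 count table (a, b; c, d) for one variable:
# rows = outcome (improved first), columns = predictor level (coded first)
count_cohort <- function(a, b, c, d, var, lev1, lev0) {
  df <- data.frame(
    group = c(rep("improved", a + b), rep("maintained_worse", c + d)),
    stringsAsFactors = FALSE)
  df[[var]] <- c(rep(lev1, a), rep(lev0, b), rep(lev1, c), rep(lev0, d))
  df
}

# 1-px rasterized circular arc spanning `angle` radians
raster_arc <- function(radius = 30, angle = pi, size = 80, n = 720) {
  t <- seq(0, angle, length.out = n)
  m <- matrix(FALSE, size, size)
  ctr <- size / 2
  m[cbind(round(ctr + radius * sin(t)), round(ctr + radius * cos(t)))] <- TRUE
  m
}

# two-level test image: background 10, vessels 200
two_level_image <- function(vessel_mask, bg = 10, fg = 200, ...) {
  px <- matrix(bg, nrow(vessel_mask), ncol(vessel_mask))
  px[vessel_mask] <- fg
  en_face_image(px, ...)
}

full_roi <- function(img) roi_mask(matrix(TRUE, nrow(img$pixels),
                                          ncol(img$pixels)), img)

# exhaustive 256-candidate Otsu oracle, independent of otsu_threshold()
otsu_oracle <- function(x) {
  lev <- round(x)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    g0 <- lev[lev <= t]; g1 <- lev[lev > t]
    if (length(g0) == 0L || length(g1) == 0L) next
    w0 <- length(g0) / length(lev); w1 <- 1 - w0
    v <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}
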