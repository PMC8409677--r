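# fixtures shared across test files; everything is generated in code

# rasterize an analytic region: inside(x, y) with coordinates in px relative
# to the canvas centre (pixel-centre sampling)
raster_region <- function(n, inside) {
  ctr <- (n + 1) / 2
  xs <- (1:n) - ctr
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  matrix(as.integer(inside(X, Y)), n, n)
}

disc_mask <- function(d_px, pad = 6L) {
  r <- d_px / 2
  raster_region(ceiling(d_px) + 2L * pad, function(x, y) x^2 + y^2 <= r^2)
}

ellipse_mask <- function(a_px, b_px, theta = 0, pad = 6L) {
  n <- ceiling(2 * max(a_px, b_px)) + 2L * pad
  raster_region(n, function(x, y) {
    u <- x * cos(theta) + y * sin(theta)
    v <- -x * sin(theta) + y * cos(theta)
    (u / a_px)^2 + (v / b_px)^2 <= 1
  })
}

square_mask <- function(side, pad = 6L) {
  n <- side + 2L * pad
  m <- matrix(0L, n, n)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- 1L
  m
}

# uniform-colour RGB array
flat_rgb <- function(n, rgb) {
  img <- array(0, c(n, n, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# a two-plane-friendly test stack: base noise pattern, selectively blurred
make_test_stack <- function(n = 64, n_planes = 3, sharp_plane = 1,
                            spacing = 8, seed = 42) {
  base <- with_seed_test(seed, matrix(runif(n * n, 0, 255), n, n))
  planes <- lapply(seq_len(n_planes), function(k) {
    y <- if (k == sharp_plane) base else
      as.matrix(EBImage::gblur(base, sigma = 2 * abs(k - sharp_plane),
                               boundary = "replicate"))
    img <- array(0, c(n, n, 3))
    for (ch in 1:3) img[, , ch] <- y
    img
  })
  focal_stack(planes, pixel_size = 0.16, plane_spacing = spacing,
              modality = "BF")
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# brute-force caliper oracle over a fine angle grid (independent of the
# package implementation: plain loop over angles and raw point projections)
oracle_calipers <- function(points, step_deg = 0.005) {
  angs <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  widths <- vapply(angs, function(a) {
    p <- points[, 1] * cos(a) + points[, 2] * sin(a)
    max(p) - min(p)
  }, 1)
  imax <- which.max(widths)
  a90 <- angs[imax] + pi / 2
  p90 <- points[, 1] * cos(a90) + points[, 2] * sin(a90)
  c(max = max(widths), min = min(widths), max90 = max(p90) - min(p90))
}

# independent triangulated-surface oracle: plain double loop over pixel cells
oracle_surface <- function(zmap, mask, s) {
  ch <- matrix(0, nrow(zmap) + 1, ncol(zmap) + 1)
  nr <- nrow(zmap)
  zp <- rbind(2 * zmap[1, ] - zmap[2, ], zmap, 2 * zmap[nr, ] - zmap[nr - 1, ])
  zp <- cbind(2 * zp[, 1] - zp[, 2], zp, 2 * zp[, ncol(zp)] - zp[, ncol(zp) - 1])
  for (i in seq_len(nrow(zmap) + 1)) for (j in seq_len(ncol(zmap) + 1))
    ch[i, j] <- mean(zp[i:(i + 1), j:(j + 1)])
  tri_area <- function(p1, p2, p3) {
    e1 <- p2 - p1; e2 <- p3 - p1
    cx <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    sqrt(sum(cx^2)) / 2
  }
  total <- 0
  for (i in seq_len(nrow(zmap))) for (j in seq_len(ncol(zmap))) {
    if (mask[i, j] != 1) next
    p11 <- c(0, 0, ch[i, j]); p21 <- c(s, 0, ch[i + 1, j])
    p12 <- c(0, s, ch[i, j + 1]); p22 <- c(s, s, ch[i + 1, j + 1])
    total <- total + tri_area(p11, p21, p12) + tri_area(p21, p22, p12)
  }
  total
}
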