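#' Per-plane focus maps
#'
#' Focus is measured per pixel and plane as the local variance of the Laplacian
#' of the luminance within an odd window (default 9 px) — the standard
#' focus-stacking metric; the acquisition software's proprietary reconstruction
#' is not published, so this is the package's stand-in.
#'
#' @param stack a \code{\link{focal_stack}}.
#' @param window odd window size >= 3, not larger than the image.
#' @return list of nonnegative focus matrices, one per plane.
#' @export
focus_measure <- function(stack, window = 9L) {
  stopifnot(inherits(stack, "focal_stack"))
  if (window < 3L || window %% 2L == 0L)
    stop_pollen("window must be odd and >= 3, got %d", window)
  d <- dim(stack$planes[[1]])
  if (window > min(d[1], d[2]))
    stop_pollen("window %d exceeds image size %dx%d", window, d[1], d[2])
  lap_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  box <- matrix(1 / window^2, window, window)
  lapply(stack$planes, function(p) {
    y <- luminance(p)
    lap <- EBImage::filter2(y, lap_k, boundary = "replicate")
    mu <- EBImage::filter2(lap, box, boundary = "replicate")
    v <- EBImage::filter2(lap^2, box, boundary = "replicate") - mu^2
    pmax(matrix(v, d[1], d[2]), 0)
  })
}

#' Extended-depth-of-focus composite and height map
#'
#' Per pixel, the winning plane is the focus-measure argmax (ties broken
#' towards the lower plane index); the composite takes that plane's colour and
#' the height map is winning index times plane spacing. The winning-plane map
#' can be median-smoothed (3x3) before conversion to micrometres, which
#' suppresses isolated focus-noise pixels; smoothing preserves the plane grid.
#'
#' @param stack a \code{\link{focal_stack}}.
#' @param window focus window, px.
#' @param smooth logical; 3x3 median smoothing of the winning-plane map.
#' @return list with \code{composite} (H x W x 3, 0..255), \code{zmap} (um),
#'   \code{focus_scores} (list of per-plane matrices).
#' @export
compose_edf <- function(stack, window = 9L, smooth = TRUE) {
  scores <- focus_measure(stack, window)
  d <- dim(scores[[1]])
  n <- length(scores)
  best <- matrix(1L, d[1], d[2])
  bestv <- scores[[1]]
  for (k in seq_len(n)[-1]) {
    upd <- scores[[k]] > bestv          # strict: ties keep the lower index
    best[upd] <- k
    bestv[upd] <- scores[[k]][upd]
  }
  if (smooth) best <- median3(best)
  comp <- array(0, c(d[1], d[2], 3))
  for (k in seq_len(n)) {
    sel <- best == k
    if (!any(sel)) next
    for (ch in 1:3) {
      pl <- comp[, , ch]
      pl[sel] <- stack$planes[[k]][, , ch][sel]
      comp[, , ch] <- pl
    }
  }
  list(composite = comp, zmap = (best - 1L) * stack$plane_spacing,
       focus_scores = scores)
}

# corner heights (n+1 x p+1) of a pixel-centre height field; edges are
# linearly extrapolated so planar fields triangulate exactly
corner_heights <- function(z) {
  n <- nrow(z); p <- ncol(z)
  stopifnot(n >= 2, p >= 2)
  pad <- matrix(0, n + 2L, p + 2L)
  pad[2:(n + 1), 2:(p + 1)] <- z
  pad[1, 2:(p + 1)] <- 2 * z[1, ] - z[2, ]
  pad[n + 2L, 2:(p + 1)] <- 2 * z[n, ] - z[n - 1L, ]
  pad[, 1] <- 2 * pad[, 2] - pad[, 3]
  pad[, p + 2L] <- 2 * pad[, p + 1L] - pad[, p]
  (pad[1:(n + 1), 1:(p + 1)] + pad[2:(n + 2), 1:(p + 1)] +
   pad[1:(n + 1), 2:(p + 2)] + pad[2:(n + 2), 2:(p + 2)]) / 4
}

#' Surface area of the reconstructed height field over a grain
#'
#' Each pixel cell is split into two triangles on its four corner heights
#' (corners are bilinear averages of the neighbouring pixel heights); the
#' surface is the sum of the two triangle areas per cell, so a flat field
#' returns exactly the planimetric area and any relief strictly increases it.
#'
#' @param zmap um height matrix.
#' @param mask 0/1 matrix selecting grain pixels.
#' @param pixel_size um/px.
#' @return surface area in um^2.
#' @export
edf_surface <- function(zmap, mask, pixel_size) {
  idx <- which(mask == 1L)
  if (!length(idx)) stop_pollen("edf_surface: empty mask")
  ch <- corner_heights(zmap)
  n <- nrow(zmap)
  rr <- ((idx - 1L) %% n) + 1L
  cc <- ((idx - 1L) %/% n) + 1L
  s <- pixel_size
  z11 <- ch[cbind(rr, cc)]         # top-left corner of the pixel cell
  z21 <- ch[cbind(rr + 1L, cc)]
  z12 <- ch[cbind(rr, cc + 1L)]
  z22 <- ch[cbind(rr + 1L, cc + 1L)]
  # triangles (z11, z21, z12) and (z21, z22, z12) on the cell of side s;
  # area = 0.5 * || e1 x e2 || per triangle
  a1 <- 0.5 * sqrt((s * (z12 - z11))^2 + (s * (z21 - z11))^2 + (s * s)^2)
  a2 <- 0.5 * sqrt((s * (z21 - z22))^2 + (s * (z12 - z22))^2 + (s * s)^2)
  sum(a1 + a2)
}

#' EDF roughness: surface to planimetric area ratio
#'
#' @param surface um^2, from \code{\link{edf_surface}}.
#' @param area um^2 planimetric grain area (> 0).
#' @return dimensionless ratio, >= 1 by construction of the triangulation.
#' @export
edf_roughness <- function(surface, area) {
  if (!is.finite(area) || area <= 0) stop_pollen("edf_roughness: area must be > 0")
  surface / area
}

#' Mean baseline-referenced height over a grain
#'
#' Mean of (z - min z over the mask) across mask pixels: object-relative
#' height, since the absolute stage position is meaningless across fields.
#'
#' @inheritParams edf_surface
#' @return um.
#' @export
mean_edf_z <- function(zmap, mask) {
  idx <- which(mask == 1L)
  if (!length(idx)) stop_pollen("mean_edf_z: empty mask")
  z <- zmap[idx]
  mean(z - min(z))
}
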