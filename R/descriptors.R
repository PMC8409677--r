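#' Rotating-caliper Feret diameters of a point set
#'
#' Caliper extents of a 2-D point cloud over a grid of directions.
#' \code{max_feret} is the largest extent, \code{min_feret} the smallest, and
#' \code{max_feret90} the extent perpendicular to the max-Feret direction.
#'
#' @param points n x 2 matrix of coordinates.
#' @param angular_step degrees between sampled directions (default 1).
#' @return named numeric vector \code{max_feret}, \code{min_feret},
#'   \code{max_feret90} in the units of \code{points}.
#' @export
feret_calipers <- function(points, angular_step = 1) {
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 1)
  hull <- points[grDevices::chull(points), , drop = FALSE]
  ang <- seq(0, 180 - angular_step, by = angular_step) * pi / 180
  U <- rbind(cos(ang), sin(ang))
  proj <- hull %*% U
  w <- apply(proj, 2, max) - apply(proj, 2, min)
  imax <- which.max(w)
  perp <- ang[imax] + pi / 2
  u90 <- c(cos(perp), sin(perp))
  p90 <- hull %*% u90
  c(max_feret = w[imax], min_feret = min(w),
    max_feret90 = max(p90) - min(p90))
}

# boundary pixels of a 0/1 mask (pixels with a 4-neighbour background/edge)
boundary_pixels <- function(mask) {
  n <- nrow(mask); p <- ncol(mask)
  pad <- matrix(0L, n + 2L, p + 2L)
  pad[2:(n + 1), 2:(p + 1)] <- mask
  core <- pad[2:(n + 1), 2:(p + 1)] == 1L &
    pad[1:n, 2:(p + 1)] == 1L & pad[3:(n + 2), 2:(p + 1)] == 1L &
    pad[2:(n + 1), 1:p] == 1L & pad[2:(n + 1), 3:(p + 2)] == 1L
  which(mask == 1L & !core, arr.ind = TRUE)
}

# corner points (px) of the boundary pixels: pixel (r, c) spans r +- 0.5, c +- 0.5
mask_corner_points <- function(mask) {
  b <- boundary_pixels(mask)
  rbind(cbind(b[, 1] - 0.5, b[, 2] - 0.5), cbind(b[, 1] - 0.5, b[, 2] + 0.5),
        cbind(b[, 1] + 0.5, b[, 2] - 0.5), cbind(b[, 1] + 0.5, b[, 2] + 0.5))
}

#' Feret diameters of a grain mask
#'
#' Calipers are taken over the convex hull of the boundary pixels' corner
#' points, so a pixel contributes its full square extent (an axis-aligned
#' 100 x 100 px square has min Feret exactly 100 px).
#'
#' @param mask single-component 0/1 matrix.
#' @param pixel_size um/px.
#' @param angular_step caliper direction grid, degrees.
#' @return named vector in um: \code{max_feret}, \code{min_feret},
#'   \code{max_feret90}.
#' @export
feret_diameters <- function(mask, pixel_size, angular_step = 1) {
  if (sum(mask) == 0) stop_pollen("feret_diameters: empty mask")
  feret_calipers(mask_corner_points(mask), angular_step) * pixel_size
}

# Vossepoel-Smeulders corrected chain-code length of the outer contour.
# The plain sqrt(2)-weighted chain overestimates smooth perimeters by ~5%;
# the corrected estimator recovers digitized circles to <1%.
contour_stats <- function(mask) {
  oc <- EBImage::ocontour(mask)
  # outer contour of the (single) component: the longest chain
  pts <- oc[[which.max(vapply(oc, nrow, 1L))]]
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  keep <- rowSums(abs(d)) > 0
  d <- d[keep, , drop = FALSE]
  diag_step <- abs(d[, 1]) == 1 & abs(d[, 2]) == 1
  dirs <- atan2(d[, 2], d[, 1])
  ncorner <- sum(dirs != c(dirs[-1], dirs[1]))
  perim_chain <- sum(ifelse(diag_step, sqrt(2), 1))
  perim_vs <- 0.980 * sum(!diag_step) + 1.406 * sum(diag_step) -
    0.091 * ncorner
  list(points = pts, perimeter = max(perim_vs, 4), chain = perim_chain)
}

polygon_perimeter <- function(p) {
  q <- rbind(p, p[1, ])
  sum(sqrt(rowSums((q[-1, , drop = FALSE] - q[-nrow(q), , drop = FALSE])^2)))
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# mean foreground run length (chords) along direction 0/45/90/135 degrees
mean_chord_px <- function(mask) {
  runs_of <- function(v) {
    r <- rle(v)
    r$lengths[r$values == 1L]
  }
  n <- nrow(mask); p <- ncol(mask)
  h <- unlist(lapply(seq_len(n), function(i) runs_of(mask[i, ])))
  v <- unlist(lapply(seq_len(p), function(j) runs_of(mask[, j])))
  rr <- row(mask); cc <- col(mask)
  # group linear indices by diagonal id
  g1 <- split(seq_len(n * p), as.vector(cc - rr))
  d1 <- unlist(lapply(g1, function(ix) runs_of(mask[ix[order(rr[ix])]])))
  g2 <- split(seq_len(n * p), as.vector(cc + rr))
  d2 <- unlist(lapply(g2, function(ix) runs_of(mask[ix[order(rr[ix])]])))
  dirs <- list(h, v, d1 * sqrt(2), d2 * sqrt(2))
  mean(vapply(dirs, function(x) if (length(x)) mean(x) else NA_real_, 1),
       na.rm = TRUE)
}

#' Two-dimensional morphological descriptors of one grain
#'
#' Computes the 13 planar descriptors: area (pixel count), equivalent-circle
#' diameter, perimeter (corrected chain-code length of the outer contour),
#' mean chord over the 0/45/90/135 degree scan directions, length (max Feret),
#' width (area/length), min Feret, max Feret 90, circularity
#' (4 pi A / P^2), elongation (max/min Feret), shape factor
#' (4 pi A / convex-perimeter^2), convexity (A / convex area) and roughness
#' (convex perimeter / perimeter).
#'
#' @param mask single 8-connected component, at least 20 px across.
#' @param pixel_size um/px.
#' @return named list of the 13 descriptors (um-based units).
#' @export
morphology_2d <- function(mask, pixel_size) {
  stopifnot(pixel_size > 0)
  if (sum(mask) == 0) stop_pollen("morphology_2d: empty mask")
  lab <- label_components(mask)
  if (max(lab) != 1L)
    stop_pollen("morphology_2d: mask has %d components, expected 1", max(lab))
  s <- pixel_size
  area <- sum(mask) * s^2
  cs <- contour_stats(mask)
  perimeter <- cs$perimeter * s
  # convex measures: perimeter on the boundary-centre hull (consistent with
  # the chain-code path), area on the corner-point hull (full pixel extent)
  centre_hull <- cs$points[grDevices::chull(cs$points), , drop = FALSE]
  convex_perimeter <- polygon_perimeter(centre_hull) * s
  corners <- mask_corner_points(mask)
  corner_hull <- corners[grDevices::chull(corners), , drop = FALSE]
  convex_area <- polygon_area(corner_hull) * s^2
  fer <- feret_calipers(corner_hull) * s
  len <- fer[["max_feret"]]
  list(
    area = area,
    eq_diameter = sqrt(4 * area / pi),
    perimeter = perimeter,
    mean_chord = mean_chord_px(mask) * s,
    length = len,
    width = area / len,
    min_feret = fer[["min_feret"]],
    max_feret90 = fer[["max_feret90"]],
    circularity = 4 * pi * area / perimeter^2,
    elongation = len / fer[["min_feret"]],
    shape_factor = 4 * pi * area / convex_perimeter^2,
    convexity = area / convex_area,
    roughness = convex_perimeter / perimeter
  )
}

#' Equivalent-sphere volume
#'
#' Volume of the sphere whose diameter is the grain's equivalent-circle
#' diameter: pi d^3 / 6.
#'
#' @param eq_diameter um, > 0.
#' @return um^3.
#' @export
volume_eq_sphere <- function(eq_diameter) {
  if (any(!is.finite(eq_diameter)) || any(eq_diameter <= 0))
    stop_pollen("volume_eq_sphere: eq_diameter must be > 0")
  pi * eq_diameter^3 / 6
}

#' Equivalent-capsule (spherocylinder) volume
#'
#' Cylinder of diameter d and height (l - d) with hemispherical caps:
#' pi d^2 (l - d) / 4 + pi d^3 / 6. Reduces exactly to the equivalent sphere
#' at l = d. A measured l < d is clamped to d with a warning.
#'
#' @param length l, um (> 0).
#' @param width d, um (> 0).
#' @return um^3.
#' @export
volume_eq_cylinder <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0))
    stop_pollen("volume_eq_cylinder: length and width must be > 0")
  if (any(length < width)) {
    warning("volume_eq_cylinder: length < width; clamping length to width")
    length <- pmax(length, width)
  }
  pi * width^2 * (length - width) / 4 + pi * width^3 / 6
}

# circular mode (1-degree bins) and circular SD, both in degrees
circular_hue_stats <- function(hue_deg) {
  bins <- tabulate(pmin(floor(hue_deg), 359) + 1L, nbins = 360L)
  typ <- which.max(bins) - 1L + 0.5
  th <- hue_deg * pi / 180
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  sdv <- if (rbar >= 1) 0 else sqrt(-2 * log(rbar)) * 180 / pi
  list(typical = typ, variation = sdv)
}

#' Colour descriptors of one grain on the EDF composite
#'
#' Channel means, per-pixel intensity mean and SD, their 0-100 brightness
#' rescalings, HSV hue mode (1-degree circular bins) and circular SD, mean
#' saturation (percent), and per-pixel optical density
#' (-log10(intensity / 255), white reference) mean and SD. By construction
#' mean_intensity = (R + G + B) / 3, mean_brightness = mean_intensity * 100/255
#' and bright_variation = intensity_variation * 100/255, exactly.
#'
#' @param image H x W x 3 array, 0..255.
#' @param mask 0/1 matrix, nonempty.
#' @return named list of the 12 colour descriptors.
#' @export
colour_stats <- function(image, mask) {
  idx <- which(mask == 1L)
  if (!length(idx)) stop_pollen("colour_stats: empty mask")
  r <- image[, , 1][idx]; g <- image[, , 2][idx]; b <- image[, , 3][idx]
  intensity <- (r + g + b) / 3
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 255)
  hue <- hsv[1, ] * 360
  hs <- circular_hue_stats(hue)
  od <- -log10(pmax(intensity, 1) / 255)
  list(
    mean_intensity = mean(intensity),
    intensity_variation = sd0(intensity),
    mean_red = mean(r), mean_green = mean(g), mean_blue = mean(b),
    hue_typical = hs$typical, hue_variation = hs$variation,
    mean_saturation = mean(hsv[2, ]) * 100,
    mean_brightness = mean(intensity) * 100 / 255,
    bright_variation = sd0(intensity) * 100 / 255,
    mean_density = mean(od), density_variation = sd0(od)
  )
}

#' Assemble the 30-descriptor feature table for segmented grains
#'
#' For each grain: 2-D morphology on its mask, equivalent volumes from
#' eq-diameter / length / width, colour statistics on the EDF composite, and
#' the three EDF descriptors on the height map. Grains whose descriptor vector
#' contains a non-finite value are dropped with a message.
#'
#' @param composite H x W x 3 EDF composite (0..255).
#' @param zmap um height matrix from \code{\link{compose_edf}}.
#' @param grains list of grain masks from \code{\link{label_grains}}.
#' @param pixel_size um/px.
#' @param taxon optional true taxon label(s) (length 1 or one per grain).
#' @param modality modality label.
#' @return feature-table data.frame.
#' @export
extract_features <- function(composite, zmap, grains, pixel_size,
                             taxon = NA_character_, modality = "BF") {
  dn <- descriptor_names()
  if (length(taxon) == 1L) taxon <- rep(taxon, length(grains))
  rows <- list()
  for (i in seq_along(grains)) {
    g <- grains[[i]]
    bb <- g$bbox
    sub_img <- composite[bb[1]:bb[2], bb[3]:bb[4], , drop = FALSE]
    sub_z <- zmap[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
    morph <- morphology_2d(g$mask, pixel_size)
    surf <- edf_surface(sub_z, g$mask, pixel_size)
    vals <- c(morph,
              list(volume_eq_sphere = volume_eq_sphere(morph$eq_diameter),
                   volume_eq_cylinder = suppressWarnings(
                     volume_eq_cylinder(morph$length, morph$width))),
              colour_stats(sub_img, g$mask),
              list(edf_surface = surf,
                   edf_roughness = edf_roughness(surf, morph$area),
                   mean_edf_z = mean_edf_z(sub_z, g$mask)))
    v <- unlist(vals[dn])
    if (any(!is.finite(v))) {
      message(sprintf("extract_features: dropping grain %d (non-finite %s)",
                      i, paste(dn[!is.finite(v)], collapse = ", ")))
      next
    }
    row <- as.data.frame(as.list(v))
    names(row) <- dn
    row$taxon <- taxon[i]
    row$modality <- modality
    row$grain_id <- i
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    out <- as.data.frame(lapply(stats::setNames(dn, dn),
                                function(x) numeric(0)))
    out$taxon <- character(0); out$modality <- character(0)
    out$grain_id <- integer(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
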