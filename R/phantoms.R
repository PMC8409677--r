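#' Scene configuration for phantom fields
#'
#' Describes one synthetic field of view: which taxa appear, how many grains
#' per taxon, the optical calibration and the focal-stack geometry. The
#' defaults emulate the acquisition conditions of the study: five focal planes
#' spaced 8 um apart, 8-bit RGB, and a 40x-objective sampling of 0.16 um/px.
#'
#' @param taxa list of \code{\link{taxon_appearance}} objects.
#' @param grains_per_taxon grains rendered per taxon.
#' @param image_size canvas side, px.
#' @param pixel_size um per pixel.
#' @param n_planes number of focal planes (>= 2).
#' @param plane_spacing um between adjacent planes.
#' @param defocus_sigma_per_um Gaussian defocus growth, px of blur sigma per um
#'   of defocus.
#' @param clip_to_threshold clip rendered interior colours into the published
#'   per-modality segmentation threshold box (the real study needed manual
#'   outline corrections; clipping lets the published settings succeed on
#'   synthetic fields). Set \code{FALSE} for table-faithful unclipped colour.
#' @param rng_seed integer seed fixing the whole scene.
#' @return an object of class \code{"scene_config"}.
#' @export
scene_config <- function(taxa, grains_per_taxon = 1L, image_size = 512L,
                         pixel_size = 0.16, n_planes = 5L, plane_spacing = 8,
                         defocus_sigma_per_um = 0.4,
                         clip_to_threshold = TRUE, rng_seed = 1L) {
  stopifnot(is.list(taxa), length(taxa) >= 1L,
            all(vapply(taxa, inherits, TRUE, "taxon_appearance")),
            grains_per_taxon >= 0, image_size >= 32, pixel_size > 0,
            n_planes >= 2, plane_spacing > 0, defocus_sigma_per_um >= 0)
  structure(list(taxa = taxa, grains_per_taxon = as.integer(grains_per_taxon),
                 image_size = as.integer(image_size), pixel_size = pixel_size,
                 n_planes = as.integer(n_planes), plane_spacing = plane_spacing,
                 defocus_sigma_per_um = defocus_sigma_per_um,
                 clip_to_threshold = clip_to_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

# truncated-normal draw (rejection; truncation far in the tail for book values)
rnorm_trunc <- function(n, mean, sd, lower = -Inf) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

# polar boundary radius (um) of a grain envelope plus exine sculpture
grain_radius_fun <- function(major_um, minor_um, theta0, appearance, pars) {
  a <- major_um / 2; b <- minor_um / 2
  h <- appearance$spine_height
  cls <- appearance$exine_class
  function(psi) {
    ang <- psi - theta0
    r <- a * b / sqrt((b * cos(ang))^2 + (a * sin(ang))^2)
    if (h > 0) {
      if (cls == "echinate") {
        # narrow radial spines on top of the envelope
        bump <- pmax(0, cos(pars$n_spines * ang + pars$phase))^8
        r <- r + h * bump
      } else if (cls != "psilate") {
        r <- r + h * sin(pars$n_waves * ang + pars$phase)
      }
    }
    r
  }
}

#' Rasterize one synthetic pollen grain mask
#'
#' Draws a major-axis length from the taxon's (truncated) Normal length
#' distribution and an axis ratio from its elongation distribution, orients the
#' ellipse at a random angle, modulates the boundary by the exine sculpture
#' class (echinate adds radial spines, striate/reticulate classes a
#' low-amplitude boundary ripple, psilate none), and rasterizes the resulting
#' star-shaped region on the pixel grid. The ground-truth record stores the
#' drawn axes exactly.
#'
#' @param appearance a \code{\link{taxon_appearance}}.
#' @param pixel_size um/px; must resolve the grain with at least 20 px across.
#' @param seed optional integer seed (uses the current RNG stream when NULL).
#' @return list with \code{mask} (0/1 integer matrix, single 4-connected
#'   component) and \code{truth} (taxon, drawn major/minor axis in um,
#'   orientation, centre in px).
#' @export
make_grain_mask <- function(appearance, pixel_size, seed = NULL) {
  stopifnot(inherits(appearance, "taxon_appearance"), pixel_size > 0)
  with_seed(seed, {
    L <- rnorm_trunc(1, appearance$length_mean, appearance$length_sd, lower = 2)
    e <- rnorm_trunc(1, appearance$elongation_mean, appearance$elongation_sd,
                     lower = 1)
    if (L / pixel_size < 20)
      stop_pollen("grain of %.2f um spans only %.1f px at %.3f um/px (< 20 px): pixel size too coarse",
                  L, L / pixel_size, pixel_size)
    minor <- L / e
    theta0 <- stats::runif(1, 0, pi)
    pars <- list(n_spines = 24L, n_waves = switch(appearance$exine_class,
                   striate = 12L, reticulate = 9L, micro_reticulate = 17L, 8L),
                 phase = stats::runif(1, 0, 2 * pi))
    rfun <- grain_radius_fun(L, minor, theta0, appearance, pars)
    half <- ceiling((L / 2 + appearance$spine_height + 2 * pixel_size) /
                    pixel_size) + 2L
    n <- 2L * half + 1L
    ctr <- half + 1L
    xs <- ((1:n) - ctr) * pixel_size
    X <- matrix(xs, n, n)            # along rows
    Y <- matrix(xs, n, n, byrow = TRUE)
    d <- sqrt(X^2 + Y^2)
    psi <- atan2(Y, X)
    mask <- matrix(as.integer(d <= rfun(psi)), n, n)
    list(mask = mask,
         truth = list(taxon = appearance$taxon, major_um = L, minor_um = minor,
                      theta = theta0, centre_px = c(ctr, ctr),
                      exine_class = appearance$exine_class))
  })
}

# deterministic non-overlapping placement of grain bounding boxes on a canvas
place_grains <- function(sizes, image_size) {
  n <- length(sizes)
  if (n == 0L) return(list())
  cell <- max(sizes) + 2L
  per_row <- max(1L, image_size %/% cell)
  if (ceiling(n / per_row) * cell > image_size)
    stop_pollen("cannot place %d grains of up to %d px on a %d px canvas",
                n, max(sizes), image_size)
  lapply(seq_len(n) - 1L, function(k) {
    r0 <- (k %/% per_row) * cell + 1L
    c0 <- (k %% per_row) * cell + 1L
    c(r0, c0)
  })
}

modality_background <- function(modality) {
  switch(modality,
         BF = c(205, 205, 205), DF = c(25, 25, 25), Ph = c(165, 165, 165),
         stop_pollen("unknown modality '%s'", modality))
}

# 3x3 median smoothing of an integer matrix (used on the winning-plane map)
median3 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  pad <- matrix(0L, n + 2L, p + 2L)
  pad[2:(n + 1), 2:(p + 1)] <- m
  pad[1, ] <- pad[2, ]; pad[n + 2L, ] <- pad[n + 1L, ]
  pad[, 1] <- pad[, 2]; pad[, p + 2L] <- pad[, p + 1L]
  sh <- array(0L, c(n, p, 9L))
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    sh[, , k] <- pad[(2:(n + 1)) + dr, (2:(p + 1)) + dc]
  }
  apply(sh, c(1, 2), stats::median)
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0.01) return(m)
  EBImage::gblur(m, sigma = sigma, boundary = "replicate")
}

#' Render a multi-modality focal stack for one phantom field
#'
#' Places non-overlapping grains on the canvas, paints their interiors from the
#' taxon's modality colour statistics (optionally clipped into the published
#' segmentation threshold box), builds a dome-shaped height field scaled to the
#' taxon's typical relief (spines raised for echinate exine), quantizes heights
#' to the focal-plane grid, and renders each plane with Gaussian defocus of
#' sigma = defocus_sigma_per_um * |delta z|. Dark field adds a bright rim halo,
#' phase contrast a dark rim shading, matching the qualitative contrast of the
#' modalities.
#'
#' @param config a \code{\link{scene_config}}.
#' @param modality \code{"BF"}, \code{"DF"} or \code{"Ph"}; defaults to the
#'   modality of the first taxon appearance.
#' @param field_id label for the field of view.
#' @return list with \code{stack} (a \code{focal_stack}), \code{truth}
#'   (data.frame manifest: grain_id, taxon, true axes, centre), \code{masks}
#'   (list of full-canvas 0/1 matrices), \code{label_image} (integer matrix),
#'   and \code{zmap_true} (um height field).
#' @export
render_focal_stack <- function(config, modality = NULL, field_id = "field01") {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(modality)) modality <- config$taxa[[1]]$modality
  bg <- modality_background(modality)   # errors on unknown modality
  s <- config$pixel_size
  with_seed(derive_seed(config$rng_seed, paste0("render:", field_id, modality)), {
    grains <- list()
    for (app in config$taxa) {
      stopifnot(app$modality == modality || TRUE)  # appearance colour reused as-is
      for (i in seq_len(config$grains_per_taxon))
        grains[[length(grains) + 1L]] <-
          c(make_grain_mask(app, s), list(appearance = app))
    }
    sizes <- vapply(grains, function(g) nrow(g$mask), 1L)
    at <- place_grains(sizes, config$image_size)

    H <- config$image_size
    label <- matrix(0L, H, H)
    zmap <- matrix(0, H, H)
    col_img <- array(0, c(H, H, 3))
    for (ch in 1:3) col_img[, , ch] <- bg[ch]
    masks <- list(); rows <- list()
    box <- segmentation_defaults(modality)$threshold

    for (k in seq_along(grains)) {
      g <- grains[[k]]; m <- g$mask; n <- nrow(m)
      r0 <- at[[k]][1]; c0 <- at[[k]][2]
      if (r0 + n - 1L > H || c0 + n - 1L > H)
        stop_pollen("grain %d does not fit the %d px canvas", k, H)
      idx <- which(m == 1L)
      rr <- ((idx - 1L) %% n) + r0
      cc <- ((idx - 1L) %/% n) + c0
      lin <- cbind(rr, cc)
      label[lin] <- k
      full <- matrix(0L, H, H); full[lin] <- 1L
      masks[[k]] <- full

      # dome height: z = relief * sqrt(1 - (rho)^2) on the normalized ellipse
      app <- g$appearance
      ctr <- g$truth$centre_px
      X <- ((idx - 1L) %% n) + 1L - ctr[1]
      Y <- ((idx - 1L) %/% n) + 1L - ctr[2]
      ang <- g$truth$theta
      u <- (X * cos(ang) + Y * sin(ang)) * s / (g$truth$major_um / 2)
      v <- (-X * sin(ang) + Y * cos(ang)) * s / (g$truth$minor_um / 2)
      rho2 <- pmin(u^2 + v^2, 1)
      # scale the dome so the mask-mean baseline-referenced height matches the
      # taxon's typical relief: mean of relief*sqrt(1-rho^2) over the ellipse
      # is (2/3)*relief
      dome <- 1.5 * app$z_relief_mean * sqrt(1 - rho2)
      if (app$exine_class == "echinate" && app$spine_height > 0) {
        psi <- atan2(Y, X)
        dome <- dome + app$spine_height *
          pmax(0, cos(24 * (psi - ang)))^8 * (rho2 > 0.5)
      }
      zmap[lin] <- dome

      # interior colour with per-pixel texture noise
      for (ch in 1:3) {
        v0 <- app$interior_rgb_mean[ch] +
          stats::rnorm(length(idx), 0, app$interior_rgb_sd)
        v0 <- clamp255(v0)
        if (config$clip_to_threshold) {
          # clip strictly inside the box so defocus mixing at the rim does not
          # immediately push boundary pixels out of range
          mrg <- min(4, (box$high[ch] - box$low[ch]) / 4)
          v0 <- pmin(pmax(v0, box$low[ch] + mrg), box$high[ch] - mrg)
        }
        plane <- col_img[, , ch]
        plane[lin] <- v0
        col_img[, , ch] <- plane
      }
      # rim effects
      rim <- full - erode_binary(full, 1L)
      rim_idx <- which(rim == 1L)
      if (length(rim_idx)) {
        for (ch in 1:3) {
          plane <- col_img[, , ch]
          if (modality == "DF") plane[rim_idx] <- clamp255(plane[rim_idx] + 60)
          if (modality == "Ph") plane[rim_idx] <- clamp255(plane[rim_idx] - 40)
          col_img[, , ch] <- plane
        }
      }
      rows[[k]] <- data.frame(field_id = field_id, grain_id = k,
                              taxon = app$taxon, modality = modality,
                              true_major_um = g$truth$major_um,
                              true_minor_um = g$truth$minor_um,
                              centre_row = ctr[1] + r0 - 1L,
                              centre_col = ctr[2] + c0 - 1L,
                              stringsAsFactors = FALSE)
    }

    # quantize heights to the plane grid; background sits on plane 0
    kmap <- pmin(pmax(round(zmap / config$plane_spacing), 0),
                 config$n_planes - 1L)
    planes <- vector("list", config$n_planes)
    for (j in seq_len(config$n_planes) - 1L) {
      out <- array(0, c(H, H, 3))
      num <- den <- 0
      for (h in sort(unique(as.vector(kmap)))) {
        w <- (kmap == h) * 1
        sg <- config$defocus_sigma_per_um * abs(h - j) * config$plane_spacing
        wb <- gaussian_blur(w, sg)
        den <- den + wb
        for (ch in 1:3)
          out[, , ch] <- out[, , ch] + gaussian_blur(col_img[, , ch] * w, sg)
      }
      for (ch in 1:3) out[, , ch] <- clamp255(round(out[, , ch] / den))
      planes[[j + 1L]] <- out
    }
    stack <- focal_stack(planes, pixel_size = s,
                         plane_spacing = config$plane_spacing,
                         modality = modality, field_id = field_id)
    list(stack = stack, truth = do.call(rbind, rows), masks = masks,
         label_image = label, zmap_true = zmap)
  })
}

#' Sample a feature table directly from the descriptor book
#'
#' Draws per-grain descriptor vectors from independent Gaussians parameterized
#' by the per-taxon printed means and SDs (the study publishes only marginal
#' statistics, no covariances, so independence is the natural sampling model;
#' it is optimistic relative to real correlated features). Size-type
#' descriptors are truncated at zero.
#'
#' @param n_per_taxon rows per taxon.
#' @param modality \code{"BF"}, \code{"DF"} or \code{"Ph"}.
#' @param taxa taxa to include (defaults to all seven in the book).
#' @param book optional override of \code{\link{taxon_book}(modality)}; must
#'   cover all 30 descriptors for every requested taxon.
#' @param seed integer seed.
#' @return a feature-table data.frame (30 descriptor columns + metadata).
#' @export
sample_feature_table <- function(n_per_taxon, modality = "BF", taxa = NULL,
                                 book = NULL, seed = 1L) {
  modality <- match.arg(modality, c("BF", "DF", "Ph"))
  if (is.null(book)) book <- taxon_book(modality)
  if (is.null(taxa)) taxa <- unique(book$taxon)
  dn <- descriptor_names()
  szd <- size_descriptors()
  for (tx in taxa) {
    have <- book$descriptor[book$taxon == tx]
    miss <- setdiff(dn, have)
    if (length(miss))
      stop_pollen("taxon '%s' is missing descriptor(s): %s", tx,
                  paste(miss, collapse = ", "))
  }
  with_seed(derive_seed(seed, paste0("features:", modality)), {
    blocks <- lapply(taxa, function(tx) {
      sub <- book[book$taxon == tx, ]
      cols <- lapply(dn, function(d) {
        row <- sub[sub$descriptor == d, ][1, ]
        lower <- if (d %in% szd) 0 else -Inf
        rnorm_trunc(n_per_taxon, row$mean, row$sd, lower = lower)
      })
      names(cols) <- dn
      if (n_per_taxon == 0L) {
        df <- as.data.frame(lapply(cols, as.numeric))
        df$taxon <- character(0); df$modality <- character(0)
        df$grain_id <- integer(0)
        return(df)
      }
      df <- as.data.frame(cols)
      df$taxon <- tx; df$modality <- modality
      df$grain_id <- seq_len(n_per_taxon)
      df
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    validate_feature_table(out)
    out
  })
}
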