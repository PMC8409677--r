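#' RGB threshold box
#'
#' Inclusive per-channel bounds on the 0..255 scale. A pixel is foreground iff
#' every channel lies inside its [low, high] interval.
#'
#' @param low,high length-3 numeric vectors (R, G, B), componentwise
#'   \code{low <= high}.
#' @export
threshold_box <- function(low, high) {
  stopifnot(length(low) == 3, length(high) == 3,
            all(low >= 0), all(high <= 255), all(low <= high))
  structure(list(low = as.numeric(low), high = as.numeric(high)),
            class = "threshold_box")
}

#' Published per-modality segmentation settings
#'
#' The object-analysis settings used in the study: an RGB threshold box per
#' modality, plus post-processing. Bright field uses thresholding only; dark
#' field adds contour smoothing (size 16) and 6 iterations of 3x3 opening;
#' phase contrast adds small-object cleaning (16 px) and 3 iterations of 3x3
#' opening.
#'
#' @param modality \code{"BF"}, \code{"DF"} or \code{"Ph"}.
#' @return list with \code{threshold} (a \code{\link{threshold_box}}) and
#'   \code{postprocess} (a \code{\link{postprocess_spec}}).
#' @export
segmentation_defaults <- function(modality) {
  switch(modality,
    BF = list(threshold = threshold_box(c(85, 80, 62), c(130, 122, 98)),
              postprocess = postprocess_spec()),
    DF = list(threshold = threshold_box(c(100, 107, 81), c(169, 154, 118)),
              postprocess = postprocess_spec(smoothing_size = 16,
                                             opening_iterations = 6)),
    Ph = list(threshold = threshold_box(c(71, 72, 59), c(136, 132, 90)),
              postprocess = postprocess_spec(cleaning_size = 16,
                                             opening_iterations = 3)),
    stop_pollen("unknown modality '%s'", modality))
}

#' Binary mask post-processing settings
#'
#' @param smoothing_size contour smoothing disc diameter in px (0 = off).
#' @param cleaning_size drop connected components smaller than this area in px
#'   (0 = off).
#' @param opening_iterations iterations of 3x3 erosion, then as many
#'   dilations (0 = off).
#' @export
postprocess_spec <- function(smoothing_size = 0L, cleaning_size = 0L,
                             opening_iterations = 0L) {
  stopifnot(smoothing_size >= 0, cleaning_size >= 0, opening_iterations >= 0)
  structure(list(smoothing_size = as.integer(smoothing_size),
                 cleaning_size = as.integer(cleaning_size),
                 opening_iterations = as.integer(opening_iterations)),
            class = "postprocess_spec")
}

#' Threshold an RGB image into a binary mask
#'
#' @param image H x W x 3 array on the 0..255 scale.
#' @param box a \code{\link{threshold_box}}.
#' @return 0/1 integer matrix.
#' @export
threshold_rgb <- function(image, box) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L,
            inherits(box, "threshold_box"))
  d <- dim(image)
  r <- matrix(image[, , 1], d[1], d[2])
  g <- matrix(image[, , 2], d[1], d[2])
  b <- matrix(image[, , 3], d[1], d[2])
  fg <- r >= box$low[1] & r <= box$high[1] &
        g >= box$low[2] & g <= box$high[2] &
        b >= box$low[3] & b <= box$high[3]
  matrix(as.integer(fg), d[1], d[2])
}

erode_binary <- function(mask, iterations = 1L, kern = NULL) {
  if (iterations == 0L) return(mask)
  if (is.null(kern)) kern <- matrix(1, 3, 3)
  m <- mask
  for (i in seq_len(iterations)) m <- EBImage::erode(m, kern)
  matrix(as.integer(m > 0.5), nrow(mask), ncol(mask))
}

dilate_binary <- function(mask, iterations = 1L, kern = NULL) {
  if (iterations == 0L) return(mask)
  if (is.null(kern)) kern <- matrix(1, 3, 3)
  m <- mask
  for (i in seq_len(iterations)) m <- EBImage::dilate(m, kern)
  matrix(as.integer(m > 0.5), nrow(mask), ncol(mask))
}

#' 8-connected labelling of a binary mask
#'
#' @param mask 0/1 integer matrix.
#' @return integer matrix of component labels in raster (row-reading) order of
#'   each component's first pixel; 0 = background.
#' @export
label_components <- function(mask) {
  n <- nrow(mask); p <- ncol(mask)
  idx <- which(mask == 1L)
  lab <- matrix(0L, n, p)
  if (!length(idx)) return(lab)
  id <- match(seq_len(n * p), idx)      # linear index -> vertex id
  edges <- NULL
  rr <- ((idx - 1L) %% n) + 1L
  cc <- ((idx - 1L) %/% n) + 1L
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rr + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= n & c2 >= 1L & c2 <= p
    nb <- (c2[ok] - 1L) * n + r2[ok]
    hit <- !is.na(id[nb])
    edges <- rbind(edges, cbind(id[idx[ok][hit]], id[nb[hit]]))
  }
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  g <- igraph::make_graph(edges = t(edges), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel components by raster order (row-major) of their first pixel
  raster <- (rr - 1L) * p + cc
  first <- vapply(split(raster, comp), min, 1)
  ord <- order(first)
  remap <- integer(length(first)); remap[ord] <- seq_along(ord)
  lab[idx] <- remap[comp]
  lab
}

#' Post-process a binary segmentation mask
#'
#' Applied in order: small-object cleaning, opening (n erosions then n
#' dilations with a 3x3 kernel), contour smoothing (morphological closing then
#' opening with a disc of the given diameter). An all-zero spec returns the
#' input unchanged.
#'
#' @param mask 0/1 integer matrix.
#' @param spec a \code{\link{postprocess_spec}}.
#' @return 0/1 integer matrix.
#' @export
postprocess <- function(mask, spec) {
  stopifnot(inherits(spec, "postprocess_spec"))
  m <- mask
  if (spec$cleaning_size > 0L) {
    lab <- label_components(m)
    if (max(lab) > 0L) {
      areas <- tabulate(lab[lab > 0L])
      drop <- which(areas < spec$cleaning_size)
      if (length(drop)) m[lab %in% drop] <- 0L
    }
  }
  if (spec$opening_iterations > 0L) {
    m <- erode_binary(m, spec$opening_iterations)
    m <- dilate_binary(m, spec$opening_iterations)
  }
  if (spec$smoothing_size > 0L) {
    sz <- spec$smoothing_size
    if (sz %% 2L == 0L) sz <- sz + 1L   # disc brushes need an odd support
    brush <- EBImage::makeBrush(sz, shape = "disc")
    m1 <- dilate_binary(m, 1L, brush)
    m1 <- erode_binary(m1, 1L, brush)    # closing
    m1 <- erode_binary(m1, 1L, brush)
    m1 <- dilate_binary(m1, 1L, brush)   # opening
    m <- m1
  }
  m
}

#' Individualize grains from a binary mask
#'
#' 8-connected components; components touching the image border are dropped
#' under \code{border_policy = "exclude"} (a partially imaged grain has invalid
#' descriptors), and components below \code{min_area} are dropped.
#'
#' @param mask 0/1 integer matrix.
#' @param min_area px.
#' @param border_policy \code{"exclude"} or \code{"keep"}.
#' @param field_id,modality provenance labels attached to each grain.
#' @return list of grain masks: each a list with \code{mask} (cropped 0/1
#'   matrix), \code{bbox} (row0, row1, col0, col1), \code{label_id},
#'   \code{area}, \code{field_id}, \code{modality}.
#' @export
label_grains <- function(mask, min_area = 0L,
                         border_policy = c("exclude", "keep"),
                         field_id = "field01", modality = "BF") {
  border_policy <- match.arg(border_policy)
  lab <- label_components(mask)
  k <- max(lab)
  out <- list()
  for (i in seq_len(k)) {
    idx <- which(lab == i, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    if (border_policy == "exclude" &&
        (r0 == 1L || c0 == 1L || r1 == nrow(mask) || c1 == ncol(mask))) next
    sub <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- 1L
    out[[length(out) + 1L]] <- list(mask = sub, bbox = c(r0, r1, c0, c1),
                                    label_id = length(out) + 1L,
                                    area = nrow(idx), field_id = field_id,
                                    modality = modality)
  }
  out
}

#' Segment an EDF composite with the published settings
#'
#' Thresholds the extended-depth-of-focus composite of a stack with the
#' modality's threshold box, applies the modality's post-processing, and
#' individualizes grains.
#'
#' @param composite H x W x 3 array (0..255), normally the EDF composite.
#' @param modality \code{"BF"}, \code{"DF"} or \code{"Ph"}.
#' @param settings override of \code{\link{segmentation_defaults}}.
#' @param min_area minimum component area, px.
#' @inheritParams label_grains
#' @return list of grain masks (see \code{\link{label_grains}}).
#' @export
segment_composite <- function(composite, modality, settings = NULL,
                              min_area = 100L,
                              border_policy = "exclude",
                              field_id = "field01") {
  if (is.null(settings)) settings <- segmentation_defaults(modality)
  m <- threshold_rgb(composite, settings$threshold)
  m <- postprocess(m, settings$postprocess)
  label_grains(m, min_area = min_area, border_policy = border_policy,
               field_id = field_id, modality = modality)
}
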