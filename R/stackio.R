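#' Focal stack container
#'
#' One field of view: an ordered list of registered 8-bit RGB focal planes
#' (bottom to top) plus the physical calibration. Calibration is carried in
#' the object (and the manifest), not in TIFF tags, which are written but never
#' trusted on read.
#'
#' @param planes list of H x W x 3 numeric arrays on the 0..255 scale.
#' @param pixel_size um/px.
#' @param plane_spacing um between planes.
#' @param modality \code{"BF"}, \code{"DF"} or \code{"Ph"}.
#' @param field_id label.
#' @return an object of class \code{"focal_stack"}.
#' @export
focal_stack <- function(planes, pixel_size, plane_spacing, modality,
                        field_id = "field01") {
  if (!is.list(planes) || length(planes) < 2L)
    stop_pollen("a focal stack needs at least 2 planes, got %d",
                length(planes))
  dims <- lapply(planes, dim)
  if (any(vapply(dims, length, 1L) != 3L) ||
      any(vapply(dims, function(d) d[3], 1L) != 3L))
    stop_pollen("all planes must be H x W x 3 RGB arrays")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop_pollen("planes differ in shape")
  stopifnot(pixel_size > 0, plane_spacing > 0)
  modality <- match.arg(modality, c("BF", "DF", "Ph"))
  structure(list(planes = planes, pixel_size = pixel_size,
                 plane_spacing = plane_spacing, modality = modality,
                 field_id = field_id),
            class = "focal_stack")
}

#' @export
print.focal_stack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<focal_stack> %s/%s: %d planes of %dx%d px, %.3f um/px, %.1f um spacing\n",
              x$field_id, x$modality, length(x$planes), d[1], d[2],
              x$pixel_size, x$plane_spacing))
  invisible(x)
}

#' Read and write focal stacks as multi-page TIFF
#'
#' Planes are stored bottom to top as 8-bit RGB pages; the round trip is
#' bit-exact. Calibration is supplied by the caller on read (it lives in the
#' run manifest, not in the file).
#'
#' @param stack a \code{\link{focal_stack}}.
#' @param path TIFF file path.
#' @param pixel_size,plane_spacing,modality,field_id calibration attached on
#'   read.
#' @return \code{read_stack} returns a \code{focal_stack};
#'   \code{write_stack} the path, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "focal_stack"))
  imgs <- lapply(stack$planes, function(p) p / 255)
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, pixel_size, plane_spacing, modality,
                       field_id = "field01") {
  if (!file.exists(path)) stop_pollen("no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop_pollen("'%s' has %d page(s); a focal stack needs at least 2",
                path, length(pages))
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop_pollen("'%s' mixes page shapes", path)
  planes <- lapply(pages, function(p) {
    if (length(dim(p)) == 2L) p <- array(rep(p, 3), c(dim(p), 3))
    if (dim(p)[3] > 3L) p <- p[, , 1:3, drop = FALSE]
    round(p * 255)
  })
  focal_stack(planes, pixel_size, plane_spacing, modality, field_id)
}

#' Read and write binary grain masks as PNG
#'
#' Masks use 255 = foreground, 0 = background; the round trip is exact.
#'
#' @param mask 0/1 integer matrix.
#' @param path PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop_pollen("no such file: %s", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

validate_feature_table <- function(table) {
  want <- c(descriptor_names(), feature_meta_cols())
  extra <- setdiff(names(table), want)
  miss <- setdiff(want, names(table))
  if (length(extra))
    stop_pollen("unknown feature-table column(s): %s",
                paste(extra, collapse = ", "))
  if (length(miss))
    stop_pollen("feature table is missing column(s): %s",
                paste(miss, collapse = ", "))
  num <- table[descriptor_names()]
  if (nrow(table) && any(!vapply(num, is.numeric, TRUE)))
    stop_pollen("descriptor columns must be numeric")
  if (nrow(table) && any(is.na(as.matrix(num))))
    stop_pollen("descriptor columns contain missing values")
  invisible(table)
}

#' Feature-table CSV I/O
#'
#' Fixed header order (the 30 canonical descriptors, then taxon, modality,
#' grain_id); values round-trip at 10 significant digits. Reading a file whose
#' header deviates from the canonical schema is an error naming the offending
#' column.
#'
#' @param table feature-table data.frame.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  out <- table[, c(descriptor_names(), feature_meta_cols())]
  for (d in descriptor_names()) out[[d]] <- signif(out[[d]], 10)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_pollen("no such file: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (d in intersect(descriptor_names(), names(tab)))
    tab[[d]] <- as.numeric(tab[[d]])
  tab$taxon <- as.character(tab$taxon)
  tab$modality <- as.character(tab$modality)
  tab$grain_id <- as.integer(tab$grain_id)
  validate_feature_table(tab)
  tab
}
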