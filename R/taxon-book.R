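#' Per-taxon descriptor statistics book
#'
#' Loads the per-taxon, per-modality descriptor means and standard deviations
#' for the seven honey pollen taxa (Asteraceae, Pyrus/Prunus, Robinia, Tilia,
#' Brassica, Salix, Phacelia) under the three transmitted-light modalities
#' (bright field \code{BF}, dark field \code{DF}, phase contrast \code{Ph}).
#' These printed population statistics parameterize the synthetic phantom
#' generator and the Gaussian feature sampler.
#'
#' 29 of the 30 descriptors have published statistics; the within-grain optical
#' density variation does not, so its entries are filled by the delta method
#' from the intensity statistics: sd(OD) ~ IntensityVariation /
#' (MeanIntensity * ln 10), with the across-grain spread propagated the same
#' way. See the methods vignette.
#'
#' @param modality one of \code{"BF"}, \code{"DF"}, \code{"Ph"}, or \code{NULL}
#'   for the long table covering all three.
#' @return a data.frame with columns \code{taxon}, \code{descriptor},
#'   \code{mean}, \code{sd} (and \code{modality} when \code{modality} is NULL).
#' @export
taxon_book <- function(modality = NULL) {
  path <- system.file("extdata", "taxon_descriptor_book.csv",
                      package = "pollenmorph", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(c("BF", "DF", "Ph"), function(m) {
    pre <- c(BF = "bf", DF = "df", Ph = "ph")[[m]]
    data.frame(taxon = raw$taxon, modality = m, descriptor = raw$descriptor,
               mean = raw[[paste0(pre, "_mean")]],
               sd = raw[[paste0(pre, "_sd")]],
               stringsAsFactors = FALSE)
  }))
  # fill the one unpublished descriptor (within-grain OD spread) per taxon
  dv <- do.call(rbind, lapply(split(long, list(long$taxon, long$modality)),
    function(d) {
      mi <- d$mean[d$descriptor == "mean_intensity"]
      iv_m <- d$mean[d$descriptor == "intensity_variation"]
      iv_s <- d$sd[d$descriptor == "intensity_variation"]
      data.frame(taxon = d$taxon[1], modality = d$modality[1],
                 descriptor = "density_variation",
                 mean = iv_m / (mi * log(10)), sd = iv_s / (mi * log(10)),
                 stringsAsFactors = FALSE)
    }))
  long <- rbind(long, dv)
  rownames(long) <- NULL
  if (!is.null(modality)) {
    modality <- match.arg(modality, c("BF", "DF", "Ph"))
    long <- long[long$modality == modality,
                 c("taxon", "descriptor", "mean", "sd")]
    rownames(long) <- NULL
  }
  long
}

#' @rdname taxon_book
#' @export
taxon_exine <- function() {
  path <- system.file("extdata", "taxon_exine.csv",
                      package = "pollenmorph", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

exine_classes <- function() {
  c("echinate", "striate", "psilate", "reticulate", "micro_reticulate")
}

#' Taxon appearance for phantom rendering
#'
#' Bundles the geometric, textural and colour parameters that the phantom
#' generator needs for one taxon under one modality: envelope size (major-axis
#' length), elongation, exine sculpture class, interior colour, and height
#' relief. Defaults are looked up from the printed per-taxon statistics via
#' \code{\link{taxon_book}}.
#'
#' @param taxon taxon name as used in the book (e.g. \code{"Brassica"}).
#' @param modality \code{"BF"}, \code{"DF"} or \code{"Ph"}.
#' @param length_mean,length_sd major-axis length distribution, um.
#' @param elongation_mean,elongation_sd axis-ratio distribution (>= 1).
#' @param exine_class one of \code{echinate}, \code{striate}, \code{psilate},
#'   \code{reticulate}, \code{micro_reticulate}.
#' @param interior_rgb_mean length-3 mean interior colour, 0-255.
#' @param interior_rgb_sd per-pixel colour noise SD (scalar), 0-255.
#' @param spine_height um; radial spine height (echinate) or boundary
#'   perturbation amplitude (striate/reticulate classes). \code{NULL} picks the
#'   class default.
#' @param z_relief_mean um; characteristic height of the grain dome.
#' @return an object of class \code{"taxon_appearance"}.
#' @export
taxon_appearance <- function(taxon = "Brassica", modality = "BF",
                             length_mean = NULL, length_sd = NULL,
                             elongation_mean = NULL, elongation_sd = NULL,
                             exine_class = NULL,
                             interior_rgb_mean = NULL, interior_rgb_sd = NULL,
                             spine_height = NULL, z_relief_mean = NULL) {
  modality <- match.arg(modality, c("BF", "DF", "Ph"))
  book <- NULL
  lookup <- function(desc, what = "mean") {
    if (is.null(book)) book <<- taxon_book(modality)
    row <- book[book$taxon == taxon & book$descriptor == desc, ]
    if (nrow(row) != 1L)
      stop_pollen("taxon '%s' has no '%s' entry in the descriptor book",
                  taxon, desc)
    row[[what]]
  }
  if (is.null(length_mean)) length_mean <- lookup("length")
  if (is.null(length_sd)) length_sd <- lookup("length", "sd")
  if (is.null(elongation_mean)) elongation_mean <- lookup("elongation")
  if (is.null(elongation_sd)) elongation_sd <- lookup("elongation", "sd")
  if (is.null(exine_class)) {
    ex <- taxon_exine()
    hit <- ex$exine_class[ex$taxon == taxon]
    exine_class <- if (length(hit) == 1L) hit else "psilate"
  }
  exine_class <- match.arg(exine_class, exine_classes())
  if (is.null(interior_rgb_mean))
    interior_rgb_mean <- c(lookup("mean_red"), lookup("mean_green"),
                           lookup("mean_blue"))
  if (is.null(interior_rgb_sd)) interior_rgb_sd <- lookup("intensity_variation")
  if (is.null(spine_height))
    spine_height <- switch(exine_class,
      echinate = 2, striate = 0.3, psilate = 0,
      reticulate = 0.25, micro_reticulate = 0.1)
  if (is.null(z_relief_mean)) z_relief_mean <- lookup("mean_edf_z")

  stopifnot(length_mean > 0, length_sd >= 0, elongation_mean >= 1,
            elongation_sd >= 0, length(interior_rgb_mean) == 3,
            all(interior_rgb_mean >= 0 & interior_rgb_mean <= 255),
            interior_rgb_sd >= 0, spine_height >= 0, z_relief_mean >= 0)
  structure(list(
    taxon = taxon, modality = modality,
    length_mean = length_mean, length_sd = length_sd,
    elongation_mean = elongation_mean, elongation_sd = elongation_sd,
    exine_class = exine_class,
    interior_rgb_mean = as.numeric(interior_rgb_mean),
    interior_rgb_sd = interior_rgb_sd,
    spine_height = spine_height, z_relief_mean = z_relief_mean
  ), class = "taxon_appearance")
}

#' @export
print.taxon_appearance <- function(x, ...) {
  cat(sprintf("<taxon_appearance> %s / %s: length %.2f +- %.2f um, elongation %.2f +- %.2f, %s exine\n",
              x$taxon, x$modality, x$length_mean, x$length_sd,
              x$elongation_mean, x$elongation_sd, x$exine_class))
  invisible(x)
}
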