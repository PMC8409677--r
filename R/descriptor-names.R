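#' Canonical descriptor catalogue
#'
#' The pipeline measures 30 descriptors per pollen grain: 13 two-dimensional
#' morphological descriptors (including Roughness, the convex-perimeter to
#' perimeter ratio), 2 equivalent-volume descriptors, 12 colour descriptors on
#' the extended-depth-of-focus composite, and 3 EDF descriptors derived from the
#' per-pixel height map. Column names are frozen: every feature table uses
#' exactly these names, in this order, followed by the metadata columns
#' \code{taxon}, \code{modality}, \code{grain_id}.
#'
#' @return \code{descriptor_names()} returns the character vector of the 30
#'   canonical names; \code{descriptor_units()} a named character vector of
#'   units; \code{size_descriptors()} the subset that is strictly positive by
#'   definition (truncated at zero when sampled).
#' @export
descriptor_names <- function() {
  c(
    # 2D morphology
    "area", "eq_diameter", "perimeter", "mean_chord", "length", "width",
    "min_feret", "max_feret90", "circularity", "elongation", "shape_factor",
    "convexity", "roughness",
    # equivalent volumes
    "volume_eq_sphere", "volume_eq_cylinder",
    # colour
    "mean_intensity", "intensity_variation", "mean_red", "mean_green",
    "mean_blue", "hue_typical", "hue_variation", "mean_saturation",
    "mean_brightness", "bright_variation", "mean_density", "density_variation",
    # extended depth of focus
    "edf_surface", "edf_roughness", "mean_edf_z"
  )
}

#' @rdname descriptor_names
#' @export
descriptor_units <- function() {
  c(
    area = "um^2", eq_diameter = "um", perimeter = "um", mean_chord = "um",
    length = "um", width = "um", min_feret = "um", max_feret90 = "um",
    circularity = "1", elongation = "1", shape_factor = "1", convexity = "1",
    roughness = "1",
    volume_eq_sphere = "um^3", volume_eq_cylinder = "um^3",
    mean_intensity = "0-255", intensity_variation = "0-255",
    mean_red = "0-255", mean_green = "0-255", mean_blue = "0-255",
    hue_typical = "deg", hue_variation = "deg", mean_saturation = "%",
    mean_brightness = "%", bright_variation = "%", mean_density = "OD",
    density_variation = "OD",
    edf_surface = "um^2", edf_roughness = "1", mean_edf_z = "um"
  )
}

#' @rdname descriptor_names
#' @export
size_descriptors <- function() {
  c("area", "eq_diameter", "perimeter", "mean_chord", "length", "width",
    "min_feret", "max_feret90", "volume_eq_sphere", "volume_eq_cylinder",
    "edf_surface", "intensity_variation", "bright_variation", "hue_variation",
    "mean_density", "density_variation")
}

feature_meta_cols <- function() c("taxon", "modality", "grain_id")
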