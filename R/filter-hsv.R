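#' Configuration for HSV threshold segmentation
#'
#' Bundles the HSV acceptance range for the histochemical reaction with the
#' two thresholds that separate bright unsaturated glass background from
#' tissue. Presets carry calibration defaults for the two stains:
#'
#' * `"pas"` — periodic acid-Schiff, magenta reaction product:
#'   H in \[280, 345\] degrees, S in \[0.15, 1\], V in \[0.15, 0.95\].
#' * `"ab"` — alcian blue (pH 2.5), blue reaction product:
#'   H in \[180, 260\] degrees, same S/V bounds.
#'
#' These defaults are calibration choices for typical brightfield material,
#' not published constants; override `reaction_range` for a different camera
#' or staining batch.
#'
#' @param stain one of `"pas"`, `"ab"`, `"custom"`. `"custom"` requires an
#'   explicit `reaction_range`.
#' @param reaction_range an [hsv_range()] overriding the preset.
#' @param background_sat_max pixels with saturation strictly below this AND
#'   value strictly above `background_val_min` count as glass background.
#' @param background_val_min see above.
#' @return A `filter_hsv_config` object.
#' @examples
#' filter_hsv_config("pas")
#' @export
filter_hsv_config <- function(stain = c("pas", "ab", "custom"),
                              reaction_range = NULL,
                              background_sat_max = 0.10,
                              background_val_min = 0.85) {
  stain <- match.arg(stain)
  if (is.null(reaction_range)) {
    reaction_range <- switch(stain,
      pas = hsv_range(280, 345, 0.15, 1, 0.15, 0.95),
      ab  = hsv_range(180, 260, 0.15, 1, 0.15, 0.95),
      custom = stop("stain = 'custom' requires an explicit 'reaction_range'")
    )
  }
  stopifnot(inherits(reaction_range, "hsv_range"))
  if (background_sat_max < 0 || background_sat_max > 1 ||
      background_val_min < 0 || background_val_min > 1) {
    stop("background thresholds must lie in [0, 1]")
  }
  structure(
    list(stain = stain, reaction_range = reaction_range,
         background_sat_max = background_sat_max,
         background_val_min = background_val_min),
    class = "filter_hsv_config"
  )
}

#' Glass-background mask
#'
#' A pixel is background iff it is bright and unsaturated:
#' `s < background_sat_max` and `v > background_val_min`. The tissue mask is
#' the complement; the area-fraction denominator counts every non-background
#' pixel, reaction included.
#'
#' @param hsv an `hsv_image`.
#' @param config a [filter_hsv_config()].
#' @return Logical matrix, `TRUE` at background pixels.
#' @export
background_mask <- function(hsv, config) {
  stopifnot(inherits(hsv, "hsv_image"), inherits(config, "filter_hsv_config"))
  hsv$s < config$background_sat_max & hsv$v > config$background_val_min
}

#' Threshold segmentation of the histochemical reaction
#'
#' A pixel belongs to the reaction iff its hue lies in the (wraparound-aware)
#' hue interval, its saturation and value fall inside their bounds, and the
#' pixel is not glass background. The result is always a subset of the tissue
#' mask. No morphological post-processing is applied.
#'
#' @inheritParams background_mask
#' @return Logical matrix, `TRUE` at reaction pixels.
#' @export
segment_reaction_hsv <- function(hsv, config) {
  stopifnot(inherits(hsv, "hsv_image"), inherits(config, "filter_hsv_config"))
  r <- config$reaction_range
  in_range <- hue_in_range(as.vector(hsv$h), r) &
    as.vector(hsv$s) >= r$sat_lo & as.vector(hsv$s) <= r$sat_hi &
    as.vector(hsv$v) >= r$val_lo & as.vector(hsv$v) <= r$val_hi
  m <- matrix(in_range, nrow(hsv$h), ncol(hsv$h))
  m & !background_mask(hsv, config)
}

field_result <- function(reaction_pixels, tissue_pixels, background_pixels,
                         backend, stain) {
  if (tissue_pixels < reaction_pixels) {
    stop("reaction pixel count exceeds tissue pixel count")
  }
  structure(
    list(reaction_pixels = as.integer(reaction_pixels),
         tissue_pixels = as.integer(tissue_pixels),
         background_pixels = as.integer(background_pixels),
         area_fraction_percent = 100 * reaction_pixels / tissue_pixels,
         backend = backend, stain = stain),
    class = "field_result"
  )
}

#' @export
print.field_result <- function(x, ...) {
  cat(sprintf(
    "<field_result [%s/%s] A%% = %.2f (reaction %d / tissue %d, background %d)>\n",
    x$backend, x$stain, x$area_fraction_percent,
    x$reaction_pixels, x$tissue_pixels, x$background_pixels))
  invisible(x)
}

#' Area fraction of one field by HSV thresholding
#'
#' Runs the full HSV filtering pipeline on a single microscope field and
#' reports the stain area fraction
#' `A% = 100 * reaction pixels / tissue pixels`, where tissue pixels are all
#' non-background pixels.
#'
#' @param image an [rgb_image()] (or plain array coercible to one).
#' @param config a [filter_hsv_config()].
#' @param name label used in the empty-field error message.
#' @return A `field_result` with pixel counts and `area_fraction_percent`.
#' @examples
#' f <- generate_field(field_spec(64, 64, target_fraction = 0.2, seed = 1))
#' field_area_fraction_hsv(f$image, filter_hsv_config("pas"))
#' @export
field_area_fraction_hsv <- function(image, config = filter_hsv_config("pas"),
                                    name = "field") {
  image <- as_rgb_image(image)
  hsv <- rgb_to_hsv_image(image)
  bg <- background_mask(hsv, config)
  reaction <- segment_reaction_hsv(hsv, config)
  tissue_px <- sum(!bg)
  if (tissue_px == 0L) {
    stop("empty field: no tissue pixels in '", name, "'")
  }
  field_result(sum(reaction), tissue_px, sum(bg),
               backend = "filter_hsv", stain = config$stain)
}
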