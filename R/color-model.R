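#' Construct an RGB raster image
#'
#' Wraps a `height x width x 3` integer array of 8-bit channel values into a
#' validated `rgb_image` object, the common raster currency of both
#' segmentation backends.
#'
#' @param pixels numeric array of dimension `c(height, width, 3)` with values
#'   in `[0, 255]`.
#' @return An `rgb_image`: the array with class attribute and validated
#'   invariants.
#' @examples
#' img <- rgb_image(array(128, dim = c(4, 5, 3)))
#' dim(img)
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("'pixels' must be a 3-dimensional array (height x width x 3)")
  }
  d <- dim(pixels)
  if (d[3] != 3L) {
    stop("channel count must be 3 (got ", d[3], ")")
  }
  if (d[1] < 1L || d[2] < 1L) {
    stop("raster must have height >= 1 and width >= 1")
  }
  if (anyNA(pixels)) stop("NA channel values are not allowed")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, 8-bit RGB>\n", d[1], d[2]))
  invisible(x)
}

#' Convert an RGB image to HSV
#'
#' Standard hexcone conversion applied per pixel. Hue is reported in degrees
#' in `[0, 360)`, saturation and value as fractions in `[0, 1]`. Achromatic
#' pixels (S = 0) get hue 0 by convention, so gray pixels are matched only
#' through saturation/value bounds, never through a hue interval.
#'
#' @param image an [rgb_image()].
#' @return An `hsv_image`: a list of three `height x width` numeric matrices
#'   `h` (degrees), `s`, `v` (fractions).
#' @examples
#' img <- rgb_image(array(c(255, 0, 255), dim = c(1, 1, 3)))
#' hsv <- rgb_to_hsv_image(img)
#' hsv$h  # 300 (magenta)
#' @export
rgb_to_hsv_image <- function(image) {
  image <- as_rgb_image(image)
  d <- dim(image)
  m <- rbind(
    as.vector(image[, , 1]),
    as.vector(image[, , 2]),
    as.vector(image[, , 3])
  )
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  out <- list(
    h = matrix(hsv[1, ] * 360, d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
  # 360 can only arise from rounding; fold onto 0
  out$h[out$h >= 360] <- 0
  structure(out, class = "hsv_image")
}

#' @export
print.hsv_image <- function(x, ...) {
  cat(sprintf("<hsv_image %d x %d>\n", nrow(x$h), ncol(x$h)))
  invisible(x)
}

#' Convert an HSV raster back to 8-bit RGB
#'
#' Inverse of [rgb_to_hsv_image()]; used by the synthetic-field generator to
#' paint in HSV terms and by round-trip tests.
#'
#' @param hsv an `hsv_image`.
#' @return An [rgb_image()].
#' @export
hsv_to_rgb_image <- function(hsv) {
  stopifnot(inherits(hsv, "hsv_image"))
  h <- as.vector(hsv$h) / 60
  s <- as.vector(hsv$s)
  v <- as.vector(hsv$v)
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - f * s)
  t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  d <- c(nrow(hsv$h), ncol(hsv$h), 3L)
  px <- array(0L, d)
  px[, , 1] <- round(r * 255)
  px[, , 2] <- round(g * 255)
  px[, , 3] <- round(b * 255)
  rgb_image(px)
}

as_rgb_image <- function(x) {
  if (inherits(x, "rgb_image")) return(x)
  rgb_image(x)
}

#' Define an HSV acceptance range
#'
#' A per-channel acceptance interval for HSV thresholding. The hue interval
#' is closed and may wrap across the 0/360 degree seam: `hue_lo > hue_hi`
#' means the interval crosses 0 (e.g. `[330, 30]` covers magenta-to-orange
#' reds). Saturation and value intervals are ordinary closed intervals.
#'
#' @param hue_lo,hue_hi hue bounds in degrees, each in `[0, 360]`.
#' @param sat_lo,sat_hi saturation bounds in `[0, 1]`, `sat_lo <= sat_hi`.
#' @param val_lo,val_hi value bounds in `[0, 1]`, `val_lo <= val_hi`.
#' @return An `hsv_range` object.
#' @examples
#' pas <- hsv_range(280, 345, 0.15, 1, 0.15, 0.95)
#' hue_in_range(322, pas)
#' @export
hsv_range <- function(hue_lo, hue_hi, sat_lo = 0, sat_hi = 1,
                      val_lo = 0, val_hi = 1) {
  vals <- c(hue_lo, hue_hi, sat_lo, sat_hi, val_lo, val_hi)
  if (anyNA(vals) || !is.numeric(vals)) stop("range bounds must be numeric")
  if (hue_lo < 0 || hue_lo > 360 || hue_hi < 0 || hue_hi > 360) {
    stop("hue bounds must lie in [0, 360]")
  }
  if (sat_lo < 0 || sat_hi > 1 || sat_lo > sat_hi) {
    stop("saturation bounds must satisfy 0 <= sat_lo <= sat_hi <= 1")
  }
  if (val_lo < 0 || val_hi > 1 || val_lo > val_hi) {
    stop("value bounds must satisfy 0 <= val_lo <= val_hi <= 1")
  }
  structure(
    list(hue_lo = hue_lo, hue_hi = hue_hi, sat_lo = sat_lo, sat_hi = sat_hi,
         val_lo = val_lo, val_hi = val_hi),
    class = "hsv_range"
  )
}

#' @export
print.hsv_range <- function(x, ...) {
  cat(sprintf("<hsv_range H [%g, %g]%s S [%g, %g] V [%g, %g]>\n",
              x$hue_lo, x$hue_hi,
              if (x$hue_lo > x$hue_hi) " (wraps 0)" else "",
              x$sat_lo, x$sat_hi, x$val_lo, x$val_hi))
  invisible(x)
}

#' Test hue membership in a (possibly wrapping) interval
#'
#' @param hue numeric vector of hues in degrees, each in `[0, 360)`.
#' @param range an [hsv_range()].
#' @return Logical vector: `TRUE` where the hue lies in the closed interval
#'   `[hue_lo, hue_hi]`, interpreted as crossing 0 degrees when
#'   `hue_lo > hue_hi`.
#' @examples
#' hue_in_range(c(350, 180), hsv_range(330, 30))  # TRUE FALSE
#' @export
hue_in_range <- function(hue, range) {
  stopifnot(inherits(range, "hsv_range"))
  if (anyNA(hue) || any(hue < 0 | hue >= 360)) {
    stop("hue values must lie in [0, 360)")
  }
  if (range$hue_lo <= range$hue_hi) {
    hue >= range$hue_lo & hue <= range$hue_hi
  } else {
    hue >= range$hue_lo | hue <= range$hue_hi
  }
}
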