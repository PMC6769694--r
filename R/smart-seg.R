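#' Fit a three-class color model from seed pixels
#'
#' Replaces the interactive color-picking step of commercial "smart
#' segmentation" tools with explicit seed pixels. Each of the three classes —
#' 1 = histochemical reaction, 2 = tissue without reaction, 3 = background —
#' gets a Gaussian color model (mean vector and full 3x3 covariance) fitted
#' to its seeds. A ridge `epsilon` is added to the covariance diagonal so a
#' class seeded with a single color stays usable (quadratic discriminants
#' need an invertible covariance).
#'
#' @param seeds named list with components `reaction`, `tissue`,
#'   `background`, each an `n x 3` matrix of seed colors. On the default
#'   `"rgb"` color space these are 8-bit RGB rows; with `"hsv-cartesian"`
#'   they are still supplied as RGB and mapped internally to
#'   `255 * (S cos H, S sin H, V)`, which removes the hue seam.
#' @param epsilon ridge added to each covariance diagonal, on the 0-255
#'   scale. Default 1.0.
#' @param colorspace `"rgb"` or `"hsv-cartesian"`.
#' @return A `color_class_model` with per-class means, regularized
#'   covariances, their inverses and log-determinants.
#' @examples
#' m <- fit_color_classes(list(
#'   reaction = matrix(c(190, 30, 130), 1),
#'   tissue = matrix(c(110, 95, 170), 1),
#'   background = matrix(c(250, 248, 251), 1)))
#' @export
fit_color_classes <- function(seeds, epsilon = 1.0,
                              colorspace = c("rgb", "hsv-cartesian")) {
  colorspace <- match.arg(colorspace)
  class_names <- c("reaction", "tissue", "background")
  for (cn in class_names) {
    s <- seeds[[cn]]
    if (is.null(s) || NROW(s) < 1L) {
      stop("no seed pixels supplied for class '", cn, "'")
    }
    if (NCOL(s) != 3L) stop("seeds for class '", cn, "' must have 3 columns")
  }
  if (epsilon <= 0) stop("'epsilon' must be positive")
  fit_one <- function(s) {
    s <- features_for(matrix(as.numeric(s), ncol = 3), colorspace)
    mu <- colMeans(s)
    sigma <- if (nrow(s) > 1L) stats::cov(s) else matrix(0, 3, 3)
    sigma <- sigma + diag(epsilon, 3)
    list(mean = mu, cov = sigma, cov_inv = solve(sigma),
         logdet = determinant(sigma, logarithm = TRUE)$modulus[1])
  }
  structure(
    list(classes = lapply(seeds[class_names], fit_one),
         epsilon = epsilon, colorspace = colorspace),
    class = "color_class_model"
  )
}

#' @export
print.color_class_model <- function(x, ...) {
  cat(sprintf("<color_class_model 3 classes, %s space, epsilon %g>\n",
              x$colorspace, x$epsilon))
  invisible(x)
}

# Map an n x 3 RGB (0-255) matrix into the model's feature space.
features_for <- function(rgb, colorspace) {
  if (colorspace == "rgb") return(rgb)
  hsv <- grDevices::rgb2hsv(t(rgb), maxColorValue = 255)
  h <- hsv[1, ] * 2 * pi
  cbind(255 * hsv[2, ] * cos(h), 255 * hsv[2, ] * sin(h), 255 * hsv[3, ])
}

#' Classify every pixel into reaction / tissue / background
#'
#' Assigns each pixel the class with the highest Gaussian log-density
#' (quadratic discriminant analysis with equal priors). Deterministic; exact
#' log-density ties go to the lowest class index.
#'
#' @param image an [rgb_image()].
#' @param model a fitted [fit_color_classes()] model.
#' @return A `label_mask`: integer matrix of labels in `{1, 2, 3}`
#'   (1 = reaction, 2 = tissue, 3 = background) with the raster's shape.
#' @export
classify_pixels <- function(image, model) {
  image <- as_rgb_image(image)
  stopifnot(inherits(model, "color_class_model"))
  d <- dim(image)
  x <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  x <- features_for(x, model$colorspace)
  scores <- vapply(model$classes, function(cl) {
    d1 <- x[, 1] - cl$mean[1]
    d2 <- x[, 2] - cl$mean[2]
    d3 <- x[, 3] - cl$mean[3]
    iv <- cl$cov_inv
    q <- iv[1, 1] * d1 * d1 + iv[2, 2] * d2 * d2 + iv[3, 3] * d3 * d3 +
      2 * (iv[1, 2] * d1 * d2 + iv[1, 3] * d1 * d3 + iv[2, 3] * d2 * d3)
    -0.5 * (q + cl$logdet)
  }, numeric(nrow(x)))
  # vapply drops to a plain vector for single-pixel rasters
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  labels <- max.col(scores, ties.method = "first")
  structure(matrix(as.integer(labels), d[1], d[2]), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  n <- tabulate(x, 3L)
  cat(sprintf("<label_mask %d x %d: reaction %d, tissue %d, background %d>\n",
              nrow(x), ncol(x), n[1], n[2], n[3]))
  invisible(x)
}

#' Area fraction from a three-class label mask
#'
#' Computes the class-based stain area fraction
#' `A% = 100 * n(class 1) / (n(class 1) + n(class 2))`. Background (class 3)
#' pixels appear in neither numerator nor denominator, so A% is invariant
#' under any change confined to class-3 pixels.
#'
#' @param mask a `label_mask` from [classify_pixels()], or an integer matrix
#'   of labels in `{1, 2, 3}`.
#' @param stain stain label carried into the result.
#' @param name label used in the empty-field error message.
#' @return A `field_result` with `backend = "smart_seg"`.
#' @examples
#' m <- matrix(c(1, 1, 2, 3), 2)
#' field_area_fraction_classes(m)$area_fraction_percent  # 66.67
#' @export
field_area_fraction_classes <- function(mask, stain = "pas", name = "field") {
  if (!is.matrix(mask) || anyNA(mask) || !all(mask %in% 1:3)) {
    stop("'mask' must be a matrix of labels in {1, 2, 3}")
  }
  n <- tabulate(as.integer(mask), 3L)
  if (n[1] + n[2] == 0L) {
    stop("empty field: no class-1 or class-2 pixels in '", name, "'")
  }
  field_result(n[1], n[1] + n[2], n[3], backend = "smart_seg", stain = stain)
}

#' Area fraction of one field by seeded pixel classification
#'
#' Convenience wrapper: classify, then apply the class-count formula.
#'
#' @inheritParams classify_pixels
#' @inheritParams field_area_fraction_classes
#' @return A `field_result`.
#' @export
field_area_fraction_smart <- function(image, model, stain = "pas",
                                      name = "field") {
  field_area_fraction_classes(
    unclass(classify_pixels(image, model)), stain = stain, name = name)
}

#' Sample classifier seeds from a labeled raster
#'
#' Draws `n_per_class` pixels of each class from a truth (or hand-labeled)
#' mask, returning them in the list format [fit_color_classes()] expects.
#' Used to seed the classifier from the synthetic generator's ground truth,
#' or from small labeled seed-mask images.
#'
#' @param image an [rgb_image()].
#' @param labels integer matrix of labels in `{1, 2, 3}`, same shape.
#' @param n_per_class seeds drawn per class (fewer if a class is smaller).
#' @param seed integer RNG seed; sampling never touches the global RNG state.
#' @return Named list of three seed matrices.
#' @export
sample_seeds_from_labels <- function(image, labels, n_per_class = 200,
                                     seed = 1L) {
  image <- as_rgb_image(image)
  stopifnot(all(dim(labels) == dim(image)[1:2]))
  chans <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                 as.vector(image[, , 3]))
  withr::with_seed(seed, {
    out <- lapply(1:3, function(k) {
      idx <- which(as.vector(labels) == k)
      if (length(idx) == 0L) return(NULL)
      take <- sample(idx, min(n_per_class, length(idx)))
      chans[take, , drop = FALSE]
    })
    names(out) <- c("reaction", "tissue", "background")
    out
  })
}
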