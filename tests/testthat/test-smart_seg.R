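test_that("well-separated seed colors classify back to their own classes", {
  model <- fit_color_classes(pure_seed_list())
  img <- patch_image(1, 1, 1)
  labels <- classify_pixels(img, model)
  expect_equal(as.vector(labels), c(1L, 2L, 3L))
})

test_that("single-seed classes survive regularization without singularity", {
  model <- fit_color_classes(pure_seed_list(), epsilon = 1.0)
  for (cl in model$classes) {
    ev <- eigen(cl$cov, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
  px <- array(c(190L, 30L, 130L), c(1, 1, 3))
  expect_equal(as.vector(classify_pixels(rgb_image(px), model)), 1L)
})

test_that("missing class seeds raise a configuration error naming the class", {
  seeds <- pure_seed_list()
  seeds$tissue <- NULL
  expect_error(fit_color_classes(seeds), "tissue")
  seeds2 <- pure_seed_list()
  seeds2$background <- matrix(numeric(0), 0, 3)
  expect_error(fit_color_classes(seeds2), "background")
})

test_that("single-pixel rasters classify to the correct class, not just class 1", {
  model <- fit_color_classes(pure_seed_list())
  px2 <- array(c(110L, 95L, 170L), c(1, 1, 3))
  expect_equal(as.vector(classify_pixels(rgb_image(px2), model)), 2L)
  px3 <- array(c(250L, 248L, 251L), c(1, 1, 3))
  expect_equal(as.vector(classify_pixels(rgb_image(px3), model)), 3L)
})

test_that("a pixel at a class mean gets that class; exact ties go to the lowest index", {
  seeds <- pure_seed_list()
  seeds$tissue <- seeds$reaction  # classes 1 and 2 now identical
  model <- fit_color_classes(seeds)
  px <- array(c(190L, 30L, 130L), c(1, 1, 3))
  expect_equal(as.vector(classify_pixels(rgb_image(px), model)), 1L)
})

test_that("label masks partition the raster", {
  f <- generate_field(field_spec(96, 96, target_fraction = 0.3, seed = 2))
  model <- fit_color_classes(sample_seeds_from_labels(f$image, f$truth,
                                                      100, seed = 3))
  labels <- classify_pixels(f$image, model)
  expect_true(all(labels %in% 1:3))
  expect_equal(sum(tabulate(as.integer(labels), 3L)), length(labels))
})

test_that("pixel accuracy against ground truth is at least 95% at default noise", {
  f <- generate_field(field_spec(256, 256, target_fraction = 0.2, seed = 13))
  model <- fit_color_classes(sample_seeds_from_labels(f$image, f$truth,
                                                      200, seed = 14))
  labels <- classify_pixels(f$image, model)
  expect_gte(mean(unclass(labels) == f$truth), 0.95)
})

test_that("the class-count formula and its edge cases are exact", {
  m <- matrix(3L, 40, 25)
  m[1:30] <- 1L
  m[31:100] <- 2L
  res <- field_area_fraction_classes(m)
  expect_equal(res$area_fraction_percent, 30)
  expect_equal(res$backend, "smart_seg")
  # class-1 absent -> 0%
  m0 <- m; m0[m0 == 1L] <- 2L
  expect_equal(field_area_fraction_classes(m0)$area_fraction_percent, 0)
  # no class 1 or 2 -> empty field error
  expect_error(field_area_fraction_classes(matrix(3L, 5, 5), name = "f3"),
               "empty field.*f3")
  expect_error(field_area_fraction_classes(matrix(0L, 2, 2)), "labels")
})

test_that("A% is invariant under changes confined to class-3 pixels", {
  m <- matrix(c(rep(1L, 30), rep(2L, 70), rep(3L, 900)), 10, 100)
  a0 <- field_area_fraction_classes(m)$area_fraction_percent
  # double the raster with pure background: counts of class 3 change only
  m2 <- cbind(m, matrix(3L, 10, 100))
  expect_identical(field_area_fraction_classes(m2)$area_fraction_percent, a0)
})

test_that("the hsv-cartesian feature space classifies across the hue seam", {
  # reds straddling 0/360: raw RGB means would be fine, but the mapped
  # space must also keep the classes coherent
  seeds <- list(
    reaction = rbind(c(200, 30, 60), c(200, 30, 40)),  # hues ~ 349 and 356
    tissue = matrix(c(40, 90, 170), 1),
    background = matrix(c(250, 248, 251), 1))
  model <- fit_color_classes(seeds, colorspace = "hsv-cartesian")
  px <- array(c(201L, 31L, 50L), c(1, 1, 3))
  expect_equal(as.vector(classify_pixels(rgb_image(px), model)), 1L)
})

test_that("smart backend recovers a synthetic field's A% within 2 pp", {
  f <- generate_field(field_spec(256, 256, target_fraction = 0.5, seed = 8))
  model <- fit_color_classes(sample_seeds_from_labels(f$image, f$truth,
                                                      200, seed = 9))
  res <- field_area_fraction_smart(f$image, model)
  expect_lt(abs(res$area_fraction_percent - f$true_fraction_percent), 2)
})
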