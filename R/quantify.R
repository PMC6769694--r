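#' Aggregate per-field area fractions into a slide summary
#'
#' Slides are scored as the arithmetic mean of the per-field A% values (with
#' sample SD and median alongside), mirroring the usual practice of reading
#' ten random fields per slide. All fields must come from the same backend
#' and stain; a slide scored with mixed methods is a consistency error.
#'
#' @param field_results list of `field_result` objects for one slide.
#' @param slide_id identifier carried into the summary.
#' @param group `"tumor"` or `"control"` (or any cohort label).
#' @param expected_fields number of fields normally read per slide; fewer
#'   triggers a warning, not an error.
#' @return A `slide_result`: list with `slide_id`, `group`, `stain`,
#'   `backend`, `field_fractions`, `mean_a_percent`, `sd_a_percent`,
#'   `median_a_percent`, `n_fields`.
#' @examples
#' fr <- lapply(c(10, 20, 30), function(a)
#'   structure(list(area_fraction_percent = a, backend = "filter_hsv",
#'                  stain = "pas"), class = "field_result"))
#' aggregate_slide(fr, "s1", expected_fields = 3)$mean_a_percent  # 20
#' @export
aggregate_slide <- function(field_results, slide_id = "slide",
                            group = "tumor", expected_fields = 10L) {
  if (length(field_results) < 1L) stop("at least one field result required")
  stopifnot(all(vapply(field_results, inherits, logical(1), "field_result")))
  backends <- unique(vapply(field_results, `[[`, character(1), "backend"))
  stains <- unique(vapply(field_results, `[[`, character(1), "stain"))
  if (length(backends) != 1L || length(stains) != 1L) {
    stop("inconsistent slide: mixed backends (", paste(backends, collapse = ","),
         ") or stains (", paste(stains, collapse = ","), ")")
  }
  a <- vapply(field_results, `[[`, numeric(1), "area_fraction_percent")
  n <- length(a)
  if (n < expected_fields) {
    warning(sprintf("slide '%s': only %d field(s), expected %d",
                    slide_id, n, expected_fields))
  }
  sd_a <- if (n > 1L) stats::sd(a) else {
    warning(sprintf("slide '%s': single field, SD undefined, reported as 0",
                    slide_id))
    0
  }
  structure(
    list(slide_id = slide_id, group = group, stain = stains,
         backend = backends, field_fractions = a,
         mean_a_percent = mean(a), sd_a_percent = sd_a,
         median_a_percent = stats::median(a), n_fields = n),
    class = "slide_result"
  )
}

#' @export
print.slide_result <- function(x, ...) {
  cat(sprintf("<slide_result %s [%s/%s/%s]: A%% %.2f +/- %.2f (n = %d)>\n",
              x$slide_id, x$group, x$stain, x$backend,
              x$mean_a_percent, x$sd_a_percent, x$n_fields))
  invisible(x)
}

#' Percentage-of-positive-cells category (PP, 0-4)
#'
#' Bins the fraction of positively stained cells into the classical
#' five-level PP category of the immunoreactive score:
#' 0 for no positive cells; 1 for under 10%; 2 for 10-50%; 3 for over 50%
#' up to 80%; 4 for over 80%. Boundaries are fixed half-open as
#' `0 | (0, 0.10) | [0.10, 0.50] | (0.50, 0.80] | (0.80, 1]` so every input
#' maps to exactly one category.
#'
#' @param fraction_positive fraction in `[0, 1]` (vectorized).
#' @return Integer vector of categories 0-4.
#' @examples
#' pp_category(c(0, 0.05, 0.10, 0.6, 0.95))  # 0 1 2 3 4
#' @export
pp_category <- function(fraction_positive) {
  f <- fraction_positive
  if (anyNA(f) || any(f < 0 | f > 1)) {
    stop("'fraction_positive' must lie in [0, 1]")
  }
  as.integer(ifelse(f == 0, 0L,
             ifelse(f < 0.10, 1L,
             ifelse(f <= 0.50, 2L,
             ifelse(f <= 0.80, 3L, 4L)))))
}

#' Inputs of the immunoreactive score
#'
#' @param pp_category integer 0-4, percentage-of-positive-cells category.
#' @param si integer 0-3, staining-intensity category (an operator judgment;
#'   never inferred from pixels here).
#' @return An `irs_inputs` object.
#' @export
irs_inputs <- function(pp_category, si) {
  if (length(pp_category) != 1L || pp_category %% 1 != 0 ||
      pp_category < 0 || pp_category > 4) {
    stop("'pp_category' must be a single integer in 0..4")
  }
  if (length(si) != 1L || si %% 1 != 0 || si < 0 || si > 3) {
    stop("'si' must be a single integer in 0..3")
  }
  structure(list(pp_category = as.integer(pp_category), si = as.integer(si)),
            class = "irs_inputs")
}

#' Immunoreactive score (IRS, 0-12)
#'
#' The semi-quantitative 12-point score: the product of the PP category
#' (0-4) and the staining-intensity category SI (0-3). Band labels follow
#' the usual reading: 0 negative, 1-2 low, 3-4 moderate, 6-12 strong.
#' Scores 5, 7, 10 and 11 cannot arise as products of the category sets.
#'
#' @param inputs an [irs_inputs()] object.
#' @return List with integer `score` and character `band`.
#' @examples
#' irs_score(irs_inputs(4, 3))  # score 12, band "strong"
#' @export
irs_score <- function(inputs) {
  stopifnot(inherits(inputs, "irs_inputs"))
  score <- inputs$pp_category * inputs$si
  band <- if (score == 0) "negative"
          else if (score <= 2) "low"
          else if (score <= 4) "moderate"
          else "strong"
  list(score = as.integer(score), band = band)
}
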