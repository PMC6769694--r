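#' Specification of a synthetic stained-tissue field
#'
#' Describes one brightfield microscope field to synthesize: a tissue region
#' on bright glass, crypt-like reaction blobs (unions of random ellipses)
#' occupying a known fraction of the tissue, counterstained tissue texture,
#' a multiplicative illumination gradient, and per-pixel Gaussian camera
#' noise. Default colors emulate the two stains: magenta reaction on
#' blue-violet hematoxylin counterstain for PAS; blue reaction on red
#' safranin counterstain for AB; near-white glass in both.
#'
#' @param width,height raster size in pixels.
#' @param target_fraction target true area fraction of the reaction within
#'   tissue, in `[0, 1]`. The generator lands exactly on
#'   `round(target_fraction * tissue pixels)` reaction pixels, so the
#'   realized true A% is within 1/tissue of the target.
#' @param stain `"pas"` or `"ab"`; selects the default reaction and
#'   counterstain colors.
#' @param reaction_color,counterstain_color,background_color length-3 RGB
#'   vectors (0-255) overriding the stain defaults.
#' @param blob_radius_range min/max semi-axis of reaction ellipses, px.
#' @param tissue_lumina number of glass lumina punched into the tissue.
#' @param texture_sd SD of the per-pixel luminance texture on tissue and
#'   reaction (same offset on all three channels, so hue is untouched).
#' @param illumination amplitude of the multiplicative illumination ramp
#'   (0 = flat; 0.08 means the far corner is 8% darker).
#' @param noise_sd SD of independent per-channel Gaussian pixel noise
#'   (0-255 scale).
#' @param seed integer RNG seed; generation never touches global RNG state.
#' @return A `field_spec` object.
#' @export
field_spec <- function(width = 512L, height = 512L, target_fraction = 0.2,
                       stain = c("pas", "ab"),
                       reaction_color = NULL, counterstain_color = NULL,
                       background_color = c(250, 248, 251),
                       blob_radius_range = c(0.015, 0.08) * width,
                       tissue_lumina = 3L, texture_sd = 10,
                       illumination = 0.08, noise_sd = 8, seed = 1L) {
  stain <- match.arg(stain)
  if (target_fraction < 0 || target_fraction > 1) {
    stop("'target_fraction' must lie in [0, 1]")
  }
  if (noise_sd < 0 || texture_sd < 0) stop("noise SDs must be >= 0")
  if (illumination < 0 || illumination >= 1) {
    stop("'illumination' must lie in [0, 1)")
  }
  if (is.null(reaction_color)) {
    reaction_color <- switch(stain, pas = c(190, 30, 130), ab = c(40, 90, 170))
  }
  if (is.null(counterstain_color)) {
    counterstain_color <- switch(stain, pas = c(110, 95, 170),
                                 ab = c(205, 85, 90))
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         target_fraction = target_fraction, stain = stain,
         reaction_color = reaction_color,
         counterstain_color = counterstain_color,
         background_color = background_color,
         blob_radius_range = blob_radius_range,
         tissue_lumina = as.integer(tissue_lumina),
         texture_sd = texture_sd, illumination = illumination,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "field_spec"
  )
}

# TRUE inside an axis-aligned ellipse, evaluated on the full raster grid.
ellipse_mask <- function(height, width, cx, cy, rx, ry) {
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  y <- matrix(seq_len(height), height, width)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

#' Generate one synthetic stained field with ground truth
#'
#' Deterministic given `spec$seed`. The truth mask uses the three-class
#' convention (1 = reaction, 2 = tissue without reaction, 3 = background)
#' and the emitted true A% is computed from the truth-mask counts by the
#' class formula `100 * n1 / (n1 + n2)`.
#'
#' @param spec a [field_spec()].
#' @return List with `image` ([rgb_image()]), `truth` (integer label
#'   matrix), `true_fraction_percent`, and the `spec`.
#' @examples
#' f <- generate_field(field_spec(64, 64, target_fraction = 0.25, seed = 7))
#' f$true_fraction_percent
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  withr::with_seed(spec$seed, generate_field_impl(spec))
}

generate_field_impl <- function(spec) {
  h <- spec$height
  w <- spec$width
  # tissue: one large central ellipse with a few glass lumina punched out
  tissue <- ellipse_mask(h, w, cx = w * stats::runif(1, 0.45, 0.55),
                         cy = h * stats::runif(1, 0.45, 0.55),
                         rx = 0.55 * w, ry = 0.55 * h)
  for (i in seq_len(spec$tissue_lumina)) {
    tissue <- tissue & !ellipse_mask(
      h, w, cx = stats::runif(1, 0.2, 0.8) * w,
      cy = stats::runif(1, 0.2, 0.8) * h,
      rx = stats::runif(1, 0.02, 0.05) * w,
      ry = stats::runif(1, 0.02, 0.05) * h)
  }
  tissue_idx <- which(tissue)
  n_tissue <- length(tissue_idx)
  target_count <- round(spec$target_fraction * n_tissue)

  reaction <- matrix(FALSE, h, w)
  n_reaction <- 0L
  attempts <- 0L
  rmin <- spec$blob_radius_range[1]
  rmax <- spec$blob_radius_range[2]
  while (n_reaction < target_count) {
    attempts <- attempts + 1L
    if (attempts > 20000L) {
      stop("unachievable target area fraction: blobs do not fit the raster")
    }
    center <- tissue_idx[sample.int(n_tissue, 1L)]
    cy <- (center - 1L) %% h + 1L
    cx <- (center - 1L) %/% h + 1L
    rx <- stats::runif(1, rmin, rmax)
    ry <- stats::runif(1, rmin, rmax)
    # rasterize on the bounding box only
    rows <- max(1L, floor(cy - ry)):min(h, ceiling(cy + ry))
    cols <- max(1L, floor(cx - rx)):min(w, ceiling(cx + rx))
    xx <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    yy <- matrix(rows, length(rows), length(cols))
    inside <- ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
    idx <- (rep(cols, each = length(rows)) - 1L) * h + rep(rows, length(cols))
    new_px <- idx[as.vector(inside) & tissue[idx] & !reaction[idx]]
    excess <- n_reaction + length(new_px) - target_count
    if (excess > 0L) {
      new_px <- sample(new_px, length(new_px) - excess)
    }
    reaction[new_px] <- TRUE
    n_reaction <- n_reaction + length(new_px)
  }

  truth <- matrix(3L, h, w)
  truth[tissue] <- 2L
  truth[reaction] <- 1L

  n <- h * w
  base <- matrix(rep(spec$background_color, each = n), n, 3)
  flat_truth <- as.vector(truth)
  for (ch in 1:3) {
    base[flat_truth == 2L, ch] <- spec$counterstain_color[ch]
    base[flat_truth == 1L, ch] <- spec$reaction_color[ch]
  }
  # luminance texture on tissue and reaction: equal offset on all channels,
  # hue-preserving
  if (spec$texture_sd > 0) {
    tex <- stats::rnorm(n, 0, spec$texture_sd) * (flat_truth != 3L)
    base <- base + tex
  }
  # multiplicative illumination ramp toward the lower-right corner
  if (spec$illumination > 0) {
    gx <- (col(truth) - 1) / max(1L, w - 1L)
    gy <- (row(truth) - 1) / max(1L, h - 1L)
    ramp <- 1 - spec$illumination * as.vector((gx + gy) / 2)
    base <- base * ramp
  }
  if (spec$noise_sd > 0) {
    base <- base + matrix(stats::rnorm(3 * n, 0, spec$noise_sd), n, 3)
  }
  px <- array(0L, c(h, w, 3))
  for (ch in 1:3) {
    px[, , ch] <- pmin(255L, pmax(0L, as.integer(round(base[, ch]))))
  }
  list(image = rgb_image(px), truth = truth,
       true_fraction_percent = 100 * target_count / n_tissue, spec = spec)
}

#' Specification of a synthetic patient cohort
#'
#' Describes a cohort of paired tumor/control slides with per-stain,
#' per-backend A% readouts, clinical covariates and survival. Default
#' location/scale parameters are anchored to the magnitudes typical of
#' colorectal material: control slides around 55-62% stained area, tumors
#' around 10-18%, mucinous tumors with elevated alcian-blue reactivity and
#' flat tumors with elevated PAS. Setting every shift, correlation and the
#' hazard ratio to its null value (and tumor means equal to control means)
#' gives a no-effect cohort for calibration studies.
#'
#' @param n_patients cohort size.
#' @param pas_tumor_mean,pas_tumor_sd,pas_control_mean,pas_control_sd
#'   latent A% distribution for the PAS stain, percent.
#' @param ab_tumor_mean,ab_tumor_sd,ab_control_mean,ab_control_sd same for
#'   alcian blue.
#' @param backend_sd SD of the independent measurement error each backend
#'   adds to the latent slide A%.
#' @param mucinous_ab_shift added to tumor AB A% of mucinous cases, pp.
#' @param flat_pas_shift added to tumor PAS A% of flat tumors, pp.
#' @param control_pas_ab_rho latent correlation between control PAS and AB.
#' @param control_ab_hb_rho latent correlation, control AB vs hemoglobin.
#' @param control_pas_glucose_rho latent correlation, control PAS vs serum
#'   glucose.
#' @param p_mucinous,p_flat,p_proximal subtype probabilities.
#' @param event_rate exponential hazard of death per month.
#' @param hazard_ratio multiplicative hazard for patients with above-mean
#'   tumor PAS expression (1 = no survival effect).
#' @param censor_range months; administrative censoring drawn uniformly.
#' @param seed integer RNG seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 33L,
                        pas_tumor_mean = 18.4, pas_tumor_sd = 11.3,
                        pas_control_mean = 61.6, pas_control_sd = 15.9,
                        ab_tumor_mean = 10.1, ab_tumor_sd = 8.3,
                        ab_control_mean = 55.8, ab_control_sd = 13.5,
                        backend_sd = 2,
                        mucinous_ab_shift = 7, flat_pas_shift = 9,
                        control_pas_ab_rho = 0.55,
                        control_ab_hb_rho = 0.45,
                        control_pas_glucose_rho = 0.40,
                        p_mucinous = 0.30, p_flat = 0.39, p_proximal = 0.40,
                        event_rate = 0.005, hazard_ratio = 1,
                        censor_range = c(30, 60), seed = 1L) {
  if (n_patients < 1L) stop("'n_patients' must be >= 1")
  sds <- c(pas_tumor_sd, pas_control_sd, ab_tumor_sd, ab_control_sd,
           backend_sd)
  if (any(sds < 0)) stop("SD parameters must be >= 0")
  probs <- c(p_mucinous, p_flat, p_proximal)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  rhos <- c(control_pas_ab_rho, control_ab_hb_rho, control_pas_glucose_rho)
  if (any(abs(rhos) > 1)) stop("correlations must lie in [-1, 1]")
  if (event_rate < 0 || hazard_ratio <= 0) {
    stop("'event_rate' must be >= 0 and 'hazard_ratio' > 0")
  }
  structure(as.list(environment()), class = "cohort_spec")
}

clamp_pct <- function(x) pmin(100, pmax(0, x))

#' Generate a synthetic patient cohort
#'
#' Deterministic given `spec$seed`. Produces one row per patient with paired
#' tumor/control A% per stain per backend, IRS scores, clinical covariates
#' and survival. The configured effects (tumor-vs-control shift via the
#' group means, mucinous AB elevation, flat-tumor PAS elevation, control
#' PAS-AB / AB-hemoglobin / PAS-glucose correlations, hazard ratio) are
#' built in at exactly the configured sizes.
#'
#' @param spec a [cohort_spec()].
#' @return A data frame (one row per patient); see the package vignette for
#'   the column dictionary.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_patients
  # latent standard normals with the configured correlation structure
  z_pas_c <- stats::rnorm(n)
  r1 <- spec$control_pas_ab_rho
  z_ab_c <- r1 * z_pas_c + sqrt(1 - r1^2) * stats::rnorm(n)
  r2 <- spec$control_ab_hb_rho
  z_hb <- r2 * z_ab_c + sqrt(1 - r2^2) * stats::rnorm(n)
  r3 <- spec$control_pas_glucose_rho
  z_glu <- r3 * z_pas_c + sqrt(1 - r3^2) * stats::rnorm(n)

  mucinous <- stats::rbinom(n, 1, spec$p_mucinous)
  macro_type <- ifelse(stats::rbinom(n, 1, spec$p_flat) == 1,
                       "flat", "protruded")
  localization <- ifelse(stats::rbinom(n, 1, spec$p_proximal) == 1,
                         "proximal", "distal")

  pas_tumor <- clamp_pct(spec$pas_tumor_mean +
                           spec$flat_pas_shift * (macro_type == "flat") +
                           spec$pas_tumor_sd * stats::rnorm(n))
  ab_tumor <- clamp_pct(spec$ab_tumor_mean +
                          spec$mucinous_ab_shift * mucinous +
                          spec$ab_tumor_sd * stats::rnorm(n))
  pas_control <- clamp_pct(spec$pas_control_mean + spec$pas_control_sd * z_pas_c)
  ab_control <- clamp_pct(spec$ab_control_mean + spec$ab_control_sd * z_ab_c)

  meas <- function(latent) clamp_pct(latent + stats::rnorm(n, 0, spec$backend_sd))

  si_from <- function(a) ifelse(a < 5, 1L, ifelse(a < 25, 2L, 3L))
  irs_from <- function(a) pp_category(a / 100) * si_from(a)

  # survival: exponential with the hazard ratio applied to above-mean tumor
  # PAS expression; administrative censoring
  above <- pas_tumor > mean(pas_tumor)
  rate <- spec$event_rate * ifelse(above, spec$hazard_ratio, 1)
  event_time <- if (spec$event_rate > 0) stats::rexp(n, rate) else rep(Inf, n)
  censor_time <- stats::runif(n, spec$censor_range[1], spec$censor_range[2])
  survival_months <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time)

  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = pmin(95, pmax(30, round(66 + 12 * stats::rnorm(n)))),
    sex = ifelse(stats::rbinom(n, 1, 0.8) == 1, "male", "female"),
    grade = sample(c("G1", "G2", "G3"), n, replace = TRUE,
                   prob = c(0.06, 0.67, 0.27)),
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.12, 0.36, 0.40, 0.12)),
    mucinous = mucinous,
    macro_type = macro_type,
    localization = localization,
    hemoglobin = round(13.5 + 1.5 * z_hb, 1),
    wbc = round(pmax(2, 7.5 + 2 * stats::rnorm(n)), 1),
    thrombocytes = round(pmax(50, 280 + 70 * stats::rnorm(n))),
    glucose = round(95 + 14 * z_glu),
    pas_tumor_hsv = meas(pas_tumor), pas_tumor_smart = meas(pas_tumor),
    pas_control_hsv = meas(pas_control), pas_control_smart = meas(pas_control),
    ab_tumor_hsv = meas(ab_tumor), ab_tumor_smart = meas(ab_tumor),
    ab_control_hsv = meas(ab_control), ab_control_smart = meas(ab_control),
    irs_pas_tumor = irs_from(pas_tumor), irs_ab_tumor = irs_from(ab_tumor),
    irs_pas_control = 12L, irs_ab_control = 12L,
    survival_months = round(survival_months, 1),
    event = event,
    stringsAsFactors = FALSE
  )
}
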