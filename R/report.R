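#' Full statistical report on a cohort table
#'
#' Runs the study's statistical plan on a cohort data frame (schema of
#' [generate_cohort()]): tumor-vs-control paired Wilcoxon per stain and
#' backend, subgroup Mann-Whitney contrasts (mucinous vs nonmucinous, flat
#' vs protruded, proximal vs distal, grade G2 vs G3, stage II vs III),
#' Spearman correlations of A% with clinical covariates, Cronbach's alpha
#' between scoring methods, and Kaplan-Meier / log-rank survival for
#' below- vs above-mean tumor expression. Two-sided p-values throughout;
#' no multiple-testing correction is applied.
#'
#' Tables whose inputs are missing or degenerate (too few patients, missing
#' columns, constant values) are skipped with a warning, never a crash; the
#' names of skipped tables are returned in `skipped`.
#'
#' @param cohort data frame with the [generate_cohort()] column dictionary.
#' @return List with `tables` (named list of data frames: `expression`,
#'   `mucinous`, `macro_type`, `localization`, `grade`, `stage`,
#'   `correlations`, `agreement`, `km_curves`, `km_test`) and `skipped`
#'   (character vector).
#' @examples
#' rep <- cohort_report(generate_cohort(cohort_spec(seed = 4)))
#' rep$tables$expression
#' @export
cohort_report <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (!"patient_id" %in% names(cohort)) stop("'cohort' lacks patient_id")
  skipped <- character(0)
  tables <- list()
  combos <- expand.grid(stain = c("pas", "ab"), backend = c("hsv", "smart"),
                        stringsAsFactors = FALSE)
  acol <- function(stain, group, backend) {
    cohort[[paste(stain, group, backend, sep = "_")]]
  }
  try_table <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      warning("table '", name, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) skipped <<- c(skipped, name)
    tables[[name]] <<- res
    invisible(NULL)
  }

  # tumor vs control expression, paired Wilcoxon, per stain x backend
  try_table("expression", {
    do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      s <- combos$stain[i]; b <- combos$backend[i]
      tum <- acol(s, "tumor", b); ctl <- acol(s, "control", b)
      if (is.null(tum) || is.null(ctl)) stop("missing A% columns")
      w <- wilcoxon_paired(tum, ctl)
      data.frame(stain = s, backend = b,
                 tumor_mean = mean(tum), tumor_sd = stats::sd(tum),
                 tumor_median = stats::median(tum),
                 control_mean = mean(ctl), control_sd = stats::sd(ctl),
                 control_median = stats::median(ctl),
                 wilcoxon_v = w$statistic, p_value = w$p_value)
    }))
  })

  subgroup_mw <- function(flag) {
    do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      s <- combos$stain[i]; b <- combos$backend[i]
      tum <- acol(s, "tumor", b)
      if (is.null(tum)) stop("missing A% columns")
      g1 <- tum[flag]; g0 <- tum[!flag]
      mw <- mann_whitney(g1, g0)
      data.frame(stain = s, backend = b,
                 group1_n = length(g1), group1_mean = mean(g1),
                 group1_median = stats::median(g1),
                 group0_n = length(g0), group0_mean = mean(g0),
                 group0_median = stats::median(g0),
                 u = mw$statistic, p_value = mw$p_value)
    }))
  }
  try_table("mucinous", subgroup_mw(cohort$mucinous == 1))
  try_table("macro_type", subgroup_mw(cohort$macro_type == "flat"))
  try_table("localization", subgroup_mw(cohort$localization == "proximal"))
  try_table("grade", {
    keep <- cohort$grade %in% c("G2", "G3")
    sub <- cohort[keep, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      s <- combos$stain[i]; b <- combos$backend[i]
      tum <- sub[[paste(s, "tumor", b, sep = "_")]]
      g1 <- tum[sub$grade == "G3"]; g0 <- tum[sub$grade == "G2"]
      mw <- mann_whitney(g1, g0)
      data.frame(stain = s, backend = b,
                 g3_n = length(g1), g3_mean = mean(g1),
                 g2_n = length(g0), g2_mean = mean(g0),
                 u = mw$statistic, p_value = mw$p_value)
    }))
  })
  try_table("stage", {
    keep <- cohort$stage %in% c("II", "III")
    sub <- cohort[keep, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      s <- combos$stain[i]; b <- combos$backend[i]
      tum <- sub[[paste(s, "tumor", b, sep = "_")]]
      g1 <- tum[sub$stage == "III"]; g0 <- tum[sub$stage == "II"]
      mw <- mann_whitney(g1, g0)
      data.frame(stain = s, backend = b,
                 iii_n = length(g1), iii_mean = mean(g1),
                 ii_n = length(g0), ii_mean = mean(g0),
                 u = mw$statistic, p_value = mw$p_value)
    }))
  })

  # Spearman correlations of A% with clinical covariates
  try_table("correlations", {
    covs <- c("age", "hemoglobin", "wbc", "thrombocytes", "glucose")
    if (!all(covs %in% names(cohort))) stop("missing covariate columns")
    grid <- expand.grid(stain = c("pas", "ab"), group = c("tumor", "control"),
                        backend = c("hsv", "smart"), covariate = covs,
                        stringsAsFactors = FALSE)
    do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      a <- acol(grid$stain[i], grid$group[i], grid$backend[i])
      sp <- spearman_rho(a, cohort[[grid$covariate[i]]])
      data.frame(grid[i, ], rho = sp$rho, p_value = sp$p_value,
                 row.names = NULL)
    }))
  })

  # method agreement: two backends, and three methods including IRS
  try_table("agreement", {
    do.call(rbind, lapply(c("pas", "ab"), function(s) {
      do.call(rbind, lapply(c("tumor", "control"), function(g) {
        two <- cbind(acol(s, g, "hsv"), acol(s, g, "smart"))
        a2 <- cronbach_alpha(two)
        irs_col <- cohort[[paste0("irs_", s, "_", g)]]
        a3 <- if (!is.null(irs_col)) {
          tryCatch(cronbach_alpha(cbind(two, irs_col * 100 / 12)),
                   error = function(e) NA_real_)
        } else NA_real_
        data.frame(stain = s, group = g, alpha_backends = a2,
                   alpha_three_methods = a3)
      }))
    }))
  })

  # survival by below/above mean tumor expression (smart backend)
  try_table("km_test", {
    if (!all(c("survival_months", "event") %in% names(cohort))) {
      stop("missing survival columns")
    }
    do.call(rbind, lapply(c("pas", "ab"), function(s) {
      a <- acol(s, "tumor", "smart")
      grp <- ifelse(a > mean(a), "high", "low")
      if (length(unique(grp)) < 2L) stop("mean split yields one group")
      kr <- km_logrank(cohort$survival_months, cohort$event, grp)
      data.frame(stain = s, chi_square = kr$chi_square, p_value = kr$p_value,
                 n_low = sum(grp == "low"), n_high = sum(grp == "high"),
                 events = sum(cohort$event))
    }))
  })
  try_table("km_curves", {
    if (!all(c("survival_months", "event") %in% names(cohort))) {
      stop("missing survival columns")
    }
    do.call(rbind, lapply(c("pas", "ab"), function(s) {
      a <- acol(s, "tumor", "smart")
      grp <- ifelse(a > mean(a), "high", "low")
      if (length(unique(grp)) < 2L) stop("mean split yields one group")
      kr <- km_logrank(cohort$survival_months, cohort$event, grp)
      do.call(rbind, lapply(names(kr$curves), function(g) {
        cv <- kr$curves[[g]]
        if (nrow(cv) == 0L) return(NULL)
        data.frame(stain = s, expression = g, cv)
      }))
    }))
  })

  list(tables = tables, skipped = skipped)
}
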