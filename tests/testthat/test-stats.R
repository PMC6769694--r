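test_that("cronbach_alpha hits the analytic endpoints", {
  x <- c(3, 1, 4, 1, 5)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)
  # equal-variance columns with exactly zero inter-item covariance -> 0
  a <- c(1, 1, -1, -1)
  b <- c(1, -1, 1, -1)
  expect_equal(cronbach_alpha(cbind(a, b)), 0)
  expect_error(cronbach_alpha(matrix(5, 4, 3)), "zero")
  expect_error(cronbach_alpha(matrix(1:4, 2, 2)), "3 slide rows")
})

test_that("cronbach_alpha matches the direct covariance-matrix oracle", {
  m <- matrix(c(4, 5, 3, 6, 5,
                3, 5, 4, 6, 6,
                5, 6, 2, 7, 4), 5, 3)
  expect_equal(cronbach_alpha(m), oracle_cronbach(m))
  set.seed(71)
  for (i in 1:10) {
    x <- matrix(rnorm(8 * 4), 8, 4)
    expect_equal(cronbach_alpha(x), oracle_cronbach(x))
  }
})

test_that("adding a duplicated column never lowers alpha for exchangeable raters", {
  # true for exchangeable items (equal variances, equal non-negative
  # covariances) -- the regime of parallel scoring methods; NOT a theorem
  # for arbitrary matrices, where sampled counterexamples exist.
  # Construct data whose sample covariance is exactly compound symmetric.
  set.seed(5)
  for (k in 2:4) {
    for (rho in c(0, 0.3, 0.6, 0.9)) {
      n <- 10
      x0 <- scale(matrix(rnorm(n * k), n, k), scale = FALSE)
      z <- x0 %*% solve(chol(cov(x0)))  # sample cov exactly identity
      cs <- matrix(rho, k, k); diag(cs) <- 1
      x <- z %*% chol(cs)               # sample cov exactly cs
      a0 <- cronbach_alpha(x)
      for (j in seq_len(k)) {
        expect_gte(cronbach_alpha(cbind(x, x[, j])), a0 - 1e-12)
      }
    }
  }
})

test_that("spearman_rho recovers perfect monotone association", {
  x <- c(2, 9, 4, 7, 1, 5)
  expect_equal(spearman_rho(x, x^3)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("spearman exact p matches full permutation enumeration, ties included", {
  x <- c(1, 2, 2, 3, 4, 5, 5)
  y <- c(2, 1, 4, 3, 6, 5, 7)
  got <- spearman_rho(x, y)
  ora <- oracle_spearman(x, y)
  expect_equal(got$method, "exact permutation")
  expect_equal(got$rho, ora$rho)
  expect_equal(got$p_value, ora$p)
  x2 <- c(3, 1, 4, 1, 5, 9)
  y2 <- c(2, 7, 1, 8, 2, 8)
  expect_equal(spearman_rho(x2, y2)$p_value, oracle_spearman(x2, y2)$p)
})

test_that("spearman t approximation agrees with cor.test beyond the exact range", {
  set.seed(31)
  x <- rnorm(30)
  y <- 0.4 * x + rnorm(30)
  got <- spearman_rho(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(got$method, "t approximation")
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("wilcoxon_paired hits the extremes and degenerate input", {
  tumor <- c(3, 8, 5, 11, 7, 2)
  control <- tumor + 4
  w <- wilcoxon_paired(tumor, control)
  expect_equal(w$statistic, 0)  # every difference negative
  expect_equal(w$p_value, 2 / 2^6)
  expect_error(wilcoxon_paired(tumor, tumor), "degenerate")
})

test_that("wilcoxon exact p matches the 2^n sign-flip oracle, ties and zeros included", {
  x <- c(10, 7, 5, 9, 12, 4)
  y <- c(6, 8, 5.5, 3, 6, 8)
  got <- wilcoxon_paired(x, y)
  ora <- oracle_wilcoxon(x, y)
  expect_equal(got$method, "exact enumeration")
  expect_equal(got$statistic, ora$v)
  expect_equal(got$p_value, ora$p)
  # tied absolute differences and a zero difference
  x2 <- c(5, 5, 9, 2, 7, 1, 3)
  y2 <- c(3, 7, 9, 4, 4, 2, 1)
  got2 <- wilcoxon_paired(x2, y2)
  ora2 <- oracle_wilcoxon(x2, y2)
  expect_equal(got2$n_zero, 1)
  expect_equal(got2$statistic, ora2$v)
  expect_equal(got2$p_value, ora2$p)
})

test_that("wilcoxon normal branch matches wilcox.test with continuity correction", {
  set.seed(9)
  x <- rnorm(25, 1)
  y <- rnorm(25)
  got <- wilcoxon_paired(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(got$method, "normal approximation")
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("mann_whitney statistic and exact p behave as enumerated", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1)  # 2 of the C(6,3) = 20 assignments
  same <- c(2, 5, 9, 2)
  expect_equal(mann_whitney(same, same)$statistic, length(same)^2 / 2)
  expect_error(mann_whitney(1:2, 1:5), "at least 3")
})

test_that("mann_whitney exact p matches the assignment-enumeration oracle", {
  a <- c(12, 5, 9, 14, 5)
  b <- c(8, 5, 3, 10, 2, 6, 1)
  got <- mann_whitney(a, b)
  ora <- oracle_mann_whitney(a, b)
  expect_equal(got$method, "exact enumeration")
  expect_equal(got$statistic, ora$u)
  expect_equal(got$p_value, ora$p)
})

test_that("mann_whitney normal branch matches wilcox.test", {
  set.seed(17)
  a <- rnorm(12, 0.8)
  b <- rnorm(15)
  got <- mann_whitney(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$method, "normal approximation")
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("split_by_mean sends ties at the mean to the low group", {
  sp <- split_by_mean(c(1, 2, 3, 4))
  expect_equal(sp$low, c(1, 2))
  expect_equal(sp$high, c(3, 4))
  sp2 <- split_by_mean(c(1, 2, 3))  # 2 equals the mean
  expect_equal(sp2$low, c(1, 2))
  expect_warning(sp3 <- split_by_mean(rep(7, 4)), "empty")
  expect_length(sp3$high, 0)
})

test_that("Kaplan-Meier product-limit matches the hand computation", {
  cv <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(cv$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(cv$n_risk, c(3, 2, 1))
  # censoring: risk set shrinks without a survival step
  cv2 <- km_curve(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(cv2$survival, c(3 / 4, 3 / 4 * 1 / 2))
})

test_that("km curves are non-increasing step functions from 1 and identical groups give chi-square 0", {
  set.seed(23)
  times <- rexp(20, 0.1)
  events <- rbinom(20, 1, 0.7)
  cv <- km_curve(times, events)
  expect_true(all(diff(cv$survival) <= 1e-12))
  expect_lte(cv$survival[1], 1)
  kr <- km_logrank(c(times, times), c(events, events),
                   rep(c("a", "b"), each = 20))
  expect_equal(kr$chi_square, 0)
  expect_error(km_logrank(times, events, rep("a", 20)), "two groups")
})

test_that("km_logrank agrees with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(41)
  for (i in 1:5) {
    n <- 40
    times <- round(rexp(n, 0.05), 2)
    events <- rbinom(n, 1, 0.6)
    groups <- rep(c("a", "b"), each = n / 2)
    got <- km_logrank(times, events, groups)
    ref <- survival::survdiff(survival::Surv(times, events) ~ groups)
    expect_equal(got$chi_square, unname(ref$chisq), tolerance = 1e-8)
    fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                             subset = groups == "a")
    ev <- summary(fit, times = got$curves$a$time)
    expect_equal(got$curves$a$survival, ev$surv, tolerance = 1e-8)
  }
})

test_that("cohort_report produces the full table set on a healthy cohort", {
  co <- generate_cohort(cohort_spec(seed = 6))
  rep <- suppressWarnings(cohort_report(co))
  expect_setequal(
    names(rep$tables),
    c("expression", "mucinous", "macro_type", "localization", "grade",
      "stage", "correlations", "agreement", "km_curves", "km_test"))
  expect_equal(nrow(rep$tables$expression), 4)
  expect_true(all(rep$tables$expression$p_value < 0.05))  # built-in shift
  expect_equal(nrow(rep$tables$correlations), 40)
})

test_that("a single-patient cohort skips every comparative table without crashing", {
  co <- generate_cohort(cohort_spec(n_patients = 1, seed = 3))
  expect_warning(rep <- cohort_report(co), "skipped")
  expect_gt(length(rep$skipped), 5)
  expect_true(all(vapply(rep$tables[rep$skipped], is.null, logical(1))))
})
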