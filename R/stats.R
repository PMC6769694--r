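#' Cronbach's alpha for inter-method consistency
#'
#' Measures agreement between scoring methods (e.g. the two segmentation
#' backends, or backends plus the IRS scale) applied to the same slides:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))` with sample
#' variances, where rows are slides and columns are methods.
#'
#' @param x numeric matrix, at least 3 rows (slides) and 2 columns
#'   (methods), no missing cells.
#' @return Scalar alpha (at most 1; can be negative).
#' @examples
#' m <- cbind(1:5, c(1.1, 2, 2.9, 4.2, 5))
#' cronbach_alpha(m)
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  if (anyNA(x)) stop("missing cells are not allowed")
  k <- ncol(x)
  if (k < 2L || nrow(x) < 3L) {
    stop("need at least 2 method columns and 3 slide rows")
  }
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) {
    stop("total score variance is zero; alpha is undefined")
  }
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
}

# All permutations of 1..n as an n! x n integer matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Spearman rank correlation with exact small-sample p
#'
#' Midranks are used for ties. For `n <= exact_max` (default 8) the
#' two-sided p-value is exact, by enumerating all `n!` permutations of one
#' rank vector (valid under ties, conditional on the observed tie pattern);
#' beyond that the usual t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df is used.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`.
#' @param exact_max largest n for which the permutation-exact p is computed.
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @examples
#' spearman_rho(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman_rho <- function(x, y, exact_max = 8L) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("constant input: correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Tests a location shift between paired measurements (e.g. tumor vs paired
#' control A%). Zero differences are dropped; tied absolute differences get
#' midranks. The statistic `V` is the sum of ranks of positive differences.
#' For at most `exact_max` (default 15) non-zero pairs the two-sided p-value
#' is exact by full enumeration of the `2^n` sign assignments (valid with
#' ties); otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param x,y equal-length paired numeric vectors.
#' @param exact_max largest number of non-zero pairs for the exact branch.
#' @return List with `statistic` (V), `p_value`, `n_used`, `n_zero`,
#'   `method`.
#' @examples
#' wilcoxon_paired(c(5, 7, 3, 9, 8, 6), c(2, 4, 4, 5, 3, 1))
#' @export
wilcoxon_paired <- function(x, y, exact_max = 15L) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate input: all paired differences are zero")
  if (n < 5L) {
    warning("fewer than 5 non-zero differences; the test has little power")
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_max) {
    # distribution of V over all 2^n sign assignments, by convolution on
    # doubled ranks (midranks are multiples of 1/2, so 2r is integer)
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1L)  # index s+1 holds #assignments with 2V = s
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    s <- seq_along(counts) - 1L
    dev <- abs(s - 2 * mu)
    p <- sum(counts[dev >= abs(2 * v - 2 * mu) - 1e-9]) / 2^n
    method <- "exact enumeration"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (abs(v - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n_used = n, n_zero = n_zero,
       method = method)
}

#' Mann-Whitney U test for two independent groups
#'
#' Compares an unpaired quantity between two groups (e.g. mucinous vs
#' nonmucinous tumors). `U` counts pairs in which a group-`a` value exceeds
#' a group-`b` value, with ties contributing 1/2 (computed via midranks).
#' When `length(a) + length(b) <= exact_max_total` (default 12) the
#' two-sided p-value is exact, by enumerating all group assignments of the
#' pooled values; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b numeric vectors, each with at least 3 values.
#' @param exact_max_total largest pooled size for the exact branch.
#' @return List with `statistic` (U for group `a`), `p_value`, `n_a`, `n_b`,
#'   `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 exactly
#' @export
mann_whitney <- function(a, b, exact_max_total = 12L) {
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed")
  na <- length(a)
  nb <- length(b)
  if (na < 3L || nb < 3L) stop("each group needs at least 3 values")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  n <- na + nb
  if (n <= exact_max_total) {
    combos <- utils::combn(n, na)
    us <- apply(combos, 2, function(idx) {
      sum(r[idx]) - na * (na + 1) / 2
    })
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - tie_term))
    if (sigma == 0) stop("all pooled values tied; test undefined")
    z <- (abs(u - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(statistic = u, p_value = p, n_a = na, n_b = nb, method = method)
}

#' Split values into below/above-mean expression groups
#'
#' The grouping used for survival contrasts: `low` holds values at or below
#' the arithmetic mean, `high` holds values strictly above it (ties at the
#' mean go low). If all values are equal the high group is empty and a
#' warning is raised.
#'
#' @param values numeric vector, `n >= 2`.
#' @return List with `low_idx`, `high_idx`, `low`, `high`, `mean`.
#' @examples
#' split_by_mean(c(1, 2, 3, 4))
#' @export
split_by_mean <- function(values) {
  if (length(values) < 2L) stop("need n >= 2")
  if (anyNA(values)) stop("missing values are not allowed")
  m <- mean(values)
  low_idx <- which(values <= m)
  high_idx <- which(values > m)
  if (length(high_idx) == 0L) {
    warning("all values equal the mean; high-expression group is empty")
  }
  list(low_idx = low_idx, high_idx = high_idx,
       low = values[low_idx], high = values[high_idx], mean = m)
}

#' Kaplan-Meier product-limit curve for one group
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators (1 = death/event, 0 = censored).
#' @return Data frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `survival` (the product-limit estimate just after
#'   `time`). Curves start at survival 1 and are non-increasing.
#' @export
km_curve <- function(times, events) {
  if (length(times) != length(events)) stop("lengths differ")
  if (any(times < 0)) stop("times must be non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  ts <- sort(unique(times[events == 1]))
  surv <- 1
  out <- data.frame(time = numeric(0), n_risk = integer(0),
                    n_event = integer(0), survival = numeric(0))
  for (t in ts) {
    n_risk <- sum(times >= t)
    n_event <- sum(times == t & events == 1)
    surv <- surv * (1 - n_event / n_risk)
    out <- rbind(out, data.frame(time = t, n_risk = n_risk,
                                 n_event = n_event, survival = surv))
  }
  out
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit estimator per group with right-censoring honored, and the
#' two-group log-rank chi-square computed on the pooled risk sets (1 df).
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @param groups vector of two group labels, both non-empty.
#' @return List with `curves` (named list of per-group [km_curve()] data
#'   frames), `chi_square`, `p_value`, `observed`, `expected`.
#' @examples
#' km_logrank(c(2, 4, 6, 1, 3, 5), c(1, 1, 0, 1, 1, 1),
#'            rep(c("a", "b"), each = 3))
#' @export
km_logrank <- function(times, events, groups) {
  if (length(times) != length(events) || length(times) != length(groups)) {
    stop("'times', 'events' and 'groups' must have equal length")
  }
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (any(table(g) == 0L)) stop("each group must contain at least one subject")
  if (any(times < 0)) stop("times must be non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  lv <- levels(g)
  curves <- lapply(lv, function(l) km_curve(times[g == l], events[g == l]))
  names(curves) <- lv
  ts <- sort(unique(times[events == 1]))
  o1 <- e1 <- v1 <- 0
  for (t in ts) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & g == lv[1])
    d_t <- sum(times == t & events == 1)
    d1_t <- sum(times == t & events == 1 & g == lv[1])
    o1 <- o1 + d1_t
    e1 <- e1 + d_t * n1_t / n_t
    if (n_t > 1) {
      v1 <- v1 + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  chi <- if (v1 > 0) (o1 - e1)^2 / v1 else 0
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  list(curves = curves, chi_square = chi, p_value = p,
       observed = o1, expected = e1)
}
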