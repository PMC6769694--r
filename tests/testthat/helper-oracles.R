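# Brute-force oracles, written independently of the package internals.

# all permutations of 1..n (recursive; oracle-side implementation)
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(seq_len(n)[-i][sub], nrow(sub)))
  }))
}

# Cronbach's alpha via the covariance matrix: k/(k-1) * (1 - tr(C)/sum(C))
oracle_cronbach <- function(x) {
  C <- stats::cov(x)
  k <- ncol(x)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# exact two-sided Spearman p by enumerating all n! pairings
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  perms <- oracle_perms(length(x))
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- sum(r) / 2
  vs <- vapply(0:(2^n - 1), function(bits) {
    keep <- bitwAnd(bits, 2^(0:(n - 1))) > 0
    sum(r[keep])
  }, numeric(1))
  list(v = v, p = mean(abs(vs - mu) >= abs(v - mu) - 1e-9))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mann_whitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  us <- utils::combn(na + nb, na, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  list(u = u, p = mean(abs(us - mu) >= abs(u - mu) - 1e-9))
}

# tiny solid-color test image: n1 reaction pixels, n2 counterstain, n3 glass
patch_image <- function(n1, n2, n3, reaction = c(190, 30, 130),
                        counterstain = c(110, 95, 170),
                        glass = c(250, 248, 251)) {
  n <- n1 + n2 + n3
  h <- 1L
  px <- array(0L, c(h, n, 3))
  one <- function(color, k) {
    if (k == 0) matrix(numeric(0), 0, 3) else matrix(color, k, 3, byrow = TRUE)
  }
  cols <- rbind(one(reaction, n1), one(counterstain, n2), one(glass, n3))
  for (ch in 1:3) px[1, , ch] <- cols[, ch]
  rgb_image(px)
}

# default-color classifier seeds (one pure color per class, PAS palette)
pure_seed_list <- function() {
  list(reaction = matrix(c(190, 30, 130), 1),
       tissue = matrix(c(110, 95, 170), 1),
       background = matrix(c(250, 248, 251), 1))
}

# null-effect cohort spec used by calibration tests
null_cohort_spec <- function(seed) {
  cohort_spec(
    pas_tumor_mean = 61.6, pas_tumor_sd = 15.9,
    ab_tumor_mean = 55.8, ab_tumor_sd = 13.5,
    mucinous_ab_shift = 0, flat_pas_shift = 0,
    control_pas_ab_rho = 0, control_ab_hb_rho = 0,
    control_pas_glucose_rho = 0, hazard_ratio = 1, seed = seed)
}
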