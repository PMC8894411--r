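# Shared oracles and generators, independent of the implementation paths they
# check.

d2r <- function(x) x * pi / 180
r2d <- function(x) x * 180 / pi

# Random medially pointing unit axes away from the degenerate guards:
# ci uniform in (1, 89), tv uniform in (-80, 80).
random_axes <- function(n, seed = 1) {
  withr::with_seed(seed, {
    ci <- runif(n, 1, 89)
    tv <- runif(n, -80, 80)
  })
  v <- cbind(1, tan(d2r(tv)), tan(d2r(ci)))
  v / sqrt(rowSums(v^2))
}

# Rodrigues rotation matrix about a unit axis by an angle in degrees.
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- d2r(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    ax <- rnorm(3)
    ang <- runif(1, -180, 180)
  })
  rotation_matrix(ax, ang)
}

# Brute-force projection oracle: the three angles read directly off the
# projections of a component-vector, no shared code with the package.
oracle_angles <- function(v) {
  c(ci = r2d(atan2(v[3], v[1])),
    si = r2d(atan2(v[2], v[3])),
    tv = r2d(atan2(v[2], v[1])))
}

# ICC(A,1) oracle via stats::aov mean squares (independent ANOVA route).
oracle_icc_a1 <- function(m) {
  long <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(stats::aov(y ~ subject + rater, data = long))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Explicit sums-of-squares ICC(A,1), written out from first principles.
oracle_icc_sums <- function(m) {
  n <- nrow(m); k <- ncol(m); g <- mean(m)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - g)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - g)^2
  sst <- sum((m - g)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Interpolated percentile written out from first principles (R type 7):
# h = (n - 1) p + 1; value = x[floor(h)] + (h - floor(h)) (x[floor(h)+1] - x[floor(h)]).
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Truncated-normal mean/sd by numerical integration, independent of the
# closed-form helper inside the package.
oracle_truncnorm_moments <- function(mean, sd, lo, hi) {
  mass <- stats::integrate(function(x) dnorm(x, mean, sd), lo, hi)$value
  m1 <- stats::integrate(function(x) x * dnorm(x, mean, sd), lo, hi)$value / mass
  m2 <- stats::integrate(function(x) x^2 * dnorm(x, mean, sd), lo, hi)$value / mass
  list(mean = m1, sd = sqrt(m2 - m1^2))
}
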