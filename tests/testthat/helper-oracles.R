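# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain normal equations, exhaustive scans, and a
# cubic-solve Hermite evaluation.

# OLS via explicit normal equations.
ols_oracle <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% beta
  list(beta = drop(beta), rss = sum(r^2), residuals = drop(r))
}

# Residual sum of squares of the continuous piecewise model at fixed psi,
# computed with base .lm.fit on a design built here.
rss_oracle <- function(x, y, psi) {
  X <- cbind(1, x)
  for (p in psi) X <- cbind(X, pmax(x - p, 0))
  f <- .lm.fit(X, y)
  sum(f$residuals^2)
}

# Exhaustive profile-RSS scan over a fine grid (1 breakpoint).
scan_1bp_oracle <- function(x, y, lo, hi, step = 0.01) {
  grid <- seq(lo, hi, by = step)
  min(vapply(grid, function(p) rss_oracle(x, y, p), numeric(1)))
}

# Exhaustive scan over a fine 2-D grid (2 breakpoints).
scan_2bp_oracle <- function(x, y, b1, b2, step = 0.01) {
  g1 <- seq(b1[1], b1[2], by = step)
  g2 <- seq(b2[1], b2[2], by = step)
  best <- Inf
  for (p1 in g1) {
    for (p2 in g2) {
      if (p2 <= p1) next
      r <- rss_oracle(x, y, c(p1, p2))
      if (r < best) best <- r
    }
  }
  best
}

# Cubic Hermite interpolation on [t0, t1] with given endpoint values and
# tangents, evaluated by solving for the monomial coefficients directly.
hermite_oracle <- function(t0, t1, v0, v1, m0, m1, t) {
  A <- rbind(c(1, t0, t0^2, t0^3),
             c(1, t1, t1^2, t1^3),
             c(0, 1, 2 * t0, 3 * t0^2),
             c(0, 1, 2 * t1, 3 * t1^2))
  cc <- solve(A, c(v0, v1, m0, m1))
  drop(cbind(1, t, t^2, t^3) %*% cc)
}

# Pooled-variance two-sample t statistic from the textbook formula.
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Build a resp_trace by hand (for drift-correction tests).
make_trace <- function(time_s, o2, wvp, segment_id, is_baseline,
                       FiO2 = 0.2095, incurrent_wvp = 0.2,
                       flow_rate = 1000, BP = 101, tau = 234) {
  structure(
    data.frame(time_s = time_s, o2_frac = o2, wvp_kpa = wvp,
               segment_id = segment_id, is_baseline = is_baseline),
    id = "test", Ta = 25, flow_rate = flow_rate,
    barometric_pressure = BP, FiO2 = FiO2, incurrent_wvp = incurrent_wvp,
    tau = tau, washout_limited = FALSE,
    class = c("resp_trace", "data.frame")
  )
}

# Noise-free piecewise profile values from the generator's stated formulas.
piecewise_vo2 <- function(Ta, BMR, Tlc, Tuc, cold_slope, hot_slope) {
  BMR + cold_slope * pmin(Ta - Tlc, 0) + hot_slope * pmax(Ta - Tuc, 0)
}
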