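# Independent oracles. These deliberately avoid the package's code paths:
# the arc length is computed by composite Simpson on the explicit integrand,
# polylines by direct chord summation, the ANOVA table by brute force.

# one-sided arc length of y = (L/W^3) x^3 - L on [0, W], composite Simpson
simpson_half_length <- function(L, W, n = 1e4) {
  f <- function(x) sqrt(1 + 9 * L^2 / W^6 * x^4)
  h <- W / n
  y <- f(seq(0, W, length.out = n + 1))
  h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, 2)]) +
             2 * sum(y[seq(3, n - 1, 2)]))
}

# chord-sum length of n_pts equal-x points on the model curve
chord_sum_length <- function(L, W, n_pts) {
  x <- seq(0, W, length.out = n_pts)
  y <- L / W^3 * x^3 - L
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# brute-force two-way ANOVA mean squares for an ICC(A,1) oracle
anova_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m); grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sse <- sum((m - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
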