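test_that("descriptive summary uses sample SD and the t-based CI", {
  s <- descriptive_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$min, 1)
  expect_equal(s$max, 3)
  expect_equal(s$ci_low, 2 - stats::qt(0.975, 2) / sqrt(3), tolerance = 1e-10)
  expect_equal(s$ci_high, 2 + stats::qt(0.975, 2) / sqrt(3), tolerance = 1e-10)
  const <- descriptive_summary(rep(5, 4))
  expect_equal(const$sd, 0)
  expect_equal(c(const$ci_low, const$ci_high), c(5, 5))
  expect_error(descriptive_summary(7), "insufficient")
  expect_error(descriptive_summary(c(1, NA)), "missing")
})

test_that("Lin's CCC matches the moment definition and its frozen toy value", {
  x <- c(2, 4, 7, 9)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4))$ccc, 4 / 7, tolerance = 1e-12)
  z <- c(-2, 0, 2)
  expect_equal(lin_ccc(z, -z)$ccc, -1)
  # independent moment oracle on arbitrary data
  set.seed(8)
  a <- rnorm(40, 20, 2); b <- a + rnorm(40, 0.3, 0.7)
  sxy <- mean((a - mean(a)) * (b - mean(b)))
  oracle <- 2 * sxy / (mean((a - mean(a))^2) + mean((b - mean(b))^2) +
                         (mean(a) - mean(b))^2)
  res <- lin_ccc(a, b)
  expect_equal(res$ccc, oracle, tolerance = 1e-12)
  # CI brackets the point estimate
  expect_true(res$ci_low < res$ccc && res$ccc < res$ci_high)
  expect_error(lin_ccc(rep(1, 3), rep(1, 3)), "undefined")
  expect_error(lin_ccc(1:3, 1:4), "equal length")
})

test_that("CCC is symmetric and bounded by the Pearson correlation", {
  set.seed(21)
  x <- rnorm(30, 50, 5)
  y <- 0.9 * x + rnorm(30, 6, 2)
  expect_equal(lin_ccc(x, y)$ccc, lin_ccc(y, x)$ccc, tolerance = 1e-12)
  expect_lte(abs(lin_ccc(x, y)$ccc), abs(cor(x, y)) + 1e-12)
})

test_that("ICC(A,1) reproduces the brute-force ANOVA oracle", {
  m <- cbind(c(10, 20, 30), c(11, 21, 31))
  res <- icc(m)
  expect_equal(res$icc, anova_icc_a1(m), tolerance = 1e-12)
  expect_equal(res$icc, 0.995025, tolerance = 1e-5) # frozen oracle value
  expect_gt(res$icc, 0.9)
  expect_lt(res$icc, 1)
  # identical columns give exactly 1
  expect_equal(icc(cbind(c(1, 5, 9), c(1, 5, 9)))$icc, 1)
  # shift invariance: adding a constant to every cell changes nothing
  set.seed(3)
  r <- matrix(rnorm(60, 20, 3), ncol = 3)
  expect_equal(icc(r)$icc, icc(r + 100)$icc, tolerance = 1e-9)
  expect_error(icc(cbind(c(1, NA), c(2, 3))), "incomplete")
  expect_error(icc(matrix(1:3, ncol = 1)), ">= 2")
})

test_that("ICC of pure noise around a common mean is near zero, unclamped", {
  set.seed(77)
  noise <- matrix(rnorm(400, 10, 1), ncol = 2)
  v <- icc(noise)$icc
  expect_lt(abs(v), 0.2)
  # degenerate matrix dominated by within-subject disagreement goes
  # negative and is reported as computed
  deg <- cbind(c(10, 11, 10), c(11, 10, 10))
  expect_lt(icc(deg)$icc, 0)
})

test_that("Bland-Altman differences, LoA and points follow the definition", {
  ba <- bland_altman(c(10, 12), c(11, 11))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_low, -1.96 * sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$points$diff, c(-1, 1))
  expect_equal(ba$points$mean, c(10.5, 11.5))
  # constant offset: measured = x, calculated = x + 1
  x <- c(3, 7, 9)
  off <- bland_altman(x, x + 1)
  expect_equal(off$mean_diff, -1)
  expect_equal(off$sd_diff, 0)
  expect_equal(c(off$loa_low, off$loa_high), c(-1, -1))
  ident <- bland_altman(x, x)
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$sd_diff, 0)
  # LoA reconstruction identity
  set.seed(14)
  a <- rnorm(25, 50, 4); b <- a + rnorm(25, 0, 0.5)
  r <- bland_altman(a, b)
  expect_equal(r$loa_high - r$loa_low, 2 * 1.96 * r$sd_diff, tolerance = 1e-12)
})

test_that("absolute-difference summary is symmetric and drops signs", {
  x <- c(1, 2, 3); y <- c(1.5, 2, 2.5)
  s <- absolute_difference_summary(x, y)
  expect_equal(s$mean, 1 / 3, tolerance = 1e-12)
  expect_equal(s$sd, stats::sd(c(0.5, 0, 0.5)), tolerance = 1e-12)
  expect_equal(s, absolute_difference_summary(y, x))
  same <- absolute_difference_summary(x, x)
  expect_equal(c(same$mean, same$sd, same$min, same$max), c(0, 0, 0, 0))
  d <- absolute_difference_summary(c(0, 2), c(1, 1)) # diffs -1, +1
  expect_equal(d$mean, 1)
  expect_equal(d$sd, 0)
})

test_that("a noise-free cohort validates the model against itself", {
  co <- generate_cohort(cohort_spec(n = 12, noise_sd = 0, n_points = 400),
                        seed = 6)
  rep <- validate_cohort(co, "T0", "upper")
  for (s in c("right", "left", "total")) {
    expect_gt(rep[[s]]$ccc$ccc, 0.999)
  }
  # per side, only the chord shortfall separates measured from calculated
  for (s in c("right", "left")) {
    expect_lt(rep[[s]]$abs_diff$max /
                rep[[s]]$descriptives$calculated$mean, 5e-4)
  }
  # the total additionally carries the side-averaging approximation
  # (calculated from mean depth and summed width of a symmetric arch,
  # measured as the sum of two asymmetric sides), so it is looser
  expect_lt(rep$total$abs_diff$max /
              rep$total$descriptives$calculated$mean, 5e-3)
})

test_that("validation with default noise reaches high concordance", {
  co <- generate_cohort(cohort_spec(n = 50), seed = 17)
  rep <- validate_cohort(co, "T0", "upper")
  expect_gt(rep$total$ccc$ccc, 0.95)
  expect_s3_class(rep, "agreement_report")
  tab <- report_table(rep)
  expect_setequal(unique(tab$series), c("right", "left", "total"))
  expect_equal(tab$value[tab$series == "total" & tab$statistic == "ccc"],
               rep$total$ccc$ccc)
})

test_that("agreement improves monotonically as measurement noise vanishes", {
  cccs <- vapply(c(0.4, 0.2, 0.1, 0), function(sd) {
    co <- generate_cohort(cohort_spec(n = 40, noise_sd = sd), seed = 200)
    validate_cohort(co, "T0", "upper")$total$ccc$ccc
  }, numeric(1))
  expect_true(all(diff(cccs) > 0))
  expect_gt(cccs[4], 0.999)
})

test_that("empty or missing strata are reported as errors", {
  co <- generate_cohort(cohort_spec(n = 3), seed = 5)
  only_upper <- co[co$jaw == "upper", ]
  expect_error(validate_cohort(only_upper, "T0", "lower"), "empty stratum")
  expect_error(validate_cohort(co[, setdiff(names(co), "AL_meas")],
                               "T0", "upper"), "lacks column")
})

test_that("Bland-Altman plot builds from a report", {
  co <- generate_cohort(cohort_spec(n = 5), seed = 9)
  rep <- validate_cohort(co, "T1", "lower")
  p <- plot_bland_altman(rep$total$bland_altman, title = "lower T1")
  expect_s3_class(p, "ggplot")
})
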