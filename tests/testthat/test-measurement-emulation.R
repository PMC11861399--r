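test_that("sampled reference points lie on the model curve", {
  arch <- arch_geometry(L = 13.9, W = 18.2)
  poly <- sample_arch_points(arch, n_points = 13)
  expect_equal(nrow(poly), 13)
  expect_true(all(diff(poly$x) > 0))
  expect_equal(poly$x[1], 0)
  expect_equal(poly$x[13], 18.2)
  expect_equal(poly$y, 13.9 / 18.2^3 * poly$x^3 - 13.9, tolerance = 1e-12)
  # random placement reproducible under seed, endpoints pinned
  p1 <- sample_arch_points(arch, 13, spacing = "random", seed = 11)
  p2 <- sample_arch_points(arch, 13, spacing = "random", seed = 11)
  expect_identical(p1, p2)
  expect_equal(range(p1$x), c(0, 18.2))
  expect_error(sample_arch_points(arch, 1), ">= 2")
})

test_that("polyline length reduces to the chord and to W in edge cases", {
  arch <- arch_geometry(L = 13.9, W = 18.2)
  two <- sample_arch_points(arch, 2)
  expect_equal(polyline_length(two), sqrt(18.2^2 + 13.9^2))
  flat <- sample_arch_points(arch_geometry(L = 0, W = 12), 9)
  expect_equal(polyline_length(flat), 12)
  # 13 equal-x points: frozen chord-sum oracle, short of the arc length
  poly13 <- sample_arch_points(arch, 13)
  expect_equal(polyline_length(poly13), 24.815433, tolerance = 1e-6)
})

test_that("chord sums stay below the arc length and converge at O(n^-2)", {
  arch <- arch_geometry(L = 13.9, W = 18.2)
  al_half <- half_arch_length(arch)
  ns <- c(4, 8, 16, 32, 64)
  err <- vapply(ns, function(n) {
    al_half - polyline_length(sample_arch_points(arch, n + 1))
  }, numeric(1))
  expect_true(all(err > 0))
  # 12 subsections already within 0.1% of the true length
  expect_lt((al_half - polyline_length(sample_arch_points(arch, 13))) /
              al_half, 0.001)
  slope <- unname(coef(stats::lm(log(err) ~ log(ns)))[2])
  expect_gt(slope, -2.3)
  expect_lt(slope, -1.7)
})

test_that("subsection deviation is zero at the reference and shrinks towards it", {
  arch <- arch_geometry(L = 13.9, W = 18.2)
  expect_equal(subsection_deviation(arch, n_sub = 14), 0)
  d12 <- subsection_deviation(arch, n_sub = 12)
  d10 <- subsection_deviation(arch, n_sub = 10)
  expect_equal(d12, 0.0115, tolerance = 1e-2) # frozen chord-sum oracle, %
  expect_true(d10 >= d12 && d12 >= 0)
  expect_error(subsection_deviation(arch, n_sub = 1), ">= 2")
  expect_error(subsection_deviation(arch, n_sub = 14, reference_n = 12),
               "reference_n")
})

test_that("measurement noise is additive, zero-mean and stream-reproducible", {
  expect_identical(measure_with_noise(24.8, sd = 0), 24.8)
  expect_error(measure_with_noise(24.8, sd = -0.1), ">= 0")
  a <- withr::with_seed(5, measure_with_noise(24.8, 0.2))
  b <- withr::with_seed(5, measure_with_noise(24.8, 0.2))
  expect_identical(a, b)
  draws <- withr::with_seed(99, measure_with_noise(rep(10, 1e4), 0.2)) - 10
  # chi-square bound on the sample SD at n = 1e4
  expect_gt(stats::sd(draws), 0.19)
  expect_lt(stats::sd(draws), 0.21)
})

test_that("cohort spec validates its inputs", {
  expect_error(cohort_spec(n = 0), "n must be >= 1")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  bad <- tibble::tibble(jaw = "upper", timepoint = "T0", side = "right",
                        variable = "L", mean = 5, sd = 1, min = 6, max = 4)
  expect_error(cohort_spec(anatomy = bad), "infeasible")
})

test_that("cohorts are reproducible and respect the anatomy ranges", {
  spec <- cohort_spec(n = 6)
  c1 <- generate_cohort(spec, seed = 123)
  c2 <- generate_cohort(spec, seed = 123)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 6 * 2 * 2 * 2) # patients x jaws x sides x timepoints
  # truncation bounds hold for the true values
  chk <- merge(as.data.frame(c1),
               as.data.frame(cohort_spec(n = 1)$anatomy),
               by = c("jaw", "timepoint", "side"))
  L_rows <- chk[chk$variable == "L", ]
  W_rows <- chk[chk$variable == "W", ]
  expect_true(all(L_rows$L_true >= L_rows$min & L_rows$L_true <= L_rows$max))
  expect_true(all(W_rows$W_true >= W_rows$min & W_rows$W_true <= W_rows$max))
  # true AL matches the model for every row
  al <- vapply(seq_len(nrow(c1)), function(i) {
    half_arch_length(arch_geometry(c1$L_true[i], c1$W_true[i]))
  }, numeric(1))
  expect_equal(c1$AL_true, al)
})

test_that("noise-free cohorts measure the model almost exactly", {
  spec <- cohort_spec(n = 4, noise_sd = 0, n_points = 200)
  co <- generate_cohort(spec, seed = 1)
  expect_identical(co$L_meas, co$L_true)
  expect_identical(co$W_meas, co$W_true)
  expect_true(all(abs(co$AL_meas - co$AL_true) / co$AL_true < 5e-4))
})

test_that("cohort sample means track the anatomy means at large n", {
  co <- generate_cohort(cohort_spec(n = 500), seed = 2024)
  ur <- co[co$jaw == "upper" & co$timepoint == "T0" & co$side == "right", ]
  # within 3 standard errors of the specified means (truncation shifts are
  # small relative to the SE at these bounds)
  expect_lt(abs(mean(ur$L_true) - 13.9), 3 * 2.2 / sqrt(500))
  expect_lt(abs(mean(ur$W_true) - 18.2), 3 * 1.5 / sqrt(500))
})

test_that("simulated intra-rater repeats reach the reported reliability", {
  # three repeated noisy measurements of each subject's true depth:
  # between-subject SD ~2 mm, within ~0.2 mm, so ICC must exceed 0.9
  co <- generate_cohort(cohort_spec(n = 50), seed = 31)
  truth <- co$L_true[co$jaw == "upper" & co$timepoint == "T0" &
                       co$side == "right"]
  ratings <- withr::with_seed(32, {
    vapply(1:3, function(.) measure_with_noise(truth, 0.2),
           numeric(length(truth)))
  })
  expect_gt(icc(ratings)$icc, 0.9)
})
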