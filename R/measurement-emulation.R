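#' Sample reference points on one side of an arch
#'
#' Emulates the cast-measurement procedure in which the anterior arch is
#' approximated by a polyline through reference points set along the curve
#' (12 linear subsections from 13 reference points in the original
#' procedure). Points lie exactly on `f(x) = (L/W^3) x^3 - L`, with the
#' endpoints pinned at the incisal point (`x = 0`) and the distal canine
#' contact (`x = W`).
#'
#' @param arch An [arch_geometry()] (one side: its own `L` and `W`).
#' @param n_points Number of reference points, `>= 2`.
#' @param spacing `"equal-x"` (deterministic, default) or `"random"`
#'   (interior x-coordinates drawn uniformly, then sorted — the hand-set
#'   points of the original procedure).
#' @param seed Optional integer; required for reproducible `"random"`
#'   spacing. `NULL` uses the current RNG state.
#' @return A `polyline_arch`: a tibble of ordered `(x, y)` coordinates in mm
#'   with strictly increasing `x`.
#' @examples
#' sample_arch_points(arch_geometry(13.9, 18.2), n_points = 13)
#' @export
sample_arch_points <- function(arch, n_points = 13,
                               spacing = c("equal-x", "random"),
                               seed = NULL) {
  arch <- as_arch_geometry(arch)
  spacing <- match.arg(spacing)
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  draw <- function() {
    if (spacing == "equal-x" || n_points == 2L) {
      x <- seq(0, arch$W, length.out = n_points)
    } else {
      x <- c(0, sort(stats::runif(n_points - 2L, 0, arch$W)), arch$W)
      # ties are measure-zero but would break the strict-monotonicity
      # invariant; nudge onto a strictly increasing grid if they occur
      while (any(diff(x) <= 0)) {
        x <- c(0, sort(stats::runif(n_points - 2L, 0, arch$W)), arch$W)
      }
    }
    x
  }
  x <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  y <- openness_coefficient(arch) * x^3 - arch$L
  structure(tibble::tibble(x = x, y = y), class = c("polyline_arch",
                                                    class(tibble::tibble())))
}

#' Length of a measured polyline
#'
#' Sum of the Euclidean chord lengths between consecutive reference points.
#' For points lying on the model curve this always under-estimates the true
#' arc length (chords of a convex, monotone arc), with equality only for the
#' degenerate straight arch.
#'
#' @param poly A `polyline_arch` or any data frame with numeric `x`, `y`
#'   columns ordered along the curve, `>= 2` rows.
#' @return Polyline length in mm.
#' @examples
#' polyline_length(sample_arch_points(arch_geometry(13.9, 18.2), 13))
#' @export
polyline_length <- function(poly) {
  stopifnot(is.data.frame(poly), all(c("x", "y") %in% names(poly)),
            nrow(poly) >= 2L)
  sum(sqrt(diff(poly$x)^2 + diff(poly$y)^2))
}

#' Percentage deviation of a coarse polyline from the reference polyline
#'
#' The measurement procedure approximates the arch from the inside by linear
#' subsections; a polyline with 14 subsections (15 points) was taken as the
#' ideal approximation. This quantifies the relative shortfall of a coarser
#' approximation: `100 * (ref_length - sub_length) / ref_length`.
#'
#' @param arch An [arch_geometry()].
#' @param n_sub Number of linear subsections to evaluate (`>= 2`); the
#'   polyline has `n_sub + 1` points.
#' @param reference_n Number of subsections of the reference polyline
#'   (default 14); must be `>= n_sub`.
#' @inheritParams sample_arch_points
#' @return Percentage deviation (non-negative for nested equal-x grids).
#' @examples
#' subsection_deviation(arch_geometry(13.9, 18.2), n_sub = 12)
#' @export
subsection_deviation <- function(arch, n_sub, reference_n = 14,
                                 spacing = c("equal-x", "random"),
                                 seed = NULL) {
  spacing <- match.arg(spacing)
  if (n_sub < 2L) stop("n_sub must be >= 2", call. = FALSE)
  if (reference_n < n_sub) stop("reference_n must be >= n_sub", call. = FALSE)
  len <- function(n, s) {
    polyline_length(sample_arch_points(arch, n_points = n + 1L,
                                       spacing = spacing, seed = s))
  }
  seed_sub <- if (is.null(seed)) NULL else seed
  seed_ref <- if (is.null(seed)) NULL else if (n_sub == reference_n) seed else seed + 1L
  ref <- len(reference_n, seed_ref)
  100 * (ref - len(n_sub, seed_sub)) / ref
}

#' Add zero-mean Gaussian measurement noise to a value
#'
#' Models intra-rater measurement variation as an additive draw from
#' `N(0, sd^2)`. The draw comes from the caller's RNG stream (set it with
#' `set.seed()` or `withr::with_seed()` for reproducibility).
#'
#' @param value Numeric value(s) in mm.
#' @param sd Noise standard deviation in mm, `>= 0`.
#' @return `value + N(0, sd^2)` (elementwise); `value` unchanged if `sd = 0`.
#' @examples
#' withr::with_seed(1, measure_with_noise(24.8, sd = 0.2))
#' @export
measure_with_noise <- function(value, sd) {
  stopifnot(is.numeric(value), is.numeric(sd), length(sd) == 1L)
  if (sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  if (sd == 0) return(value)
  value + stats::rnorm(length(value), mean = 0, sd = sd)
}

# ---- cohort specification ---------------------------------------------------

# Descriptive anatomy of the validation cohort: mean/SD/min/max of the
# sagittal depth L and per-side half-width W, per jaw, side and timepoint
# (mm; N = 50 treated cases, measured three times and averaged).
.cohort_anatomy <- function() {
  tribble_row <- function(jaw, timepoint, side, variable, mean, sd, min, max) {
    tibble::tibble(jaw = jaw, timepoint = timepoint, side = side,
                   variable = variable, mean = mean, sd = sd,
                   min = min, max = max)
  }
  dplyr::bind_rows(
    tribble_row("upper", "T0", "right", "L", 13.9, 2.2,  7.7, 18.3),
    tribble_row("upper", "T0", "left",  "L", 14.0, 2.0,  9.8, 17.9),
    tribble_row("upper", "T0", "right", "W", 18.2, 1.5, 13.3, 20.5),
    tribble_row("upper", "T0", "left",  "W", 18.1, 1.4, 13.3, 20.6),
    tribble_row("lower", "T0", "right", "L",  9.0, 2.0,  4.9, 14.1),
    tribble_row("lower", "T0", "left",  "L",  9.1, 1.5,  5.9, 12.9),
    tribble_row("lower", "T0", "right", "W", 14.9, 1.3, 12.0, 17.8),
    tribble_row("lower", "T0", "left",  "W", 14.8, 1.4, 12.2, 17.3),
    tribble_row("upper", "T1", "right", "L", 13.5, 1.5, 10.5, 16.6),
    tribble_row("upper", "T1", "left",  "L", 13.6, 1.4, 10.9, 17.0),
    tribble_row("upper", "T1", "right", "W", 18.8, 1.0, 16.0, 21.3),
    tribble_row("upper", "T1", "left",  "W", 18.8, 1.1, 16.1, 21.6),
    tribble_row("lower", "T1", "right", "L",  9.1, 1.4,  6.6, 12.7),
    tribble_row("lower", "T1", "left",  "L",  9.0, 1.4,  6.5, 12.0),
    tribble_row("lower", "T1", "right", "W", 15.2, 0.9, 13.0, 17.4),
    tribble_row("lower", "T1", "left",  "W", 15.0, 0.9, 13.2, 16.8)
  )
}

#' Specification of a synthetic validation cohort
#'
#' Defines the statistical structure of a cohort of treated orthodontic
#' cases: per jaw, side and timepoint, the mean, SD, minimum and maximum of
#' the true sagittal depth `L` and half-width `W` (defaults reproduce the
#' descriptive statistics of the 50-cast validation cohort), plus the
#' measurement-noise level and the polyline used for the "measured" arch
#' length.
#'
#' @param n Number of patients, `>= 1`.
#' @param anatomy Tibble with columns `jaw`, `timepoint`, `side`,
#'   `variable` (`"L"`/`"W"`), `mean`, `sd`, `min`, `max` (mm). Default:
#'   the validation-cohort values.
#' @param noise_sd Measurement-noise SD in mm of a single measurement
#'   (default 0.2, chosen so the simulated intra-rater ICC exceeds 0.9).
#' @param n_repeats Number of repeated measurements averaged into each
#'   reported value (default 3, mirroring the cast-analysis procedure in
#'   which every distance was measured three times and the mean used).
#' @param n_points Reference points of the measured polyline (default 13,
#'   i.e. 12 linear subsections).
#' @param spacing Polyline point placement, `"equal-x"` or `"random"`.
#' @param side_correlation Correlation between left and right values of a
#'   patient (anatomically coupled sides; default 0.7).
#' @return A `cohort_spec` object.
#' @examples
#' cohort_spec(n = 10)
#' @export
cohort_spec <- function(n = 50, anatomy = NULL, noise_sd = 0.2,
                        n_repeats = 3, n_points = 13,
                        spacing = c("equal-x", "random"),
                        side_correlation = 0.7) {
  spacing <- match.arg(spacing)
  if (n < 1L) stop("cohort size n must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  if (abs(side_correlation) >= 1) {
    stop("side_correlation must lie in (-1, 1)", call. = FALSE)
  }
  if (is.null(anatomy)) anatomy <- .cohort_anatomy()
  needed <- c("jaw", "timepoint", "side", "variable", "mean", "sd", "min", "max")
  stopifnot(is.data.frame(anatomy), all(needed %in% names(anatomy)))
  bad <- anatomy$min > anatomy$mean | anatomy$mean > anatomy$max | anatomy$sd < 0
  if (any(bad)) {
    stop("infeasible anatomy rows (need min <= mean <= max, sd >= 0): rows ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  structure(list(n = as.integer(n), anatomy = anatomy,
                 noise_sd = noise_sd, n_repeats = as.integer(n_repeats),
                 n_points = as.integer(n_points),
                 spacing = spacing, side_correlation = side_correlation),
            class = "cohort_spec")
}

# one correlated, per-component truncated bivariate normal pair (rejection)
.rtrunc_pair <- function(mean, sd, min, max, rho) {
  stopifnot(length(mean) == 2L)
  repeat {
    z1 <- stats::rnorm(1)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
    v <- mean + sd * c(z1, z2)
    if (all(v >= min & v <= max)) return(v)
  }
}

#' Generate a synthetic validation cohort
#'
#' Draws per-patient true anatomy (`L`, `W` per jaw, side and timepoint)
#' from normals truncated to the specified ranges, with left-right values
#' correlated within a patient; computes the true arch length from the
#' cubic-parabola model; and produces "measured" values by adding
#' independent zero-mean Gaussian noise to `L` and `W` and by chord-summing
#' a polyline whose reference points carry coordinate noise (the measured
#' arch length, like the original procedure, approximates the arch from the
#' inside). Each reported measured value is the mean of `n_repeats`
#' independent noisy measurements, emulating the repeat-and-average
#' protocol of the cast analysis. T1 anatomy is drawn independently from
#' the T1 rows of the anatomy table; it does not simulate a treatment plan.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the cohort is fully reproducible given the seed.
#' @return A tibble with one row per patient x jaw x side x timepoint and
#'   columns `patient_id`, `jaw`, `side`, `timepoint`, `L_true`, `W_true`,
#'   `AL_true`, `L_meas`, `W_meas`, `AL_meas` (per-side arch lengths, mm).
#' @examples
#' generate_cohort(cohort_spec(n = 3), seed = 1)
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  withr::with_seed(as.integer(seed), .generate_cohort_impl(spec))
}

.generate_cohort_impl <- function(spec) {
  strata <- unique(spec$anatomy[, c("jaw", "timepoint")])
  rows <- list()
  for (pid in seq_len(spec$n)) {
    for (k in seq_len(nrow(strata))) {
      jaw <- strata$jaw[k]
      tp <- strata$timepoint[k]
      par <- function(variable, side) {
        r <- spec$anatomy[spec$anatomy$jaw == jaw &
                          spec$anatomy$timepoint == tp &
                          spec$anatomy$side == side &
                          spec$anatomy$variable == variable, ]
        if (nrow(r) != 1L) {
          stop("anatomy table needs exactly one row for ", variable, " ",
               jaw, "/", side, "/", tp, call. = FALSE)
        }
        r
      }
      Lr <- par("L", "right"); Ll <- par("L", "left")
      Wr <- par("W", "right"); Wl <- par("W", "left")
      L <- .rtrunc_pair(c(Lr$mean, Ll$mean), c(Lr$sd, Ll$sd),
                        c(Lr$min, Ll$min), c(Lr$max, Ll$max),
                        spec$side_correlation)
      W <- .rtrunc_pair(c(Wr$mean, Wl$mean), c(Wr$sd, Wl$sd),
                        c(Wr$min, Wl$min), c(Wr$max, Wl$max),
                        spec$side_correlation)
      for (s in 1:2) {
        side <- c("right", "left")[s]
        arch <- arch_geometry(L = L[s], W = W[s], side = side,
                              jaw = jaw, timepoint = tp)
        al_true <- half_arch_length(arch)
        al_once <- function() {
          poly <- sample_arch_points(arch, n_points = spec$n_points,
                                     spacing = spec$spacing, seed = NULL)
          if (spec$noise_sd > 0) {
            poly$x <- measure_with_noise(poly$x, spec$noise_sd)
            poly$y <- measure_with_noise(poly$y, spec$noise_sd)
          }
          polyline_length(poly)
        }
        reps <- seq_len(spec$n_repeats)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          patient_id = sprintf("P%03d", pid), jaw = jaw, side = side,
          timepoint = tp,
          L_true = L[s], W_true = W[s], AL_true = al_true,
          L_meas = mean(vapply(reps, function(.) {
            measure_with_noise(L[s], spec$noise_sd)
          }, numeric(1))),
          W_meas = mean(vapply(reps, function(.) {
            measure_with_noise(W[s], spec$noise_sd)
          }, numeric(1))),
          AL_meas = mean(vapply(reps, function(.) al_once(), numeric(1))))
      }
    }
  }
  dplyr::bind_rows(rows)
}
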