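#' Construct an anterior-arch geometry
#'
#' The anterior dental arch (distal canine contact to distal canine contact,
#' through the incisal point) is modelled as a third-degree parabola reflected
#' at the raphe median plane. In the occlusal-plane coordinate system the
#' x-axis runs through the distal canine contact points, the y-axis lies on
#' the raphe median plane, and the incisal point sits at (0, -L). One side of
#' the arch is then `y = a x^3 - L` on `[0, W]` with openness coefficient
#' `a = L / W^3`.
#'
#' @param L Sagittal depth of the anterior arch in mm (perpendicular distance
#'   from the incisal point to the intercanine line). `L = 0` is admitted as
#'   the degenerate straight arch.
#' @param W Half arch width in mm, i.e. `aaw / 2`, the distance from the
#'   raphe median plane to the distal canine contact point. Must be positive.
#' @param side One of `"left"`, `"right"`, `"combined"`.
#' @param jaw One of `"upper"`, `"lower"`, or `NA`.
#' @param timepoint One of `"T0"`, `"T1"`, or `NA`.
#'
#' @return An object of class `arch_geometry`: a list with elements `L`, `W`,
#'   `aaw` (`= 2 * W` exactly), and the labels.
#' @examples
#' arch_geometry(L = 13.9, W = 18.2, jaw = "upper", timepoint = "T0")
#' @export
arch_geometry <- function(L, W, side = "combined", jaw = NA_character_,
                          timepoint = NA_character_) {
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L),
            is.numeric(W), length(W) == 1L, is.finite(W))
  if (W <= 0) {
    stop("invalid arch geometry: half arch width W must be > 0 (got W = ",
         format(W), " mm)", call. = FALSE)
  }
  if (L < 0) {
    stop("invalid arch geometry: sagittal depth L must be >= 0 (got L = ",
         format(L), " mm)", call. = FALSE)
  }
  side <- match.arg(side, c("combined", "left", "right"))
  if (!is.na(jaw)) jaw <- match.arg(jaw, c("upper", "lower"))
  if (!is.na(timepoint)) timepoint <- match.arg(timepoint, c("T0", "T1"))
  structure(
    list(L = as.numeric(L), W = as.numeric(W), aaw = 2 * as.numeric(W),
         side = side, jaw = jaw, timepoint = timepoint),
    class = "arch_geometry"
  )
}

#' @export
print.arch_geometry <- function(x, ...) {
  cat(sprintf(
    "<arch_geometry> L = %.3f mm, W = %.3f mm (aaw = %.3f mm), a = %.6g mm^-2\n",
    x$L, x$W, x$aaw, openness_coefficient(x)))
  cat(sprintf("  side: %s, jaw: %s, timepoint: %s\n",
              x$side, x$jaw, x$timepoint))
  invisible(x)
}

#' Construct a planned change of the arch
#'
#' Bundles the total sagittal displacement of the incisal point (protrusion
#' positive, retrusion negative) with a planned change in anterior arch
#' width. The post-treatment geometry is `L_T1 = L_T0 + delta_s_total`,
#' `aaw_T1 = aaw_T0 + delta_aaw`; validity of those is checked when the change
#' is applied to a concrete arch.
#'
#' @param delta_s_total Sagittal incisal-point displacement in mm.
#' @param delta_aaw Change of anterior arch width in mm (default 0).
#' @return An object of class `arch_change`.
#' @examples
#' arch_change(delta_s_total = 2, delta_aaw = 0)
#' @export
arch_change <- function(delta_s_total, delta_aaw = 0) {
  stopifnot(is.numeric(delta_s_total), length(delta_s_total) == 1L,
            is.finite(delta_s_total),
            is.numeric(delta_aaw), length(delta_aaw) == 1L,
            is.finite(delta_aaw))
  structure(list(delta_s_total = as.numeric(delta_s_total),
                 delta_aaw = as.numeric(delta_aaw)),
            class = "arch_change")
}

#' @export
print.arch_change <- function(x, ...) {
  cat(sprintf("<arch_change> delta_s_total = %+.3f mm, delta_aaw = %+.3f mm\n",
              x$delta_s_total, x$delta_aaw))
  invisible(x)
}

as_arch_geometry <- function(x) {
  if (inherits(x, "arch_geometry")) return(x)
  stop("expected an `arch_geometry` object", call. = FALSE)
}

#' Openness coefficient of the arch parabola
#'
#' The leading coefficient `a = L / W^3` of `y = a x^3 - L`. Smaller values
#' describe wider, flatter arches; `a` has units mm^-2.
#'
#' @param arch An [arch_geometry()] object.
#' @return The coefficient `a` in mm^-2.
#' @examples
#' openness_coefficient(arch_geometry(L = 8, W = 2)) # 1
#' @export
openness_coefficient <- function(arch) {
  arch <- as_arch_geometry(arch)
  arch$L / arch$W^3
}

#' Evaluate the arch profile y = a x^3 - L
#'
#' @param x Transverse coordinate(s) in mm; the model domain is `[0, W]`.
#'   Values outside are evaluated analytically but flagged with a warning and
#'   an `"extrapolated"` attribute (useful for plotting, never silently valid).
#' @param arch An [arch_geometry()] object.
#' @return `y` in mm, vectorised over `x`; `f(0) = -L`, `f(W) = 0`.
#' @examples
#' arch_profile(c(0, 9, 18), arch_geometry(L = 14, W = 18))
#' @export
arch_profile <- function(x, arch) {
  arch <- as_arch_geometry(arch)
  stopifnot(is.numeric(x))
  y <- openness_coefficient(arch) * x^3 - arch$L
  outside <- x < 0 | x > arch$W
  if (any(outside)) {
    warning("arch_profile evaluated outside [0, W] at ",
            sum(outside), " point(s); values are extrapolated", call. = FALSE)
    attr(y, "extrapolated") <- outside
  }
  y
}

# Arc-length integrand of one side: sqrt(1 + f'(x)^2) with f'(x) = 3 a x^2,
# i.e. sqrt(1 + 9 L^2 / W^6 * x^4). Smooth on [0, W].
arc_integrand <- function(x, L, W) {
  sqrt(1 + 9 * L^2 / W^6 * x^4)
}

#' One-sided arch length by line integration
#'
#' Integrates `sqrt(1 + 9 L^2 / W^6 x^4)` from 0 to `W` with adaptive
#' Gauss-Kronrod quadrature (absolute and relative tolerance 1e-9 mm, far
#' below the 0.1 mm precision that is clinically meaningful).
#'
#' @param arch An [arch_geometry()] object (its `L`, `W` are used).
#' @return The one-sided arc length in mm. Always within
#'   `[sqrt(W^2 + L^2), W + L]` since the curve is monotone in both
#'   coordinates.
#' @examples
#' half_arch_length(arch_geometry(L = 13.9, W = 18.2)) # ~24.826
#' @export
half_arch_length <- function(arch) {
  arch <- as_arch_geometry(arch)
  L <- arch$L
  W <- arch$W
  if (L == 0) return(W) # integrand is identically 1
  q <- stats::integrate(arc_integrand, lower = 0, upper = W, L = L, W = W,
                        rel.tol = 1e-9, abs.tol = 1e-9, subdivisions = 200L)
  if (q$message != "OK") {
    stop("arc-length quadrature did not converge: ", q$message,
         " (L = ", format(L), ", W = ", format(W),
         ", abs.error = ", format(q$abs.error), ")", call. = FALSE)
  }
  q$value
}

#' Anterior arch length AL for a full (two-sided) arch
#'
#' The model is symmetric about the raphe median plane, so the full arch
#' length is exactly twice the one-sided line integral:
#' `AL = 2 * integral_0^{aaw/2} sqrt(1 + 9 L^2 / (aaw/2)^6 x^4) dx`.
#'
#' @param L Sagittal depth in mm (`>= 0`).
#' @param aaw Anterior arch width in mm (`> 0`); the half-width is `aaw / 2`.
#' @return `AL` in mm.
#' @examples
#' anterior_arch_length(L = 13.9, aaw = 36.4) # ~49.652
#' anterior_arch_length(L = 0, aaw = 30)      # 30 exactly
#' @export
anterior_arch_length <- function(L, aaw) {
  2 * half_arch_length(arch_geometry(L = L, W = aaw / 2))
}

# Post-treatment geometry from an arch + change, with plan validation.
apply_arch_change <- function(arch_T0, change) {
  arch_T0 <- as_arch_geometry(arch_T0)
  stopifnot(inherits(change, "arch_change"))
  L1 <- arch_T0$L + change$delta_s_total
  aaw1 <- arch_T0$aaw + change$delta_aaw
  if (L1 < 0) {
    stop("invalid treatment plan: post-treatment sagittal depth ",
         "L_T0 + delta_s_total = ", format(L1),
         " mm is negative", call. = FALSE)
  }
  if (aaw1 <= 0) {
    stop("invalid treatment plan: post-treatment arch width ",
         "aaw_T0 + delta_aaw = ", format(aaw1),
         " mm is not positive", call. = FALSE)
  }
  arch_geometry(L = L1, W = aaw1 / 2, side = arch_T0$side,
                jaw = arch_T0$jaw, timepoint = "T1")
}

#' Predicted post-treatment anterior arch length AL_T1
#'
#' Applies a planned sagittal incisal-point displacement and arch-width
#' change to a pre-treatment full arch and evaluates the arc-length integral
#' of the adapted parabola:
#' `AL_T1 = 2 * integral_0^{(aaw+daaw)/2} sqrt(1 + 9 (L+ds)^2 / ((aaw+daaw)/2)^6 x^4) dx`.
#' With a zero change this reproduces `AL_T0` bit-for-bit (same code path).
#'
#' @param arch_T0 Pre-treatment full arch as an [arch_geometry()] (here `L`
#'   is the total sagittal depth and `W = aaw / 2`).
#' @param change An [arch_change()].
#' @return `AL_T1` in mm.
#' @examples
#' a0 <- arch_geometry(L = 13.9, W = 18.2)
#' predicted_arch_length(a0, arch_change(2))   # ~52.70
#' predicted_arch_length(a0, arch_change(0))   # identical to AL_T0
#' @export
predicted_arch_length <- function(arch_T0, change) {
  arch_T1 <- apply_arch_change(arch_T0, change)
  anterior_arch_length(L = arch_T1$L, aaw = arch_T1$aaw)
}

#' Therapeutic change in anterior arch length
#'
#' `delta_AL = AL_T1 - AL_T0`. With `delta_aaw = 0` its sign matches the
#' direction of the sagittal movement (protrusion lengthens the arch).
#'
#' @inheritParams predicted_arch_length
#' @return `delta_AL` in mm.
#' @examples
#' delta_arch_length(arch_geometry(L = 13.9, W = 18.2), arch_change(2))
#' @export
delta_arch_length <- function(arch_T0, change) {
  predicted_arch_length(arch_T0, change) -
    anterior_arch_length(L = as_arch_geometry(arch_T0)$L,
                         aaw = as_arch_geometry(arch_T0)$aaw)
}

#' Adapted openness coefficient after treatment
#'
#' When the incisal point moves sagittally and/or the arch width changes, the
#' openness coefficient becomes
#' `a' = (L_T0 + delta_s_total) / ((aaw_T0 + delta_aaw) / 2)^3`, i.e. the
#' openness coefficient of the post-treatment geometry.
#'
#' @inheritParams predicted_arch_length
#' @return `a'` in mm^-2.
#' @examples
#' adapted_openness(arch_geometry(L = 13.9, W = 18.2), arch_change(2))
#' @export
adapted_openness <- function(arch_T0, change) {
  openness_coefficient(apply_arch_change(arch_T0, change))
}

#' Combine left and right half-arches into the total arch
#'
#' Follows the cast-analysis bookkeeping: the total sagittal depth is the
#' mean of the two sides, `L_total = (L_left + L_right) / 2`, and the total
#' width is their sum, `W_total = aaw = W_left + W_right`.
#'
#' @param left,right [arch_geometry()] objects for the left and right side
#'   (each with its own `L` and per-side half-width `W`).
#' @return An [arch_geometry()] for the combined arch, with
#'   `L = (L_l + L_r) / 2` and `W = (W_l + W_r) / 2` so that
#'   `aaw = W_l + W_r`.
#' @examples
#' combine_sides(arch_geometry(14.0, 18.1, side = "left"),
#'               arch_geometry(13.9, 18.2, side = "right"))
#' @export
combine_sides <- function(left, right) {
  left <- as_arch_geometry(left)
  right <- as_arch_geometry(right)
  jaw <- if (identical(left$jaw, right$jaw)) left$jaw else NA_character_
  tp <- if (identical(left$timepoint, right$timepoint)) left$timepoint else NA_character_
  arch_geometry(L = (left$L + right$L) / 2,
                W = (left$W + right$W) / 2,
                side = "combined", jaw = jaw, timepoint = tp)
}
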