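#' Cephalometric state of one jaw at T0
#'
#' Holds the angular measurements read from a lateral cephalogram that the
#' trigonometric displacement formulas need, plus the rotation radius `c`
#' (linear distance between the incisors' centre of rotation and the incisal
#' edge). For the upper jaw the incisor axis and the occlusal plane are both
#' referenced to the nasal line NL (angles 1/NL and OcP/NL); for the lower
#' jaw both are referenced to the mandibular line ML (1/ML and OcP/ML).
#'
#' @param jaw `"upper"` or `"lower"`.
#' @param angle_incisor_ref Incisor-axis angle at T0 in degrees
#'   (1/NL for the upper jaw, 1/ML for the lower), in (0, 180).
#' @param angle_ocp_ref Occlusal-plane angle at T0 in degrees
#'   (OcP/NL upper, OcP/ML lower), in (0, 180).
#' @param c Rotation radius in mm, `> 0`.
#' @return An object of class `ceph_state`.
#' @examples
#' ceph_state("upper", angle_incisor_ref = 110, angle_ocp_ref = 10, c = 22)
#' @export
ceph_state <- function(jaw, angle_incisor_ref, angle_ocp_ref, c) {
  jaw <- match.arg(jaw, c("upper", "lower"))
  stopifnot(is.numeric(angle_incisor_ref), length(angle_incisor_ref) == 1L,
            is.numeric(angle_ocp_ref), length(angle_ocp_ref) == 1L,
            is.numeric(c), length(c) == 1L)
  if (c <= 0) stop("rotation radius c must be > 0 mm", call. = FALSE)
  if (angle_incisor_ref <= 0 || angle_incisor_ref >= 180 ||
      angle_ocp_ref <= 0 || angle_ocp_ref >= 180) {
    stop("cephalometric angles must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  structure(list(jaw = jaw,
                 angle_incisor_ref = as.numeric(angle_incisor_ref),
                 angle_ocp_ref = as.numeric(angle_ocp_ref),
                 c = as.numeric(c)),
            class = "ceph_state")
}

#' @export
print.ceph_state <- function(x, ...) {
  ref <- if (x$jaw == "upper") "NL" else "ML"
  cat(sprintf("<ceph_state> %s jaw: 1/%s = %.1f deg, OcP/%s = %.1f deg, c = %.1f mm\n",
              x$jaw, ref, x$angle_incisor_ref, ref, x$angle_ocp_ref, x$c))
  invisible(x)
}

#' Planned incisor movement read off the treatment plan
#'
#' @param delta_inclination Planned change of incisor inclination in degrees,
#'   signed as (angle at T1) minus (angle at T0) of the jaw's reference angle
#'   (1/NL upper, 1/ML lower). Must satisfy `|delta| < 90` (sanity bound).
#' @param s_translation Bodily sagittal movement in mm, protrusion positive.
#' @return An object of class `treatment_angles`.
#' @examples
#' treatment_angles(delta_inclination = 5, s_translation = 0)
#' @export
treatment_angles <- function(delta_inclination = 0, s_translation = 0) {
  stopifnot(is.numeric(delta_inclination), length(delta_inclination) == 1L,
            is.numeric(s_translation), length(s_translation) == 1L)
  if (abs(delta_inclination) >= 90) {
    stop("|delta_inclination| must be < 90 degrees", call. = FALSE)
  }
  structure(list(delta_inclination = as.numeric(delta_inclination),
                 s_translation = as.numeric(s_translation)),
            class = "treatment_angles")
}

deg2rad <- function(deg) deg * pi / 180

#' Sagittal incisal-point displacement due to tipping
#'
#' Trigonometric conversion of a planned inclination change into the sagittal
#' displacement of the incisal edge, projected onto the occlusal plane.
#' The printed formulas are applied literally:
#' upper jaw `c * (cos(1/NL - OcP/NL - (-d1/NL)) - cos(1/NL - OcP/NL))`;
#' lower jaw `c * (cos(180 - OcP/ML - 1/ML - d1/ML) - cos(180 - OcP/ML - 1/ML))`.
#'
#' Sign semantics follow from that literal form: with
#' `delta_inclination = angle(T1) - angle(T0)`, an increasing upper 1/NL
#' (at typical angles around 100-110 degrees with the cosine argument near
#' 100 degrees) yields a *negative* sagittal displacement. No sign flip is
#' applied; callers who want "proclination = protrusion" semantics must
#' choose the sign of `delta_inclination` accordingly.
#'
#' @param state A [ceph_state()].
#' @param plan A [treatment_angles()].
#' @return Displacement in mm; exactly 0 when `delta_inclination = 0`.
#' @examples
#' st <- ceph_state("upper", 110, 10, c = 22)
#' delta_s_tipping(st, treatment_angles(5)) # ~ -1.874
#' @export
delta_s_tipping <- function(state, plan) {
  stopifnot(inherits(state, "ceph_state"), inherits(plan, "treatment_angles"))
  d <- plan$delta_inclination
  if (d == 0) return(0)
  if (state$jaw == "upper") {
    theta <- state$angle_incisor_ref - state$angle_ocp_ref
    state$c * (cos(deg2rad(theta - (-d))) - cos(deg2rad(theta)))
  } else {
    theta <- 180 - state$angle_ocp_ref - state$angle_incisor_ref
    state$c * (cos(deg2rad(theta - d)) - cos(deg2rad(theta)))
  }
}

#' Total sagittal incisal-point displacement
#'
#' Exact sum of the tipping contribution and the bodily translation:
#' `delta_s_total = delta_s_tipping + s_translation`.
#'
#' @inheritParams delta_s_tipping
#' @return Displacement in mm (protrusion positive).
#' @examples
#' st <- ceph_state("upper", 110, 10, c = 22)
#' delta_s_total(st, treatment_angles(5, s_translation = 3))
#' @export
delta_s_total <- function(state, plan) {
  delta_s_tipping(state, plan) + plan$s_translation
}

#' Vertical incisal-point displacement due to tipping
#'
#' Measured perpendicularly to the occlusal plane; positive values denote
#' movement of the incisal point away from OcP (intrusion), negative values
#' extrusion. Literal formulas:
#' upper `-c * (sin(1/NL - OcP/NL - (-d)) - sin(1/NL - OcP/NL))`;
#' lower `-c * (sin(1/ML + OcP/ML + d) - sin(1/ML + OcP/ML))`.
#'
#' @inheritParams delta_s_tipping
#' @return Displacement in mm; exactly 0 when `delta_inclination = 0`.
#' @examples
#' delta_v(ceph_state("upper", 110, 10, c = 22), treatment_angles(5)) # ~ +0.415
#' @export
delta_v <- function(state, plan) {
  stopifnot(inherits(state, "ceph_state"), inherits(plan, "treatment_angles"))
  d <- plan$delta_inclination
  if (d == 0) return(0)
  if (state$jaw == "upper") {
    theta <- state$angle_incisor_ref - state$angle_ocp_ref
    -state$c * (sin(deg2rad(theta - (-d))) - sin(deg2rad(theta)))
  } else {
    theta <- state$angle_incisor_ref + state$angle_ocp_ref
    -state$c * (sin(deg2rad(theta + d)) - sin(deg2rad(theta)))
  }
}

#' Total bite opening or deepening
#'
#' Plain sum of the vertical displacements in the two jaws:
#' `delta_v_total = delta_v(lower) + delta_v(upper)`.
#'
#' @param dv_upper,dv_lower Vertical displacements in mm as returned by
#'   [delta_v()].
#' @return Total vertical change in mm.
#' @examples
#' delta_v_total(0.415, 0.668)
#' @export
delta_v_total <- function(dv_upper, dv_lower) {
  stopifnot(is.numeric(dv_upper), is.numeric(dv_lower))
  dv_lower + dv_upper
}

# angle names understood by convert_incisor_angle, per jaw
.aux_incisor <- c("1/NL", "1/ML", "1/NSL", "1/NA", "1/NB")
.aux_refs <- c("NL/NSL", "ML/NSL", "SNA", "SNB")

#' Convert between incisor inclination angles
#'
#' Incisor inclination can be referenced to several cephalometric lines
#' (NL, ML, NSL, NA, NB); the references differ by known plane-to-plane
#' rotations, so the angles are related by additive identities. The
#' identities used, with `dir` the opening-direction convention (`-1` by
#' default, meaning the incisor-to-NSL angle shrinks as the reference plane
#' rotates away by a positive plane angle):
#'
#' * `1/NSL = 1/NL  + dir * NL/NSL`
#' * `1/NSL = 1/ML  + dir * ML/NSL`
#' * `1/NA  = 1/NSL + dir * SNA`
#' * `1/NB  = 1/NSL + dir * SNB`
#'
#' When the supplied angles over-determine the target, all derivation routes
#' are evaluated and must agree to 0.5 degrees.
#'
#' @param angles Named list or named numeric vector of known angles in
#'   degrees; recognised names: `"1/NL"`, `"1/ML"`, `"1/NSL"`, `"1/NA"`,
#'   `"1/NB"`, `"NL/NSL"`, `"ML/NSL"`, `"SNA"`, `"SNB"`.
#' @param target The angle name to compute.
#' @param direction Opening-direction convention, `-1` (default) or `+1`.
#' @return The target angle in degrees.
#' @examples
#' convert_incisor_angle(c(`1/NL` = 110, `NL/NSL` = 8), "1/NSL") # 102
#' @export
convert_incisor_angle <- function(angles, target, direction = -1) {
  angles <- unlist(angles)
  stopifnot(is.numeric(angles), !is.null(names(angles)))
  if (!direction %in% c(-1, 1)) stop("direction must be -1 or +1", call. = FALSE)
  known_names <- c(.aux_incisor, .aux_refs)
  bad <- setdiff(names(angles), known_names)
  if (length(bad)) {
    stop("unrecognised angle name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!target %in% .aux_incisor) {
    stop("target must be one of: ", paste(.aux_incisor, collapse = ", "),
         call. = FALSE)
  }
  have <- function(nm) nm %in% names(angles)
  val <- function(nm) unname(angles[[nm]])

  # derive every obtainable value of `1/NSL` (the hub angle)
  hub <- numeric(0)
  if (have("1/NSL")) hub <- c(hub, val("1/NSL"))
  if (have("1/NL") && have("NL/NSL"))
    hub <- c(hub, val("1/NL") + direction * val("NL/NSL"))
  if (have("1/ML") && have("ML/NSL"))
    hub <- c(hub, val("1/ML") + direction * val("ML/NSL"))
  if (have("1/NA") && have("SNA"))
    hub <- c(hub, val("1/NA") - direction * val("SNA"))
  if (have("1/NB") && have("SNB"))
    hub <- c(hub, val("1/NB") - direction * val("SNB"))

  routes <- numeric(0)
  if (target != "1/NSL" && have(target)) routes <- c(routes, val(target))
  needs <- switch(target,
    "1/NSL" = list(ref = NULL,      sign = 0),
    "1/NL"  = list(ref = "NL/NSL",  sign = -1),
    "1/ML"  = list(ref = "ML/NSL",  sign = -1),
    "1/NA"  = list(ref = "SNA",     sign = +1),
    "1/NB"  = list(ref = "SNB",     sign = +1))
  if (is.null(needs$ref)) {
    routes <- c(routes, hub)
  } else if (have(needs$ref) && length(hub)) {
    routes <- c(routes, hub + needs$sign * direction * val(needs$ref))
  }
  if (!length(routes)) {
    missing_refs <- if (is.null(needs$ref)) {
      "one of 1/NL with NL/NSL, 1/ML with ML/NSL, 1/NA with SNA, 1/NB with SNB"
    } else {
      paste0("`", needs$ref, "` together with a route to 1/NSL ",
             "(1/NSL itself, or 1/NL with NL/NSL, 1/ML with ML/NSL, ",
             "1/NA with SNA, 1/NB with SNB)")
    }
    stop("cannot determine ", target, ": need ", missing_refs, call. = FALSE)
  }
  if (diff(range(routes)) > 0.5) {
    stop("inconsistent over-determined angles: routes to ", target,
         " disagree by ", format(round(diff(range(routes)), 3)),
         " degrees (> 0.5)", call. = FALSE)
  }
  mean(routes)
}

#' Sensitivity of the predicted arch length to occlusal-plane identification
#'
#' The occlusal plane must be identified on the cephalogram before the
#' tipping trigonometry can be applied; misidentifying its inclination
#' changes the computed sagittal displacement and hence the predicted arch
#' length. This substitutes each candidate OcP inclination (everything else,
#' including ML-NL, held fixed) into the tipping formula, propagates the
#' resulting `delta_s_total` into the post-treatment arc-length integral,
#' and returns the maximum pairwise spread of the predicted `AL_T1`.
#'
#' @param state A [ceph_state()]; its `angle_ocp_ref` is replaced in turn by
#'   each element of `ocp_values`.
#' @param plan A [treatment_angles()].
#' @param arch_T0 Pre-treatment full arch as an [arch_geometry()].
#' @param ocp_values Non-empty numeric vector of OcP inclinations in degrees.
#' @param delta_aaw Planned arch-width change in mm (default 0).
#' @return Maximum pairwise absolute difference of `AL_T1` across
#'   `ocp_values`, in mm. 0 for a single value or a zero-change plan.
#' @examples
#' st <- ceph_state("upper", 110, 10, c = 22)
#' ocp_sensitivity(st, treatment_angles(5),
#'                 arch_geometry(L = 14, W = 18.1), ocp_values = 4:10)
#' @export
ocp_sensitivity <- function(state, plan, arch_T0, ocp_values, delta_aaw = 0) {
  stopifnot(inherits(state, "ceph_state"), inherits(plan, "treatment_angles"))
  if (length(ocp_values) < 1L) {
    stop("ocp_values must contain at least one inclination", call. = FALSE)
  }
  al1 <- vapply(ocp_values, function(ocp) {
    st <- ceph_state(state$jaw, state$angle_incisor_ref, ocp, state$c)
    ds <- delta_s_total(st, plan)
    predicted_arch_length(arch_T0, arch_change(ds, delta_aaw))
  }, numeric(1))
  max(al1) - min(al1)
}
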