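---
title: "The cubic-parabola anterior arch-length model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cubic-parabola anterior arch-length model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archlength)
```

## The model

Orthodontic treatment of anterior crowding or spacing often moves the
incisors sagittally, which changes the length of the anterior dental arch
(canine to canine through the incisal point) and therefore the space
available. `archlength` implements a geometric model of that arch and the
machinery needed to predict treatment-induced length changes.

One side of the anterior arch is described in the occlusal plane by a
third-degree parabola. With the x-axis through the distal canine contact
points, the y-axis on the raphe median plane, and the incisal point at
$(0, -L)$, the curve is

$$ y = a\,x^3 - L, \qquad a = \frac{L}{W^3}, $$

where $L$ (mm) is the sagittal depth of the anterior arch, $W = aaw/2$ (mm)
the half arch width, and $a$ (mm$^{-2}$) the *openness coefficient* —
smaller $a$, wider arch. A third-degree curve is used because
anatomical–morphological work on arch form has found it the most suitable
simple family for the anterior segment; the reflected cubic gives the
U-shape with a smooth vertex at the incisal point. The arch length is the
line integral

$$ AL = 2 \int_0^{aaw/2} \sqrt{1 + 9\,\frac{L^2}{(aaw/2)^6}\,x^4}\; dx , $$

the factor 2 coming from the symmetry of the two sides. Treatment planning
enters through the post-treatment parameters: a sagittal incisal-point
displacement $\Delta s$ (protrusion positive) and a width change
$\Delta aaw$ give $L_{T1} = L_{T0} + \Delta s$,
$aaw_{T1} = aaw_{T0} + \Delta aaw$, an adapted openness
$a' = L_{T1} / (aaw_{T1}/2)^3$, and hence a predicted $AL_{T1}$ and
$\Delta AL = AL_{T1} - AL_{T0}$.

```{r}
anterior_arch_length(L = 13.9, aaw = 36.4)
delta_arch_length(arch_geometry(L = 13.9, W = 18.2),
                  arch_change(delta_s_total = 2))
```

### Cephalometric trigonometry

$\Delta s$ is rarely planned directly; clinicians plan a change of incisor
*inclination* (tipping about a centre of rotation at distance $c$ from the
incisal edge) plus possibly a bodily translation. With the incisor axis and
the occlusal plane referenced to the nasal line (upper jaw) or the
mandibular line (lower jaw), the tipping contribution follows from plain
trigonometry; the package evaluates the defining formulas literally:

* upper: $\Delta s_{tip} = c\,[\cos(\angle 1/NL - \angle OcP/NL -
  (-\Delta\angle 1/NL)) - \cos(\angle 1/NL - \angle OcP/NL)]$
* lower: $\Delta s_{tip} = c\,[\cos(180^\circ - \angle OcP/ML - \angle 1/ML
  - \Delta\angle 1/ML) - \cos(180^\circ - \angle OcP/ML - \angle 1/ML)]$

and analogously with sines (and a leading minus) for the vertical
displacement $\Delta v$, measured perpendicular to the occlusal plane with
intrusion positive. Two consequences of taking the formulas literally are
worth stating plainly:

* **Sign semantics.** `delta_inclination` is defined as (angle at T1)
  minus (angle at T0). At typical upper-incisor angles the literal upper
  formula then maps a *positive* $\Delta\angle 1/NL$ to a *negative*
  $\Delta s$. The library performs no silent sign flip; users who think in
  "proclination = protrusion" terms must set the sign of the planned
  angular change accordingly. We chose fidelity to the defining equations
  over a guessed intent, and the behaviour is documented on
  `delta_s_tipping()`.
* **Projection.** $\Delta v$ is reported for bite-opening bookkeeping
  ($\Delta v_{total} = \Delta v_{lj} + \Delta v_{uj}$) but does not feed
  back into the arch integral: incisal-point movement is projected onto the
  occlusal plane, and only $\Delta s_{total}$ enters $AL_{T1}$.

Incisor inclination can be referenced to several cephalometric lines
(NSL, NL, ML, NA, NB). The exact published conversion diagrams were not
available to this implementation, so `convert_incisor_angle()` uses
additive plane identities (e.g. $\angle 1/NA = \angle 1/NSL - SNA$) with an
explicit opening-direction flag; the default direction reproduces the
worked conversion $\angle 1/NL = 110^\circ$, $\angle NL/NSL = 8^\circ
\Rightarrow \angle 1/NSL = 102^\circ$. Over-determined inputs must agree to
0.5° or an error is raised rather than silently averaging gross
inconsistency.

### Occlusal-plane sensitivity

Identifying the occlusal plane on a cephalogram is itself error-prone.
`ocp_sensitivity()` substitutes a grid of candidate OcP inclinations into
the tipping formula (everything else fixed), propagates each resulting
$\Delta s_{total}$ through the arc-length integral, and reports the spread
of predicted $AL_{T1}$. For a representative upper-jaw configuration
($c = 22$ mm, $\angle 1/NL = 110^\circ$, $+5^\circ$ tipping, $L = 14$ mm,
$aaw = 36.2$ mm) a 6° misidentification range moves the prediction by

```{r}
ocp_sensitivity(ceph_state("upper", 110, 7, c = 22),
                treatment_angles(5),
                arch_geometry(L = 14, W = 18.1), ocp_values = 4:10)
```

— under 0.1 mm, i.e. clinically negligible. The grid is taken at integer
degrees with no interpolation; the spread is the max–min range.

## Numerical choices

* **Quadrature.** The integrand $\sqrt{1 + 9L^2 x^4/W^6}$ is smooth on
  $[0, W]$, so adaptive Gauss–Kronrod quadrature (`stats::integrate`) with
  absolute and relative tolerances of $10^{-9}$ needs no special handling.
  That is seven orders of magnitude below the 0.1 mm resolution that
  matters clinically. The test suite checks it against an independent
  composite-Simpson oracle ($10^4$ panels) to a relative $10^{-6}$ on a
  20×20 grid of $L \in [0, 25]$, $aaw \in [20, 45]$ mm, together with the
  geometric bounds $2\sqrt{W^2 + L^2} \le AL \le 2(W + L)$ and scale
  covariance $AL(cL, c\,aaw) = c\,AL(L, aaw)$.
* **Degenerate arches.** $L = 0$ (a straight arch) is admitted even though
  real arches have $L > 0$: it is the limit in which $AL = aaw$ exactly,
  which anchors the identity tests, and it arises transiently when a plan
  retracts the incisal point all the way to the intercanine line.
  Zero-change plans reuse the same code path as the pre-treatment length,
  so $AL_{T1} = AL_{T0}$ holds bit-for-bit, not merely to tolerance.
* **Per-side vs total bookkeeping.** Cast measurements are taken per side
  (each side has its own $L$ and $W$, and per-side arch length is the
  one-sided integral). Totals follow the cast-analysis rules:
  $L_{total} = (L_{left} + L_{right})/2$,
  $W_{total} = W_{left} + W_{right}$, measured
  $AL_{total} = AL_{left} + AL_{right}$. Note the structural consequence:
  the calculated total evaluates a *symmetric* arch at averaged depth,
  while the measured total sums two asymmetric sides, so even noise-free
  data show a small systematic total difference (~0.2%); the per-side
  comparison is the clean one.
* **Invalid plans.** A plan driving $L_{T1} < 0$ or $aaw_{T1} \le 0$ is an
  error naming the offending quantity, not a clamped value.
* **Profile extrapolation.** `arch_profile()` outside $[0, W]$ returns the
  analytic cubic but warns and flags the points, so plots can extend the
  curve without extrapolation ever passing silently through validation.

## The synthetic cohort: what it emulates, and what it does not

No individual-level measurements are published for the validation cohort —
only stratum-level descriptive statistics (mean, SD, min, max of $L$ and
$W$ per jaw, side and timepoint for 50 treated cases). The generator
therefore draws *true* anatomy from normal distributions truncated (by
rejection) to the printed ranges, with a left–right correlation of 0.7
within a patient — sides of one arch are anatomically coupled; the source
statistics are silent on the value, so it is exposed as a knob with a
physiologically plausible default.

Measurement is emulated the way the cast analysis worked:

* the "measured" arch length is a 13-point (12-subsection) polyline chord
  sum, approximating the arch from the inside — with points on the curve
  it underestimates the true length by about 0.04%, and the chord error
  vanishes as $O(n^{-2})$ (checked by a log–log slope test);
* every coordinate and every distance carries additive zero-mean Gaussian
  noise with SD 0.2 mm — chosen once so that the simulated intra-rater
  reliability of three repeated measurements lands above ICC 0.9, the
  reliability band reported for the real raters;
* each reported value is the mean of three repeated noisy measurements,
  because the cast protocol measured every distance three times and used
  the mean.

Under exactly these defaults, a 50-patient cohort yields a mean
concordance (CCC, measured vs calculated AL, across all jaw × timepoint ×
series strata) of about 0.96, and exceeds 0.95 in at least 90% of seeded
replicates — the qualitative analogue of the published validation. What
passing this does **not** show: the generator draws from the *model's own*
curve family, so it validates the computational pipeline and the noise
robustness of the agreement statistics, not the anatomical adequacy of a
cubic parabola for real arches (that evidence can only come from casts).
Real measurement error is also not purely additive-Gaussian (digitisation,
landmark ambiguity, photographic projection), and T1 anatomy is drawn
independently from the T1 strata rather than generated by simulating a
treatment — a coupled mode (apply a plan to T0 geometry via
`predicted_arch_length()`) is available for end-to-end prediction tests.

The per-subsection deviation figures reported for the original hand-drawn
arch (0.9%/0.5% at 10/12 subsections) are not reproduction targets: they
depend on one unrecoverable hand-drawn curve and manually placed points.
The module reproduces the *procedure* (`subsection_deviation()` against a
14-subsection reference), and on the model curve the equal-x deviation at
12 subsections is far smaller (~0.01%).

## Agreement statistics

`validate_cohort()` computes the calculated AL from the *measured* depth
and width, pairs it with the measured AL per side and total, and reports:

* **Lin's CCC** with population ($n$-denominator) moments, per the original
  definition, with a Fisher-z asymptotic 95% CI. CCC is used for
  method agreement because it penalises both location and scale shifts,
  unlike Pearson correlation (and $|CCC| \le |r|$ always).
* **ICC**, two-way absolute-agreement single-measure, from the standard
  mean-square decomposition. The published analysis names only "ICC"; this
  variant is the defensible default for one rater measuring each subject
  repeatedly, the variant label travels with the result, and degenerate
  (non-positive) values are reported as computed, never clamped.
* **Bland–Altman** differences oriented measured − calculated, limits of
  agreement $\bar d \pm 1.96\,s_d$ with the conventional normal quantile
  (not t-adjusted), plus the per-pair points for plotting
  (`plot_bland_altman()`).
* **Absolute-difference summaries** (mean, SD, min, max, t-based 95% CI of
  $|d|$), because signed differences cancel and the clinically relevant
  quantity is the magnitude of disagreement in mm.

Interpretation scales for the coefficients (e.g. Fleiss-style cut-offs)
are a labelling aid, not enforced thresholds.

## Problem sizes and defaults

The shipped tests run cohorts of 4–50 patients and 20 seeded replicates of
the 50-patient validation, grid checks at 20×20, and $10^4$-panel Simpson
oracles; these sizes make every check decisive for the properties above
while keeping the whole suite comfortably interactive. All lengths are
millimetres and all angles degrees throughout — the package deliberately
has no unit-system object, since every quantity in this domain is
single-unit.

## Known limitations

* The model is anterior-only (canine to canine) and 2-D (occlusal-plane
  projection); vertical incisor movement changes $AL$ only through its
  planned sagittal component.
* The cubic family is assumed, not fitted; fitting arch curves to measured
  point clouds, and alternative families (beta, catenary, Fourier,
  higher-degree polynomials), are out of scope.
* The centre-of-rotation distance $c$ is an input; estimating it from
  moment-to-force mechanics is not implemented.
* Angle conversions use additive identities under a declared convention;
  cases where reference planes open to opposite sides need the
  `direction` flag set deliberately.
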