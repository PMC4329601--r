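---
title: "Methods: the geometric body-segment-inertia model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the geometric body-segment-inertia model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthroinertia)
```

## The model and its assumptions

The package implements Yeadon's geometric method for estimating body
segment inertial parameters. Its assumptions are those of the original
model: the body is a chain of eleven rigid segments; each segment's
shape is captured by a small number of transverse cross-sections
("levels"), each a *stadium* (a rectangle capped by two semicircles,
degenerating to a circle); between consecutive levels the cross-section
interpolates linearly, giving a *stadium solid*; the cranium above the
ear level is a semi-ellipsoid; and density is uniform within each solid,
defaulting to Dempster's segmental values. Personalisation is entirely
geometric: 95 measurements (lengths along each segment chain,
perimeters, widths, anteroposterior depths) fix every stadium and every
solid height.

Segments and solids: `P` pelvis (`s0`–`s1`), `T` thorax (`s2`), `C`
chest-head (`s3`–`s7`), left/right upper arm `A1`/`B1` (`a0`–`a1`),
forearm-hand `A2`/`B2` (`a2`–`a6`), left/right thigh `J1`/`K1`
(`j0`–`j2`) and shank-foot `J2`/`K2` (`j3`–`j8`). Solids are numbered
from 0 at the proximal end of each chain. The global frame sits at the
bottom center of `s0`, the midpoint of the two hip joint centers: z up,
x mediolateral toward the left hip, y posterior.

## Measurement processing

Length measurements are cumulative within blocks (torso levels 1–5 from
`Ls0`, 6–8 restarting from `Ls5`; arm levels 2–4 from the shoulder, 5–7
from the wrist; leg levels 1 and 3–6 from the hip, 8–9 from the ankle)
and are differenced into per-solid heights; a violated ordering is
reported naming the offending pair. Three kinds of levels are not
measured directly:

* **Mid-limb levels.** The mid upper arm level `La1` sits at half the
  shoulder-elbow length. The analogous leg levels are placed midway
  between their measured neighbours: mid-thigh `Lj2` between crotch and
  knee, foot arch `Lj7` between heel and ball. The stated half-length
  rule generalises to "midway between the adjacent measured levels"
  (for the arm, the chain origin is at 0, so both readings coincide);
  we adopt that reading for the legs, where the proximal neighbour is
  not at the chain origin.
* **The acromion stadium.** Two cross-sections coexist at the acromion
  level: the top of the shoulder solid `s4` is derived from the `Ls4`
  stadium as `r = 0.57 r_Ls4`, `t = w_Ls4/2 − r`, while the bottom of
  the neck solid `s5` is the circle measured by `Ls5p`.
* **Hip stadia.** The thigh roots `Lj0`/`Lk0` are unmeasured circles of
  radius `sqrt(r_Ls0 w_Ls0)/2`.

The heel levels `Lj6`/`Lk6` are the only anteroposterior stadia; their
measured depth is the width of a stadium rotated through 90°, which the
package represents as a mediolateral stadium plus an in-plane quarter
turn applied at assembly. Measured perimeter/width pairs must satisfy
`2 < p/w < π`; a violating pair cannot be a stadium and is downgraded
to a circle recovered from the perimeter (the directly measured
quantity), with a warning rather than an error, since such
inconsistencies are common in field data. The boundary ratios are kept
as degenerate-but-valid shapes. Left/right limb averaging is available
(`symmetric = TRUE`) but off by default.

## Solid mass properties

For a stadium of radius $r$ and thickness $t$, area and centroidal
second moments are
$A = 4rt + \pi r^2$,
$I_x = \tfrac43 t r^3 + \tfrac{\pi}{4} r^4$,
$I_y = \tfrac43 r t^3 + \tfrac83 t r^3 + \pi t^2 r^2 + \tfrac{\pi}{4} r^4$.
Along a stadium solid, $r(z)$ and $t(z)$ are linear, so every integrand
(mass, first moment, longitudinal and transverse second moments) is a
polynomial of degree at most four in $z$ and is integrated *exactly*
from its coefficients. This arrangement was chosen deliberately: it has
no denominators, so the classical divide-by-zero of degenerate (circular)
stadia never arises and no small-thickness approximation is needed
anywhere. Two special-case branches are nonetheless kept, both for
fidelity to the method's history and as internal cross-checks: a solid
bounded by exactly one circle is evaluated through the swapped
(upside-down) arrangement and transported back, and a solid bounded by
two circles uses the classical truncated-cone closed forms. Tests
verify all three routes agree to near machine precision, and that the
degenerate paths match the generic path evaluated at a thickness of
$10^{-9}$ m (the historical workaround) to better than $10^{-5}$
relative.

The semi-ellipsoid (semi-axes $a, b$, height $c$) has mass
$\tfrac23 \pi a b c \rho$, center of mass at $3c/8$, and inertia about
the base center $I_{xx} = m(b^2+c^2)/5$, $I_{yy} = m(a^2+c^2)/5$,
$I_{zz} = m(a^2+b^2)/5$.

All properties are carried as `(mass, com, tensor, frame, point)`
records; frame transport is a rotation congruence $R I R^\top$ and
reference-point changes always route through the center of mass
(parallel axis theorem applied twice), which is valid between arbitrary
points.

## Configuration

The 21 joint angles are applied as body-fixed X-Y-Z Euler rotations at
each joint; joints with fewer degrees of freedom keep the same order.
`somersault`, `tilt`, `twist` orient the pelvis in the fixed frame. All
angles are independent; no left/right coupling is imposed. Signs follow
the right-hand rule about the local axes, so that e.g.
`CA1adduction = -pi/2` abducts the left arm to horizontal and
`CB1abduction = +pi/2` abducts the right arm. Joint centers are at the
center of each segment's base stadium, with three exceptions taken from
the model definition: the shoulder joints at the most distal points of
level `Ls4` (x = ±(t+r) of that stadium), the hip joints at
x = ±(t\_Ls0 + r\_Ls0)/2, and the torso–chest-head joint at the center of
level `Ls3`. There are no wrist or ankle joints. Angle bounds are data,
not anatomy: a conservative physiological table
(`configuration_bounds()`) can be bypassed with `check_bounds = FALSE`.

## Numerical choices

* Closed forms are exact; the only tolerance in the package is the
  `1e-8` orthonormality check on user-supplied rotations.
* The quadrature oracle (`numeric_mass_properties()`) exists to
  *validate* the closed forms and shares no algebra with them: it
  integrates over the volume with Gauss–Legendre nodes along the axis
  and, within each slice, resolves the boundary by the substitution
  $y = r\sin\theta$ (half-width $t + r\cos\theta$), making the
  integrand smooth so the quadrature converges spectrally. At
  resolution 48 it agrees with the closed forms to ~$10^{-15}$.
* Whole-body aggregation shifts each solid's tensor to the common
  reference point through its own center of mass; no intermediate
  origin is privileged, keeping cancellation error at the $10^{-12}$
  level required by the aggregation tests.

## The synthetic-data generator

`generate_synthetic_measurements()` produces complete measurement sets
from a template of a ~1.7 m, ~78 kg adult (template girths and lengths
were chosen once from standard anthropometric proportions so that all
derived stadia are valid and the default densities give a mass well
inside the 40–120 kg range). Stature and girth scales act on length and
girth measurements respectively; left/right asymmetry jitters each
limb's lengths by one common factor and each level's girths by a joint
factor, so perimeter/width ratios and length orderings remain valid *by
construction* for any jitter up to the 20 % cap. The generator emulates
the measurement inventory and its consistency constraints — it does
**not** emulate population covariance between measurements, sex- or
age-specific proportions, or measurement noise that violates the
scheme. Passing tests therefore demonstrate correctness of the
geometry, kinematics, and aggregation on valid inputs, not the model's
anthropometric accuracy for real subjects, which rests on the original
method's validation literature.

Test problem sizes (100-solid oracle sweeps at resolution 48, 25-seed
pipeline property, 20-case degenerate sweeps) were chosen as the
smallest sets that exercise the full parameter ranges; the whole suite
runs in well under a minute.

## Known limitations

* The per-solid default densities apply Dempster's segment values
  uniformly within each region; all correctness tests inject uniform
  density so nothing depends on these constants.
* No wrist/ankle joints, no joint coupling, no soft-tissue deformation:
  the model is rigid and piecewise-linear in cross-section by design.
* Angle bounds are deliberately generous; they prevent gross
  self-intersection only in the sense of keeping angles physiological,
  and the model does not detect self-intersection.
* The measurement parser accepts only the documented 95-key YAML
  dialect; statistical imputation of missing measurements is out of
  scope.
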