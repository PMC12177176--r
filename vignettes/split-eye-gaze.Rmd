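---
title: "Split-eye optics and gaze under body rotation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-eye optics and gaze under body rotation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitgaze)
```

`splitgaze` reconstructs the optics of miniature split compound eyes from
digitized lens landmarks and simulates how the visual gaze of the two eye
sections moves as the body rotates. This vignette is the package's
account of the model: what is computed, under which assumptions, which
parameters matter, and what the tests do and do not establish.

## Coordinate conventions and units

All eye coordinates live in a right-handed head frame: `x` anterior, `y`
toward the animal's left, `z` dorsal, in micrometres. Lab-frame flight
coordinates are in millimetres with `z` vertical-up. All angles are in
degrees. Azimuth is measured from anterior (`+x`), positive toward `+y`;
elevation is positive dorsal. Head width — the distance between the two
ocelli — is the normalization length that makes eye geometry comparable
across individuals; normalization is a pure scaling and leaves every
angle unchanged.

## Per-lens geometry

Each ommatidium is digitized as six base points on the rim of the corneal
lens plus one point on the lens top. Reconstruction proceeds in four
steps.

**Basis plane.** The lens opening plane is defined as the plane onto
which the orthogonal projection of the six base points has maximum
polygon area. A total-least-squares plane (the smallest-singular-value
direction of the centred points) seeds a Nelder-Mead optimization of the
projected area over unit normals; an optional coarse spherical grid
(`grid_guard`) restarts the search if some grid normal beats the local
optimum. For near-planar hexagons the TLS plane and the area maximizer
coincide, which is why the guard is off by default in `lens_geometry()`.
Projected polygon area is computed after sorting the vertices by angle
about their centroid, so digitization order does not matter.

**Circle fit.** The in-plane base points get an algebraic (Kasa)
least-squares circle, refined by Gauss-Newton iterations on the geometric
radial residuals to a relative step of 1e-10 (at most 100 iterations).
Lens diameter is twice the fitted radius and the optical aperture is the
fitted circle's area; the residual RMS is reported per lens as a
digitization-quality diagnostic.

**Spherical cap.** The outer lens surface is modelled as the unique
sphere through the fitted base circle (radius `a`) and the apex at
orthogonal height `h` above the basis plane: `R = (a^2 + h^2) / (2h)`.
`h` is measured orthogonally to the basis plane rather than along the
visual axis; for near-normal apices the difference is second order. An
apex on the wrong side of the plane (h <= 0) is a hard error, not a sign
flip.

**Visual axis.** The gaze direction of an ommatidium is the unit vector
from the fitted circle centre (lifted back to 3D) through the digitized
lens top, pointing out of the eye. This sign convention (outward) is
fixed package-wide.

All four outputs are equivariant under rigid motions and covariant under
scaling, which the test suite asserts to 1e-9 relative tolerance.

## Ommatidial map and interommatidial angles

The angular resolution of the eye is summarized per facet by the mean
angular difference between its visual axis and the axes of its six
angularly nearest neighbours. Edge facets have no six geometric ring
neighbours; the implementation follows the six-nearest definition
regardless of ring position and flags records whose sixth neighbour lies
beyond a 45 degree cutoff (configurable) rather than dropping them. The
neighbour relation is directional and nothing in the package assumes its
symmetry. Neighbour search pools the dorsal and ventral sections of one
eye by default, because facets at the section border can have their
nearest neighbours across the divide; `pool_sections = FALSE` restricts
the search within sections (used when comparing against per-section
nominal values).

Cross-individual averaging matches homologous landmarks by
`(section, ommatidium_id)` — the digitization order within section — and
averages head-width-normalized coordinates; downstream geometry is then
computed on the averaged eye. A mismatched correspondence is an error
listing the absent homologs, never silently dropped.

## Lens optics

Only refraction at the air-cornea transition is modelled, with
refractive index `n = 1.4`. Two single-surface formulas are exposed:
`front_focal` (`f = R/(n-1)`, the default) and `back_focal`
(`f = nR/(n-1)`). The default was chosen because measured focal lengths
of strongly curved miniature lenses sit near `2.5 R`; the alternative
stays selectable through `optics_config()` so the assumption is explicit
rather than buried. Focal depth is reported as the fraction `f / L` of
the mean ommatidium length `L = 34` um — the depth within the rhabdomere
at which the focal point falls.

The expected aperture area of a lens population whose diameter has mean
`mu` and SD `sigma` is `pi/4 (mu^2 + sigma^2)`. The identity is
distribution-free given the first two moments; a Monte-Carlo check with
a million normal draws agrees within 0.1%. Comparative statistics
between sections use `|a-b| / max(a,b) * 100`.

## Gaze under body rotation

The mean gaze of an eye section is the normalized vector sum of all its
facet axes; a balanced antiparallel set (zero resultant) is a degenerate
error. Gaze is projected from inside a 10 mm virtual sphere whose centre
sits midway between the left and right convergence points of all visual
axes (the least-squares point minimizing summed squared distances to the
axis lines, solved in closed form). Right-eye data are mirrored across
the sagittal plane to obtain the left convergence point. Because the
sphere is two orders of magnitude larger than the head, azimuth and
elevation are insensitive to the exact rotation point: a 1 mm shift of
the ray origin can move the projection by at most `asin(1/10) = 5.74`
degrees, a bound the tests verify over random configurations.

Body rotations use the intrinsic z-y-x (yaw-pitch-roll) Euler
composition, right-handed, with positive pitch lifting the anterior axis
dorsally. `gaze_sweep()` rotates the eye rigidly about the centre of
mass in fixed steps (default 1 degree) about one axis and reports where
each section's mean gaze meets the fixed sphere — the gaze rotates, the
sphere does not, so the output is the lab-frame footprint of gaze.
Default sweep envelopes are those typical of small free-flying insects:
pitch 0-150, yaw +/-90, roll +/-50 degrees. The `base_pitch` argument
takes sweeps about a nominal posture; rolling at `base_pitch = 80`
emulates rolling at the typical flight posture, which is where the
characteristic pitch/roll complementarity of the two sections appears:
under pitch the dorsal gaze (near the zenith) moves mostly in azimuth
and the ventral gaze in elevation, and under roll the ordering flips.
Yaw moves gaze strictly horizontally — elevation is constant to
numerical precision — which is the model's statement that pure yaw
produces no vertical optic flow.

## Flight kinematics

Body pitch is the angle of the thorax-to-head vector against the
horizontal forward direction, measured in the vertical plane and mapped
to [0, 180] degrees (0 horizontal head-forward, 90 vertical, above 90
pitched past vertical); it is invariant to yaw when the forward
reference is rotated with the scene. Forward velocity is the
horizontal-plane speed of the tracked point (head by default, the
head-thorax midpoint optionally; total 3D speed behind a flag), by
central differences at interior frames and one-sided differences at the
ends. Time-normalization uses a natural cubic spline (no smoothing
parameter) resampled onto [0, 1], so bouts of different duration can be
averaged sample-by-sample; endpoints are preserved exactly.

Pitch is binned over speed in 2 cm/s bins; single-observation bins
report a missing SD rather than zero, and empty bins are absent rather
than zero-filled. The summary fit regresses per-bin mean pitch on the
per-bin mean speed (not the bin centre), avoiding discretization
attenuation. Head wobble from tethered two-marker tracks is the angle of
the marker-connecting line against the horizontal image axis, reported
as deviation from its series mean, with three summary measures: mean
absolute frame-to-frame change, raw peak-to-peak (max minus min), and a
sinusoid-amplitude peak-to-peak (`2 sqrt(2) sd`) that is robust to
per-frame tracking noise — the raw extremum statistic inflates under
even small noise, so both are reported.

## The synthetic-data generators

The generators exist so that every analysis stage can be tested against
known ground truth; their defaults are the study conditions, not tuning
knobs.

**Eyes.** `generate_eye()` places 42 dorsal and 31 ventral facet axes on
two spherical caps whose mean gazes subtend exactly 53 degrees (the
layout is rotated so the resultant matches the nominal direction
exactly, making the separation a strict ground truth). Facets sit on a
triangular (hexagonal) lattice mapped to the sphere by an
azimuthal-equidistant projection, with the local radial pitch rising
from 1 degree at the array centre to 30 degrees at the rim following a
`(rho/rho_max)^1.5` profile. The exponent is a calibration: it places
the dorsal nominal mean interommatidial angle near 12.2 degrees; a
gradient shared by both sections cannot simultaneously put the ventral
mean near 16 degrees, so the ventral lands near 13.5 degrees with the
correct ordering (dorsal finer than ventral). Tests therefore compare
against the generator's own nominal values (`truth$io_nominal`), not
against literature means. Per-lens diameters and curvature radii are
drawn from section-specific normal distributions (6.35 +/- 0.51 /
7.67 +/- 0.89 um diameters; 3.98 +/- 0.72 / 5.81 +/- 0.92 um radii);
draws violating the cap-feasibility constraint `R >= a` are redrawn and
counted (`truth$n_redraws`). Each lens is realized as six base points on
the drawn circle plus an apex at the cap height solving the spherical-cap
identity, and isotropic Gaussian digitization noise is added last. The
rest-pose section gazes sit at azimuth -20 degrees (the right eye looks
slightly to the animal's right) and elevations -5/-58 degrees (dorsal /
ventral), so the dorsal gaze crosses the zenith within the natural
body-pitch range — the geometry that produces the observed
azimuth-dominant dorsal response to pitch.

**Flights.** `generate_flight()` integrates a smooth speed profile from
a take-off speed (default 14 cm/s) over a peak (27.5 cm/s at a quarter
of the bout) down to the landing speed (17.8 cm/s), at 7000 fps. Body
pitch follows the linear model through (27.5 cm/s, 48.1 deg) and
(17.8 cm/s, 113 deg) — slope -6.69 deg per cm/s — plus band-limited
Gaussian jitter (a natural spline through ~20 Gaussian knots, SD 3
degrees). The jitter is band-limited deliberately: white per-frame angle
noise at 7000 fps would imply unphysical angular rates and, through the
tracked points, contaminate differentiated velocities. The take-off
speed is kept above hovering so the linear pitch model stays inside the
physical 0-150 degree range over the whole profile; the linear model is
an idealization that would extrapolate absurdly at very low speeds.
Head, thorax-abdomen transition and abdomen tip are placed rigidly along
the pitched body axis with a 0.92 mm body length.

**Head wobble.** Two markers rotate about their fixed midpoint with a
sinusoidal angle (default amplitude 0.5 degrees, i.e. 1.0 degree
peak-to-peak; 150 Hz, of the order of a wingbeat) plus Gaussian position
noise.

All generators are pure functions of `(spec, seed)`.

### What the synthetic data do not emulate

Digitization error in real micro-CT landmarking is unlikely to be
isotropic Gaussian; tissue shrinkage during preparation deforms the eye
systematically; real facet lattices are irregular at section borders; and
real flight speed profiles are not a fixed analytic shape. Passing the
recovery tests therefore demonstrates correctness of the algorithms
under the stated noise model, not robustness to every artefact of real
specimens.

## Numerical choices and degenerate inputs

- Circle fit: Kasa seed + Gauss-Newton, convergence 1e-10 relative.
- Basis plane: TLS seed + Nelder-Mead (`reltol` 1e-12); optional
  10-degree grid restart.
- Vertex order for polygon areas: sorted by angle about the centroid.
- Collinear or coincident base points, apex on the basis plane, zero
  head width, antiparallel gaze sets, all-parallel axis bundles, and ray
  origins outside the sphere are hard, classed errors
  (`splitgaze_degenerate_geometry`, `splitgaze_schema_error`,
  `splitgaze_degenerate_gaze`), never silent fallbacks.
- Degenerate poses inside a sweep yield flagged rows, not dropped rows.
- Neighbour ties are broken toward the lower ommatidium id.

## Problem sizes used in the test suite

The suite runs the full reconstruction on default 73-facet eyes, noise
studies on 500-lens eyes at three noise levels, 50 seeded flights for
slope-recovery coverage, 1000 random configurations for the
origin-offset bound, and brute-force oracle comparisons (dense grid
circle search, 2-degree hemispheric normal grids, exhaustive neighbour
sort, quaternion rotation composition) on smaller batches. These sizes
give stable Monte-Carlo margins while keeping the default check fast on
one CPU.

## Known limitations

- The inner lens surface is not modelled; focal lengths assume a single
  refracting surface.
- Printed focal-length means for real whitefly lenses are not exactly
  `R/(n-1)` times the printed curvature means; per-lens averaging on a
  subsample can produce such offsets, and the package exposes both
  focal formulas instead of guessing the original computation.
- Reported aperture-area means imply a ventral/dorsal light-capture
  ratio of about +47%, not the +36% sometimes quoted alongside them;
  the package computes ratios only from its own outputs.
- Cross-individual correspondence by digitization order assumes a
  consistent digitization protocol; an explicit correspondence table is
  the safer route for heterogeneous data.
- Significance testing on synthetic data would be meaningless and is
  deliberately absent; the pipelines report descriptive statistics and
  effect sizes only.
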