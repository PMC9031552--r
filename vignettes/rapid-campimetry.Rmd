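---
title: "Simulating rapid kinetic campimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating rapid kinetic campimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rapidcamp)
```

## The method being simulated

Rapid campimetry is a screening test for absolute scotomas in the central
10° of the visual field. A bright dot (140 cd/m² on a 0.8 cd/m² background
— carried here as metadata, nothing is rendered photometrically) moves at
3 cm/s across a flat screen 40 cm from the eye, first vertically through
the blind spot at 15° temporal, then along seven paths (three vertical,
two diagonal, two horizontal) through the central field. The patient
presses a button when the dot vanishes and again when it reappears; the
off/on point pairs, joined by a segment, summarise any scotoma crossed.
Because the dot is small — 1.05 mm at fixation, growing to 2.72 mm at 15°
so that it stays near the local resolution limit — a defect barely wider
than the dot can swallow it completely. A suspected defect is then
*delineated* by slow vertical sweeps at 1/4 or 1/8 of the screening speed.

`rapidcamp` implements this procedure as a deterministic, testable engine:
tangent-screen geometry, the stimulus size law, trajectory execution at the
display frame rate, a simulated observer, off/on event pairing, slow-sweep
delineation, and a geometric proxy of a 68-point 10-2 static perimetry exam
run on the same synthetic ground truth, so that the kinetic-vs-static
comparison becomes a reproducible geometric fact.

## Geometry

All conversions use the separable tangent projection with fixation at the
origin: $x_{cm} = D\tan x_\circ$, and likewise for $y$. A radial gnomonic
projection would differ only off-axis; the separable form maps vertical
field lines to vertical screen lines (which is how the trajectory is
specified) and reproduces the published 14.1 cm edge of the ±10° square and
the full printed size ladder, so it is the projection of record here.

Angular stimulus size uses the small-angle conversion $d/D$, not a
cos²-foreshortened version, because that is what the published angular
column follows (0.39° for 2.72 mm at 40 cm). One printed value — 0.16° for
1.05 mm at 0°, where $d/D$ gives 0.150° — does not follow either
convention; we treat it as a rounding anomaly and exclude only that cell
from exact comparisons.

The size law interpolates linearly between its two calibrated endpoints,
giving a slope of $(2.72-1.05)/15 \approx 0.111$ mm/°, rather than using
the rounded "0.11 mm per degree": the endpoints are stated as achieved
values and the exact-endpoint form reproduces all eight ladder rows within
0.03 mm.

A dot moving at constant linear speed on a flat screen slows in angular
terms as $\cos^2(\mathrm{ecc})$; at 10° this is a ~3% deviation, which is
why the flat screen is an acceptable stand-in for a perimeter bowl over the
central field (`angular_speed_ratio()`).

## The trajectory and what it covers

The published material fixes the path count and total (~70 cm) but not the
exact line placements. The default layout is back-solved from the per-path
coverage table: the mid-path dot thicknesses imply verticals at 10°, 6.5°
and 2.5° temporal spanning ±10°; the half-run figures imply 7.44 cm
diagonals at ±45° and 5.6 cm horizontals at y = ±3.2°. With that layout the
computed per-path thickness extrema round to every printed value at 0.01 cm
precision — a strong consistency check — and the seven central paths total
68.4 cm, i.e. 22.8 s at 3 cm/s. Every layout element is configurable, and
`coverage_report()` accepts explicit thickness/half-run rows so the
published arithmetic is reproducible independently of the layout.

The swept area per path is modelled as `(thickest + thinnest) * half_run`
(two congruent trapezoids side by side). On the canonical rows this totals
~13.42 cm² of the 198.81 cm² central square, 6.75% — against 3.1% for 68
static stimuli of 4 mm² over the 87.58 cm² central disc
(`static_grid_coverage_percent()`).

## The synthetic fields

`make_preset_field()` builds ground truths emulating characteristic
glaucomatous defects: the blind spot (ellipse at (15°, −1.5°), semi-axes
2.75° × 3.75°, always absolute), arcuate nerve-fibre-bundle bands, and
quadrant wedges, each absolute or relative (with a dB attenuation). Nerve
fibre arcs are modelled as circular arcs through the blind-spot centre with
their centre on the vertical meridian — a deliberate simplification of
retinal fibre anatomy (no published equation exists for these trajectories);
the preset exposes apex eccentricity (default 8°, the Bjerrum region) and
span. Classification is total and order-independent, with
absolute > relative > normal on overlap; the precedence matches the clinical
observation that regions scored relative by coarse testing are reclassified
absolute when probed more finely.

The presets are qualitative emulations, not digitisations of any patient's
field. What passing tests show is that the *engine* behaves correctly on
fields with known geometry; they say nothing about sensitivity or
specificity in real patients, which would require a psychophysically
calibrated observer and empirical fields.

## The observer

Visibility is a hard containment rule: the dot is reported invisible
exactly when the fraction of its disc inside absolute scotoma reaches a
threshold (default 1 — full containment). Relative regions dim the dot but
never extinguish it, so they generate no events; a partial-dimming percept
has no agreed mapping to button presses and is deliberately kept out of the
event grammar. The disc fraction is computed on a fixed polar grid (16
equal-area rings × 32 spokes + centre, 513 samples), so the whole pipeline
is deterministic and seed-free by default; the sampler's radial reach is
0.984 of the dot radius, which bounds the containment law's resolution at
about 1.6% of the radius. Reaction time is Gaussian truncated at zero
(default 0/0), lapses delete off/on pairs together, and false alarms insert
brief spurious pairs — all off by default, all driven by one seed when on.

## Numerical choices in the engine

The dot centre advances `speed / frame_rate` cm per frame (0.05 cm at the
defaults) along each straight screen path, with the diameter re-evaluated
every frame. Off/on events are recorded at the (possibly latency-shifted)
response frame; no latency correction is applied, matching the method as
practised. Event pairing closes an unresolved *off* at the path endpoint
and opens an unmatched *on* at the path start.

One threshold deserves a note: the minimum invisible run that registers as
a disappearance (`min_invisible_frames`) defaults to 1 frame. The narrowest
clinically interesting band (0.35°) fully contains the screening dot for
only ~0.05 cm of travel — almost exactly one frame step at 3 cm/s and
60 Hz — so any debouncing would erase precisely the events the method
exists to find, and the exact geometric observer produces no rasterisation
flicker that would need suppressing. Users simulating noisy visibility
back-ends can raise the threshold.

Delineation sweeps vertically (configurable) over the segment's bounding
box padded by 2° per side, at 0.5° spacing by default; neither value is
published, and both are exposed. Each sweep's off/on pair is corrected by
the local dot radius to estimate the boundary (the dot vanishes only once
fully inside), and the per-sweep width estimate is
`(y_on − y_off) + dot diameter`. The latency-induced boundary displacement
is `latency × speed/divisor`, which is the quantitative content of the
claim that slowing the dot by 4–8× sharpens the borders: at 0.2 s latency a
divisor-1 sweep misplaces the boundary by ~0.8° and a divisor-8 sweep by
~0.1°.

The analytic oracle (`analytic_segments()`) recomputes the containment
intervals in the continuous domain by scanning at 0.01 cm and bisecting to
1e−7 cm, independent of frame rate and observer; engine segments must agree
with it to within one frame step, and the test suite additionally checks
the oracle itself against a closed-form straight-band law.

## The static-exam proxy and the method comparison

The 10-2 grid is the unique 68-point odd lattice with
$x^2 + y^2 \le 82$; the published description does not print coordinates,
and this cutoff is the only one giving exactly 68 points. The simulator is
geometric, not psychophysical — no staircases or dB thresholds — because
the comparison argument is purely about stimulus containment: a 0.43°
(Goldmann III) stimulus cannot fit inside a 0.35° band, so the static exam
can score such a band at most *relative*, while the 0.31° moving dot
vanishes in it and the kinetic exam scores it *absolute*. The discordance
window for band widths is therefore (0.31°, 0.43°) up to sampler
resolution, and `compare_methods()` flags exactly this pattern.

## Problem sizes and determinism

The default screening run samples ~1570 frames (26 s at 60 Hz) and a
divisor-8 delineation of a narrow band runs nine sweeps of a few hundred
frames each; the full test suite, including the continuous-domain oracle
sweeps, completes in under a minute on one core. With default (noise-free)
observers every result in the package is bit-reproducible with no seed;
stochastic observers are bit-reproducible given their seed.

## Known limitations

* No psychometric visibility function: detection is a step function of
  containment, with no luminance or eccentricity dependence beyond dot
  size.
* No fixation instability or eye movements; positions are exact.
* Relative-defect depth (dB) is carried but unused by the observer.
* The nerve-fibre arc is a one-parameter circular idealisation.
* The static proxy ignores threshold variability, so its relative defects
  arise only from partial containment or relative ground truth.
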