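# rapidcamp

Deterministic simulation engine for **rapid kinetic campimetry** — a
high-contrast tangent-screen screening test for absolute scotomas in the
central 10° visual field — together with a geometric proxy of a 68-point
10-2 static perimetry exam, so the two methods can be compared on the same
synthetic ground truth.

The package is aimed at visual-psychophysics and perimetry researchers who
want to study the geometry of kinetic screening: a bright dot moves at
3 cm/s across a dark screen 40 cm from the eye, its diameter growing with
eccentricity as

d(e) = d₀ + (d₁₅ − d₀)/15 · e  (d₀ = 1.05 mm, d₁₅ = 2.72 mm, clamped),

so the dot subtends ≈0.16° at fixation and ≈0.39° in the blind-spot
region. The dot is reported invisible exactly when its disc is fully
contained in absolute scotoma; the off/on button events are paired into
scotoma segments, and suspected defects are delineated by vertical sweeps
at 1/4 or 1/8 speed. Because a 0.43° (Goldmann III) static stimulus cannot
fit inside a band narrower than 0.43°, while the 0.31° moving dot vanishes
in anything wider than ≈0.31°, band widths in (0.31°, 0.43°) are classified
*absolute* by the kinetic exam but at most *relative* by the static grid —
the discordance this engine reproduces as a geometric fact.

## What is in the box

* `screen_geometry()`, `stimulus_spec()` — tangent projection
  (x_cm = D·tan x°), size law, pixel and timing conversions.
* `build_screening_trajectory()`, `path_pixel_count()`,
  `coverage_report()` — the blind-spot pass plus seven central paths
  (~68.4 cm), and the trapezoid model of the area they sweep.
* `make_preset_field()`, `classify_point()`, `disc_coverage_fraction()` —
  synthetic fields: blind spot, arcuate nerve-fibre bands, quadrant
  wedges, absolute or relative.
* `observer_params()`, `run_screening()`, `run_delineation()` — the
  simulated patient and the exam engine, with `analytic_segments()` as a
  continuous-domain cross-check.
* `grid_10_2()`, `simulate_static_exam()`, `compare_methods()` — the
  static-exam proxy and the method comparison.
* JSON/CSV/SVG input-output and a thin CLI (`inst/scripts/rapidcamp.R`).

## Worked example

```r
library(rapidcamp)

field <- make_preset_field("narrow_arcuate_035")  # 0.35-degree absolute band
exam  <- run_screening(field, observer_params())
exam$segments[exam$segments$path != "blind_spot_line",
              c("path", "x_off_deg", "y_off_deg", "y_on_deg")]
#>         path x_off_deg y_off_deg y_on_deg
#>   vertical_1      10.0  4.640697 4.711840
#>   vertical_2       6.5  6.697175 6.767811
#>   vertical_3       2.5  7.824748 7.895028

static <- simulate_static_exam(field)
static$counts
#>          normal relative_defect absolute_defect
#>              66               2               0

compare_methods(exam, static, field)$any_discordant
#> [1] TRUE
```

The moving dot vanishes in the band on all three vertical paths (off/on
pairs at ≈8° eccentricity, exactly where the band crosses them), while no
10-2 point can be an absolute defect — the 0.43° stimulus never fits into
the 0.35° band. Delineating the `vertical_3` segment at divisor 8 recovers
the band width:

```r
seg <- exam$segments[exam$segments$path == "vertical_3", ]
del <- run_delineation(field, observer_params(), seg, divisor = 8)
del$recovered_width_deg
#> [1] 0.3582409
```

Coverage accounting for the default run:

```r
coverage_report(reference_coverage_rows())
#>   total 13.42 cm^2 of 198.81 cm^2 (6.75%)
static_grid_coverage_percent(68, 4, disc_region_area_cm2(5.28))
#> [1] 3.105641
```

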