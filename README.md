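# vaudit — virtual dosimetry audit for IMRT credentialing

Before an institution may enroll patients in a clinical trial that uses
intensity-modulated radiotherapy (IMRT), its delivery chain is credentialed:
the institution plans and delivers a standardized C-shaped target to its own
QA phantom, and an auditing group independently compares the measured dose
distribution against the institution's planned one. `vaudit` implements the
analysis side of such a *virtual* (remote) audit for the two measurement
routes institutions actually use:

* **Radiochromic film** — a composite flatbed scan (150 dpi, 48-bit RGB)
  containing the irradiated film plus calibration subfilms at nominal
  0 / 0.5 / 2 Gy. The pipeline extracts the red channel without filtering,
  converts to optical density, corrects scanner non-uniformity by
  unset-film subtraction, fits a constrained polynomial calibration
  `D(x) = a1 x + a2 x² + a3 x³` (with `D(0) = 0`; degree adapts to the
  number of subfilms), registers the film to the plan isocenter from four
  fiducial marks, and scores it against the planned dose plane.
* **Detector arrays** — ArcCHECK (diodes on a helical cylinder lattice,
  10 mm spacing, analyzed on the unwrapped cylinder surface) and Delta4
  (two orthogonal planes, 5 mm pitch in the central 6 × 6 cm², 10 mm
  outside), read from a documented tab-separated text export and compared
  against the planned dose sampled on the detector geometry.

Both routes feed a **global gamma-index engine**. For each measured
(reference) point `r` with dose above the threshold,

    γ(r) = min over e of sqrt( ‖e − r‖²/Δd² + (D_eval(e) − D_ref(r))²/ΔD² )

where `D_eval` is the planned (evaluated) distribution interpolated
bilinearly on a dense search lattice, `Δd` is the distance-to-agreement and
`ΔD` the dose tolerance as a fixed fraction of a global denominator. Two
credentialing presets are built in:

| preset | criteria | denominator | threshold | tolerance |
|---|---|---|---|---|
| `jcog-film` | 3%/3 mm | 2 Gy (fixed) | 30% | 90% |
| `jcog-array` | 3%/2 mm | max of evaluated plane | 10% | 95% |

The verdict is `pass` iff the percentage of evaluated points with γ ≤ 1 is
at least the tolerance (both comparisons inclusive). No dataset scaling is
applied anywhere. An exhaustive brute-force gamma (`gamma_bruteforce`)
serves as an independent oracle for the optimized engine.

Because no audit measurements are publicly deposited, the package ships a
fully seeded synthetic-data generator (`scenario()`, `make_c_shape_dose()`,
`make_film_scan()`, `make_array_measurement()`, `write_rt_files()`) that
emulates every input — C-shaped per-fraction dose grids with the trial's
dose-volume properties, DICOM-RT Dose/Plan files, composite film scans,
array exports — with plantable delivery errors (over-dosed calibration
subfilm, global dose scaling, spatial shift, film rotation).

## Worked example

Generate a synthetic audit dataset and run both workflows (the same calls
back the `exec/vaudit` command-line tool):

```r
library(vaudit)

scen  <- scenario(seed = 3)                 # error-free study conditions
cd    <- make_c_shape_dose(scen)            # 2 Gy/fraction C-shaped target
rt    <- write_rt_files(cd$grid, cd$plan, "demo", seed = 3)
plane <- extract_plane(cd$grid, "axial", 0)
film  <- make_film_scan(plane, scen, "demo")

film_audit(film$scan, rt$dose, rt$plan, film$layout,
           unset_scan_path = film$unset)
#> vaudit report — device: film
#> criteria: 3%/3 mm, threshold 30%, tolerance 90%
#> denominator: 2 Gy
#> evaluated points: 14228
#> passing rate: 99.8%
#> verdict: PASS
#> warnings: none

make_array_measurement(cd$grid, delta4_geometry(), scen, "demo/m_d4.txt")
array_audit("demo/m_d4.txt", rt$dose, rt$plan, "delta4")
#> vaudit report — device: delta4
#> criteria: 3%/2 mm, threshold 10%, tolerance 95%
#> denominator: 2 / 2 Gy
#> evaluated points: 478
#> passing rate: 100.0%
#> verdict: PASS
#> warnings: none
```

The film audit evaluates 14 228 one-millimetre points of the registered
film against the planned axial plane and passes at 99.8% under 3%/3 mm —
the residual ≲0.2% comes from the planted 0.5% pixel noise and the
quadratic three-point calibration of a cubic film response. The Delta4
audit pools both detector planes (one denominator per plane, here 2 Gy
each) and passes at 100%.

Planting the delivery error reported in real audits — a "2 Gy" calibration
subfilm actually given 2.293 Gy — drags the film rate to ~86%, flips the
verdict to FAIL and raises a `calibration-suspect` warning (the measured
plateau reads ~10% low against the plan).

From a shell:

```sh
exec/vaudit synth --out demo --seed 3
exec/vaudit film  --scan demo/scan.tif --unset demo/unset.tif \
  --dose demo/rtdose.dcm --plan demo/rtplan.dcm --layout demo/layout.json -o report.json
exec/vaudit array --device arccheck --measured demo/measured_arccheck.txt \
  --dose demo/rtdose.dcm --plan demo/rtplan.dcm -o report.json
```

Exit codes: 0 = pass, 1 = fail, 2 = error.

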