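# mriexposure

Occupational exposure assessment for personnel moving through the static
stray (fringe) field of closed-bore MRI magnets — radiographers entering the
room, centering patients, recovering dropped objects; cleaners sweeping and
mopping around the couch.

A body moving with velocity **v** through a static magnetic field **B**
experiences, per unit charge, the Lorentz electromotive field

    E_em = v × B        (exposure metric, V/m)

whose modulus is the package's exposure metric. Neglecting the reaction
electrostatic field that builds up inside tissue makes |v × B| a
precautionary overestimate of the motion-induced internal field that
Directive 2013/35/EU limits: the health-effects ELV (1.1 V/m anywhere in the
body) and the frequency-adjusted sensory-effects ELV (0.7/f V/m in the head,
f the motion-related frequency in Hz). The coarser ICNIRP conversion-factor
estimator E_i = C·d|B|/dt is included for side-by-side comparison only.

The stray field itself is represented parsimoniously by a point magnetic
dipole,

    B(r) = (μ0 / 4π) · [3 (m·r̂) r̂ − m] / |r|³,

whose planar offsets (Δx, Δy) — the two unknowns — are conformed by
nonlinear least squares to a gridded |B| survey (70 planar stations × 3
heights = 210 Hall-probe measures; 20/40 cm short/long steps), starting from
preliminary estimates of the moment magnitude (1.06 MA·m² for a 3.0 T
closed full-body scanner) and its height above the floor (1.00 m).

Motion input is full-body stereophotogrammetry: 47 reflective markers at
100 Hz (6 for anatomical calibration only), smoothed, clustered into segment
centroids and differentiated into velocities at 23 representative body
points (11 centroids + 12 markers; 5 of them in the head). A seeded
synthetic generator reproduces the study conditions — U-shaped speed
profiles (fast at the doors, slow at the magnet), feet up to 5 m/s, hands up
to 3.5 m/s, head below 2 m/s for the small-stature radiographer — so the
whole pipeline is testable without laboratory recordings.

## Worked example

Fit a simulated 3.0 T survey and assess one simulated "object recovering"
trial (task N6, small-stature radiographer):

```r
library(mriexposure)

preliminary <- dipole_model()                       # m = 1.06e6 A·m², h = 1 m
truth       <- dipole_model(position = c(2.69, 5.08, 1.0))
map <- make_field_map(truth, noise_rel = 0.02, seed = 3)
fit <- fit_dipole(map, preliminary)
fit
#> Dipole fit: dx = 0.6923 m, dy = 0.0817 m, m = 1.06e+06 A m^2
#>   Pearson r (predicted vs measured |B|) = 0.9997, RMS residual = 0.0012 T

rec <- make_task_recording(operator_profiles()[2, ], task_scripts()$N6, seed = 7)
kin <- extract_exposure_points(rec)                 # 23 points, smoothed, m/s
res <- assess_task(kin, fit$model)
f   <- spectral_centroid_frequency(res$head_peak_series, res$rate)
check_compliance(res, f)
#> Health ELV 1.10 V/m: body peak 0.1211 V/m -> PASS (margin +0.9789)
#> Sensory ELV 1.5680 V/m (f = 0.446 Hz): head peak 0.1031 V/m -> PASS (margin +1.4649)
```

The fit recovers the generating planar offsets (0.69, 0.08) m to a few
millimetres despite 2% multiplicative probe noise, and the whole-body peak
electromotive field of the trial stays an order of magnitude below the
health ELV — the operator is slowest exactly where the field is strongest.

`run_pipeline(demo_config())` chains all stages (map → fit → trials →
assessment → verdicts) into a report bundle (compliance CSV, fit
diagnostics, manifest with all seeds). A thin command-line wrapper lives at
`inst/cli/mriexposure.R` (`simulate-map`, `fit-map`, `simulate-motion`,
`assess`, `report`, `demo`).

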