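Package: mriexposure
Title: Motion-Induced Electromotive Field Exposure Assessment Near MRI Magnets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment of occupational exposure of MRI room personnel to the
    static stray (fringe) field of closed-bore scanners. Fits a point magnetic
    dipole model to gridded Hall-probe field maps, processes full-body
    marker-trajectory recordings (100 Hz stereophotogrammetry) into smoothed
    per-point velocities at 23 representative body points, computes the
    motion-induced electromotive field |v x B| at each point, estimates the
    motion-related frequency by the spectral centroid of the periodogram, and
    checks compliance against the exposure limit values of Directive
    2013/35/EU (health ELV 1.1 V/m; sensory ELV 0.7/f V/m). Includes a seeded
    synthetic generator for stray-field maps and operator task trajectories so
    the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
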