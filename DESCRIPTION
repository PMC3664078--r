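Package: extremabeat
Title: Extrema-Points Analysis of Beat-to-Beat Haemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing beat-to-beat haemodynamic recordings
    (systolic, diastolic and mean arterial pressure, heart rate, stroke
    volume, cardiac output and total peripheral resistance) with the
    extrema-points model: detection of strict local maxima and minima in
    each parameter's beat series, computation of inter-extrema intervals,
    frequencies (Hz) and amplitudes, normality-gated two-group comparison
    of those metrics (Welch t or Mann-Whitney U), and correlation checks.
    Includes a synthetic beat-to-beat simulator (truncated-normal RR
    intervals, slow sinusoidal oscillations plus measurement noise, with
    physiologically consistent derived parameters) for validating every
    pipeline stage without subject data, a CSV dialect reader/writer for
    Finometer-style beat-by-beat exports, and a command-line interface
    with analyze, compare and simulate subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
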