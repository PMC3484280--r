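Package: blmotion
Title: Augmented Barlow-Levick Circuit for Motion Onset and Offset Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a rate-based nulling-inhibition (Barlow-Levick) motion
    detection circuit extended with short-range-filter, motion-onset and
    motion-offset cell layers, driven by a magnocellular-LGN temporal-frequency
    front end. Cell activities follow shunting membrane equations integrated
    with an adaptive Runge-Kutta solver. Slow evidence-accumulator populations
    read out onset, direction and offset signals; their peak activity
    (selectivity) and threshold-crossing latency are tabulated across stimulus
    speed and circuit-parameter sweeps, and selectivities are transformed into
    predicted manual reaction times for comparison with the empirical power-law
    form of simple reaction time to motion onset and offset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
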