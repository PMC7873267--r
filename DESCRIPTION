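Package: ismsloop
Title: Closed-Loop Intraspinal Microstimulation Control of Bladder Voiding, in Silico
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for closed-loop intraspinal microstimulation
    (ISMS) of bladder voiding. Builds charge-balanced biphasic pulse trains and
    duty-cycled one- or two-channel stimulation timelines (synchronous or
    asynchronously interleaved), runs a finite-state closed-loop controller
    with hybrid pulse-amplitude/pulse-frequency modulation driven by
    residual-volume feedback, and closes the loop through a configurable
    lumped-parameter bladder-urethra plant model. Computes standard cystometry
    metrics (peak pressure, per-epoch pressure change, residual volume,
    voiding efficiency) from simulated or externally recorded trials, and
    ships scripted experiments comparing stimulation protocols.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
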