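Package: streamseg
Title: Simulation of Rhythm-Delay Stream Segregation Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating an objective auditory stream-segregation
    experiment end to end: amplitude-modulated narrowband-noise ABAB burst
    sequences with a rhythm-delay target, ACE-style n-of-m cochlear-implant
    electrodogram simulation, a single-interval yes/no session engine with
    adaptive loudness balancing and a training gate, simulated listeners
    (signal-detection and envelope-based observers), and d-prime scoring of
    blocks including build-up contrasts between sequence durations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
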