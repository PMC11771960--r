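Package: hemigait
Title: Bilateral Spinal Rhythm-Generator Model and Gait Timing Analysis
    After Lateral Hemisection
Version: 1.0.0
Authors@R:
    person("Alex", "Moreau", email = "alex.moreau@example.org",
           role = c("aut", "cre"))
Description: Simulates a bilateral spinal locomotor circuit for cat hindlimb
    treadmill locomotion: two half-center rhythm generators built from
    persistent-sodium conditional bursters, coupled by commissural
    interneuron pathways (V0D, V0V, V2a, V3), driven by supraspinal drives
    and belt-speed-dependent somatosensory feedback gated by presynaptic
    inhibition.  Supports intact, hemisected and spinal-transected
    configurations under tied-belt and split-belt protocols, extracts
    cycle/stance/swing durations and duty factors from simulated or
    experimental-style gait event streams, classifies rhythm-generator
    operating regimes (state-machine, flexor-driven, classical half-center),
    and ships a seeded synthetic gait-data generator for fully offline
    testing of the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
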