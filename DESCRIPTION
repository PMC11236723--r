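Package: collikinetics
Title: Visuo-Motor Tuning, Alignment and Network Simulation for Collicular Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how midbrain superior colliculus neurons link
    vision to head movement. Implements spike-triggered averaging of 3D head
    kinematics with circular-shift shuffled nulls, direction/orientation
    selectivity indices and receptive-field mapping for standard visual
    protocols, a rigid-body geometric model that projects head rotations to a
    gaze track on the stimulus screen, circular statistics for population
    visuo-motor alignment, a three-layer rate-based network simulator
    comparing kinetic and static visuo-motor pathways for target
    interception, and synthetic-session generators with planted ground truth
    for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm
Suggests: testthat (>= 3.0.0), Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
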