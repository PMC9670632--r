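Package: rehabgym
Title: Patient-Robot Assignment and Training Scheduling for Robotic Rehabilitation Gyms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a simplified robotic rehabilitation gym in which several
    patients share several single-skill training robots over a session of
    discrete time steps. Skill acquisition follows hyperbolic learning curves
    with diminishing returns; schedules assign patients to robots as inclusive
    time intervals subject to no-overlap, single-visit and robot exit-time
    constraints. Provides feasibility checking against both a time-indexed and
    a disjunctive mixed-integer encoding, two naive baseline schedulers (best
    robot only, switch halfway), a schedule repair heuristic, exact per-patient
    bounds, a brute-force oracle for small instances, a deterministic anytime
    optimizer, alternative group objectives (variance-penalized and
    relative-to-individual-maximum), random patient-group generation and a
    scenario evaluation suite.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
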