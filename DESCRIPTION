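Package: ergoforces
Title: Joint-Load Inverse Dynamics and Musculoskeletal Risk Scoring for
    Repetitive Workstations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a motion-capture driven ergonomic assessment
    pipeline for repetitive industrial work. From per-frame joint
    rotations, worker anthropometry and a table of declared external hand
    actions, the package scales an articulated human model from
    percentile tables, computes forward kinematics with numerical
    differentiation, runs a two-stage inverse-dynamics solve (support
    reactions, then distal-to-proximal force/torque propagation in
    kilogram-force units), scores musculoskeletal-disorder risk per
    posture and per minute for the lumbar and cervical spine, shoulders,
    elbows, wrists and knees, and aggregates scored captures into
    workstation risk maps and job-rotation assessments. Includes the
    calibration arithmetic used to derive effort thresholds from capture
    sets, a synthetic work-cycle generator, CSV/BVH readers and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    optparse,
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
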