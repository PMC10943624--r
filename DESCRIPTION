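Package: cogdriver
Title: Production-System Driver Model with Central and Problem-State Bottlenecks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale discrete-event simulator of a production-system
    (ACT-R-style) driver performing a speed-sign n-back task, implementing two
    competing multitasking hypotheses: a central bottleneck arising from
    serialized production initiation, and a problem-state bottleneck gating the
    driving loop on working-memory availability. Includes a two-point steering
    law with high- and low-control loops, declarative memory with base-level
    activation and partial matching, threaded-cognition goal arbitration with
    delay instrumentation, the full 2 (road) x 5 (n-back) block design, the
    behavioral-metric pipeline (steering reversal rate, lane deviation,
    speed-compliance errors, bottleneck cost, RMSE and R-squared), and
    pupillometry preprocessing (despiking and baseline normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
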