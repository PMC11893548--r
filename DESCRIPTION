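Package: affectdyn
Title: Affect Dynamics from Heart Rate Variability via Markov Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantifies affect dynamics from short-term heart rate
    variability. RMSSD (root mean square of successive RR-interval
    differences) is computed in 30-second windows placed around
    transitions between the four circumplex affect quadrants (stress,
    engagement, boredom, relaxation), then row-relativized into a
    discrete-time, discrete-space Markov transition matrix. Provides the
    block-design scheduling machinery (an Eulerian circuit over the 12
    directed quadrant transitions), RR-interval reading and artifact
    correction, descriptive transition indexes (vertical, horizontal,
    oblique, self), predictive steady-state distributions by power
    iteration and by the eigenvector method, a synthetic RR-series
    generator for end-to-end parameter-recovery testing, and
    clinician-readable outputs including a Graphviz DOT transition graph.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
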