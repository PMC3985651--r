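Package: fdlogic
Title: Facilitated-Diffusion Kinetics of Bacterial Promoter Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-analytical simulation of transcription-factor target search
    on bacterial promoters. Promoter occupancy is modelled as a continuous-time
    Markov chain over binding-site configurations, with binding, unbinding and
    relocation propensities derived from the physics of facilitated diffusion
    (alternating 1D sliding along the DNA and 3D cytoplasmic excursions), and
    simulated exactly with the Gillespie stochastic simulation algorithm.
    Includes classification of promoter architectures into switch, barrier and
    cluster building blocks, ensemble statistics (first-arrival times and their
    bimodality via Hartigan's dip test, AND-configuration first-passage times,
    impulse-response profiles, occupancy and Fano factors), an explicit-walker
    Monte-Carlo validator, TSV/BED site-table input and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
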