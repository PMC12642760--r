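Package: electrofish
Title: Multi-Agent Reinforcement Learning Simulator of Electric-Fish Foraging and Electro-Communication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time 2D foraging arena in which recurrent artificial
    agents modeled on weakly electric fish emit and sense electric organ
    discharges (EODs). Includes a dipole forward model of the electric
    landscape (emitters, induced sources on food and conspecifics, wall
    reflections by the method of images), biomimetic sensor channels (active,
    passive, and Knollenorgan social sensing, with a collective-sensing
    pathway), a shared-parameter recurrent actor-critic policy trained by
    multi-agent proximal policy optimization, and a behavioral analytics
    suite: sequential-pulse-interval distributions and heavy-tail fits,
    condition-wise EOD probabilities, displacement windows, Theil inequality
    index, pairwise social EOD motif mining, freeloading metrics, and a
    minimal two-fish assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
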