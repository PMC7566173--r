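Package: lineadapt
Title: Production-System Simulation of Automation Reliance in a
    Line-Following Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete-event simulator of a time-critical tracking task
    ("line following") with switchable automatic and manual control, driven
    by a production-system cognitive model in the style of ACT-R.  Mode
    choice is learned online by utility reinforcement; two mechanism
    variants -- semi-Markov reward summation over the interval since the
    last reward, and a gate comparing self-confidence against trust -- can
    be switched on independently, giving a 2x2 family of models.  Includes
    procedural course generation, an auto controller, scripted baseline
    agents, grid sweeps over command-success capabilities, behavioral
    indices (tracking performance, auto-use ratio, switch count), and fit
    statistics against reference grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
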