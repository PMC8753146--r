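Package: demotip
Title: Spin Dynamics of Parochial Altruism and the Democracy-Corruption
    Tipping Point
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how a tipping point in the relationship
    between democratic norms and corruption suppression can emerge from
    micro-scale social dynamics. Implements a stochastic agent-based spin
    model of altruists, parochialists and opportunists on a social
    network; its mean-field approximation with multi-root detection,
    phase-diagram classification, critical-threshold location and
    hysteresis; slow society-scale dynamics with elections and reforms;
    model-generated democracy and corruption-suppression indices for
    ensembles of simulated societies; and the accompanying empirical
    estimators, namely continuous piecewise-linear changepoint regression
    fitted by multistart Levenberg-Marquardt and principal component
    regression with adjusted R-squared model selection. Synthetic-data
    generators and a small command-line workbench make every analysis
    reproducible without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    Matrix,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
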