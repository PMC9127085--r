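Package: routewalk
Title: Pedestrian Route Choice Analysis on Street Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing how the street environment shapes pedestrian
    route choice. Models a planar street network with per-edge walkability
    audit attributes, generates labeled alternative routes (shortest distance
    and least directional change, via an angular segment graph), decomposes
    chosen versus alternative routes by edge overlap into entire-route and
    deviated part-route observations, aggregates street-environment attributes
    to the route level by length weighting, and estimates conditional logit
    models of environmental influence on route choice by maximum likelihood.
    Includes a synthetic street-network and choice simulator with known
    utility coefficients for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
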