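Package: cellobind
Title: Quantitative Analysis of CBM and Cellulase Binding to Cellulose Allomorphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of carbohydrate-binding
    module (CBM) and processive cellulase interactions with crystalline
    cellulose allomorphs (cellulose I versus ammonia-pretreated cellulose
    III). Implements Langmuir one-site, two-site, and Langmuir-Freundlich
    adsorption isotherm fitting with truncation-sensitivity and Scatchard
    diagnostics; change-point step and dwell extraction, velocity, and
    binding-commitment classification for optical-tweezer bead-position
    traces; force-binned Bell slip-bond lifetime fitting, exponential
    mixture-order selection by parametric-bootstrap likelihood-ratio tests,
    and one-way ANOVA for rupture events; reaction-dominated FRAP recovery
    and Sauerbrey-based QCM-D Langmuir-kinetics fitting; a Buffon-needle
    geometric model of CBM orientation on the cellulose hydrophobic face;
    Segal crystallinity and Scherrer crystallite-size metrics for powder
    XRD; seeded synthetic-data generators for every input type; and a
    pipeline that tabulates cellulose I versus cellulose III comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
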