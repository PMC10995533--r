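Package: huttrap
Title: Analysis of Experimental Hut Trials of Trapping Bednets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design, simulation and analysis of experimental hut trials
    evaluating hybrid trapping bednets (T-LLINs) against malaria vectors.
    Provides Latin-square rotation schedules for huts, sleepers and nets;
    a validated hut-night record format with fate-stratified mosquito
    counts (trapped, dead, delayed death, survived); arm-level endpoint
    summaries treating trapped mosquitoes as killed; the increased
    killing-effect statistic in both of its published formulations;
    Kruskal-Wallis and Conover-Iman nonparametric inference with
    Bonferroni correction and compact letter displays; and an
    overdispersed negative-binomial trial simulator with closed-form
    expectations for parameter recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
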