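Package: clocknet
Title: Connectomic Analysis of Circadian Clock Neuron Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synaptic connectivity among identified
    circadian clock neurons in dense electron-microscopy connectomes such as
    the Drosophila hemibrain. Connections are classified by synaptic strength
    (weak, medium, strong), cell groups are compared through shared
    strong-partner analysis and Jaccard similarity of medium-plus-strong
    partner sets, recurrent "inter-clock" relay neurons are detected as
    strong shared targets that contact clock cells in turn, and neuropil
    innervation profiles summarise where connections are made. A synthetic
    connectome generator with planted group structure and ground truth
    supports validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
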