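Package: qualnet
Title: Sign-Consistency Analysis of Signed Gene-Regulatory Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Qualitative constraint-based analysis of signed, directed
    gene-regulatory networks observed across a steady-state shift.
    Transforms a curated gene-product network into an mRNA/protein-separated
    interaction graph, checks sign consistency of observed expression
    variations against the network topology, predicts invariant variation
    signs of unobserved nodes (with forward/backward deduction labels),
    localizes inconsistent parts of the network, and classifies protein
    predictions against transcript observations (Type I/II/III) to flag
    potentially active post-translational regulations. Includes a
    microarray time-series trend caller that turns probe-level expression
    series into signed observations, and generators for synthetic networks,
    consistent observation sets and expression series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
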