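Package: immortalGRN
Title: Boolean Regulatory Network Model of Epithelial Spontaneous Immortalization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Dynamic analysis of the nine-node Boolean gene regulatory network
    that underlies the spontaneous immortalization of epithelial cells via an
    epithelial - senescent - mesenchymal stem-like progression. Provides a
    synchronous Boolean network engine with exhaustive attractor enumeration,
    basin-of-attraction partitioning and node clamping; the curated core
    network linking NF-kB, ESE-2, Snai2, p16, p53, Rb, E2F, Cyclin and
    Telomerase, reconstructed from the signed interaction list and validated
    against the reference attractor profiles and basin sizes; network
    reduction of signed digraphs and Boolean networks by mediator and source
    removal; in-silico loss- and gain-of-function mutants and logic
    robustness analysis; and an epigenetic-landscape layer based on the
    stochasticity-in-nodes noise model, attractor-level Markov chains,
    mean first-passage times and the consistent global attractor ordering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
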