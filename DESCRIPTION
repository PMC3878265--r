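Package: reprodet
Title: Reprogramming Determinants from Differential Stability Analysis of
    Boolean Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies minimal sets of reprogramming determinant genes whose
    perturbation drives a Boolean gene regulatory network from one stable
    phenotype (attractor) to another.  Implements synchronous fixed-point
    attractor enumeration under an inhibitor-dominant update rule, elementary
    circuit detection in signed digraphs (Johnson's algorithm with self-loops),
    identification of differentially expressed positive circuits (DEPCs)
    between an attractor pair, simulation-validated minimal perturbation-set
    search, an evolutionary (estimation-of-distribution) network
    contextualization that prunes interactions inconsistent with observed
    expression profiles, and generators for synthetic signed networks used to
    validate the whole pipeline in silico.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
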