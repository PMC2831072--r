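Package: bnexpand
Title: Bayesian Network Pathway Models, Consensus Networks, and Single-Gene
    Expansion from Expression Compendia
Version: 0.1.0
Authors@R:
    person("Ada", "Kovarik", email = "ada.kovarik@example.org",
           role = c("aut", "cre"))
Description: Learns discrete Bayesian network models of gene pathways from
    microarray expression compendia.  Genes are filtered by coefficient of
    variation, discretized per gene into equal-frequency (maximum-entropy)
    terciles, and scored with the Cooper-Herskovits BDe marginal likelihood.
    Network structures are searched by simulated annealing over
    add/delete/reverse edge moves with random restarts; equally top-scoring
    structures are summarized as a consensus network of unanimous edges.  A
    single-gene expansion procedure ranks every out-of-network gene by the
    best score obtainable after adding it to a core network, and a term
    enrichment module associates sample-annotation words with discretization
    bins of a gene pair via Fisher's exact test.  A synthetic-data generator
    provides ground-truth networks, emissions, planted regulators, and
    annotated metadata for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
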