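Package: flynetbc
Title: Social Network Analysis of Drosophila Group Behaviour from Arena
    Trajectories
Version: 0.1.0
Authors@R: person("flynetbc", "developers", role = c("aut", "cre"),
    email = "flynetbc@example.org")
Description: Tools to infer directed social networks from per-frame arena
    trajectories of fly groups and to standardize network metrics against
    degree-preserving null models.  Includes an agent-based arena simulator
    with tunable social structure, a geometric interaction detector
    (heading angle, body-length distance, minimum bout duration), sliding
    boxcar network construction over the stream of first-occurrence
    directed interactions, betweenness centrality and auxiliary graph
    metrics z-scored against directed double-edge-swap ensembles, the
    group-level statistical procedure (IQR outlier trimming, one-way
    ANOVA, Tukey-Kramer post hoc with compact letter display, t-tests,
    Bonferroni alpha contexts), a per-locality nucleotide tally with
    chi-square homogeneity testing for natural-variant surveys, and
    recombinant interval-intersection mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
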