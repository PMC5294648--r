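Package: xfnet
Title: Bipartite Graph Filtration for Time-Delayed Cross-Frequency Brain Networks
Version: 0.1.0
Authors@R: person("Jae", "Han", email = "jae.han@example.org", role = c("aut", "cre"))
Description: Threshold-free topological analysis of time-delayed cross-frequency
    power-power coupling networks. From trial-level region-of-interest band-power
    tables it builds negative-correlation bipartite distance matrices, sweeps a
    graph filtration over them (per-partition Betti-0 curves, barcodes,
    single-linkage matrices and dendrograms), and runs trial-relabeling and
    group-relabeling permutation statistics together with d-prime behavioral
    scoring and Bonferroni-corrected behavior correlations. Includes a synthetic
    cohort generator with planted negative couplings for ground-truth testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
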