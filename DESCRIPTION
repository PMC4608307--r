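Package: nkfcnet
Title: Blocked-ANOVA Differential Expression and Network Centrality
    Prioritization for NK-Cell Stimulation Studies
Version: 0.1.0
Authors@R:
    person("NK Systems Analysis", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for prioritizing genes in blocked factorial expression
    studies of natural killer (NK) cell activation, such as FcR stimulation
    with and without interleukin-12. Implements per-gene randomized complete
    block ANOVA with cell-mean contrasts and a triple significance filter
    (Bonferroni-corrected p-value, median per-subject fold change, median
    absolute intensity difference), Venn partitioning of differential gene
    sets, hypergeometric functional-category enrichment with gene-set
    augmentation, and directed-network gene ranking by Brandes betweenness
    centrality and HITS hub/authority scores. Includes a truth-known
    synthetic-data generator emulating the 8-donor by 4-condition design and
    a pipeline driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
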