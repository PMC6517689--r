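Package: frigg
Title: Resistance Gene-Directed Mining of Fungal Secondary Metabolite Gene Clusters
Version: 0.1.0
Authors@R:
    person("Ingrid", "Voss", email = "ingrid.voss@example.org", role = c("aut", "cre"))
Description: Identifies predicted fungal secondary-metabolite gene clusters
    that carry a putative self-resistance gene: an extra, cluster-resident
    copy of an otherwise single-copy, broadly conserved gene. Works from
    multi-genome protein catalogs, predicted cluster membership tables and
    homologous protein families (either precomputed or built by
    single-linkage clustering of bidirectional BLASTp hits under identity
    and coverage thresholds). Provides the five-step selection and
    filtering pipeline with strict and large-family-exempting selection
    patterns, multi-setting run grids with combined presence matrices,
    curation support (context labels, per-family FASTA export, step-count
    summaries), and a deterministic synthetic-data generator with planted
    resistance architectures and decoys for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
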