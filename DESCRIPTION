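Package: arblink
Title: Custom Sequence Databases, Import Filters and Tree Linking for ARB
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Middleware between the ARB desktop phylogenetics environment
    and outsourced (cloud) alignment and tree-building services. Builds
    custom FASTA databases with tab-delimited metadata headers from
    GenBank flat files and a user-supplied meta-labels schema, mints short
    stable unique identifiers for every record, generates the matching ARB
    import filter (.ift) automatically, exports bare-ID FASTA for external
    computation, and links returned Newick trees back to the local
    metadata via the unique IDs, including leaf relabeling by any metadata
    field. Ships a reference interpreter for the emitted import-filter
    dialect and a deterministic synthetic-data generator so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
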