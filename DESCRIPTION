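Package: bufdbg
Title: Buffered Dynamic Succinct de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A succinct, BWT-based index of the edge-centric de Bruijn graph
    (a Wheeler-graph formulation of the BOSS representation) made dynamic by
    buffering edge insertions in a hash-style addition buffer and edge
    removals in a bit vector over colexicographic edge ranks.  Membership and
    traversal queries consult the static index and both buffers transparently;
    a batched merge algorithm periodically rebuilds the static index from the
    buffers using partition refinement over implicit label matrices, followed
    by an optional cleanup of redundant dummy nodes.  Includes FASTA/FASTQ
    ingestion, a binary serialization format, a command-line interface, and a
    brute-force reference implementation used for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
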