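Package: tandemasm
Title: Tandem-Repeat-Aware De Novo Assembly of Short Reads
Version: 0.1.0
Authors@R: person("tandemasm", "developers", role = c("aut", "cre"),
    email = "tandemasm@example.org")
Description: A de Bruijn graph assembler for short sequencing reads that
    restores tandem repeats longer than the read and insert length. Edge
    weights (k-mer counts) are modelled as Poisson draws and normalized into
    per-genome copy numbers; tandem repeats appear as loops in the graph whose
    branch weights are equalized and balanced so that a weight-consuming
    traversal emits each repeat motif the correct number of times. Includes a
    paired-end read simulator with configurable tandem-array references, an
    exact-match tandem-repeat evaluator, and a required-coverage planner.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    Biostrings,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
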