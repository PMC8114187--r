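Package: flowkern
Title: Rule-Based Workflow Engine with Exact Job Scheduling and Provenance Caching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained kernel of a make-style workflow manager for
    scientific data analyses. Workflows are declared as generic rules with
    wildcard file patterns; the directed acyclic graph (DAG) of concrete jobs
    is inferred recursively from requested target files, including
    checkpoint-driven re-evaluation of conditional branches. Pending jobs are
    launched according to an exact solution of a mixed-integer linear program
    that lexicographically maximises job priority, core utilisation, and the
    prompt deletion of temporary files. Jobs sharing a group label are
    partitioned into connected subgraphs submitted as units, with level-wise
    resource aggregation. A blockchain-style recursive SHA-256 provenance
    hash addresses a between-workflow result cache, and completed runs can be
    turned into byte-by-byte replay unit tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    digest,
    jsonlite,
    processx,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
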