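Package: dpmlcs
Title: Dominant-Point Search for All Multiple Longest Common Subsequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exact enumeration of all multiple longest common subsequences
    (MLCS) of two or more DNA or protein sequences using the dominant-point
    family of algorithms: successor-table preprocessing, level-wise
    match-point expansion, dominance-based pruning, construction of a
    directed acyclic graph over the retained points, and exhaustive
    depth-first backtracking.  Components (pruning mode, pairwise
    dynamic-programming baselines, an exponential brute-force oracle) are
    pluggable so algorithm variants can be assembled from a registry, and a
    seeded synthetic sequence generator supports fully reproducible
    verification without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    optparse,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
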