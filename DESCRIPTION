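Package: rtcnspace
Title: Spaces of Ranked Tree-Child Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with ranked tree-child networks (RTCNs) via
    their encoding as maximal chains of cluster systems.  Provides the join
    and reticulation successor relations on cluster systems, validation and
    enumeration of (maximal) chains, the graded poset of chain-realizable
    cluster systems, decoding of chains into ranked networks and the reverse
    encoding, ranked nearest-neighbor-interchange (rNNI*) moves with exact
    breadth-first-search distances, a ranked analogue of the Robinson-Foulds
    distance, and the CAT(0) orthant space of equidistant tree-child
    networks with exact geodesic distances computed by a successive
    path-space refinement algorithm.  Networks can be exported as extended
    Newick strings and all objects round-trip through a documented JSON
    interchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
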