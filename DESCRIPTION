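Package: homoplasyscan
Title: Identify Homoplasies on a Phylogeny with the Consistency Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects homoplasious sites in a nucleotide alignment given a rooted
    phylogeny. For every alignment site a Fitch-style post-order downpass computes
    the minimum number of state changes on the tree (the per-site tree length); the
    consistency index (distinct states minus one, divided by tree length) flags
    sites that require more changes than a single origin would. Produces a CSV
    consistency report, a filtered alignment without the inconsistent sites, and a
    Newick phylogeny whose internal nodes are annotated with the homoplasious
    positions that required a change there. Includes a validation harness that
    simulates transmission-linked outbreaks of continuously mutating sequences,
    inserts known homoplasies and recombination events, rebuilds trees by
    neighbour joining, and measures detection rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
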