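Package: vennwalk
Title: Venn-Region Seeded Network Propagation for Comparing Gene Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions two or more differential-expression gene lists into
    the disjoint regions of their Venn diagram, lets the user pick any union
    of regions as seed genes, and prioritizes the remaining genes by a
    random walk with restart over the high-confidence protein-protein
    interaction subnetwork induced on the gene union. Includes a synthetic
    fixture generator with planted region and module structure so the full
    pipeline can be exercised and benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
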