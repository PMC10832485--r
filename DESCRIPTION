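Package: maotofu
Title: Nutritional, Flavor and Bacterial Community Analysis of Fermented Soy Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for mold-fermented soy products (Mao-tofu and
    related foods) covering four linked stages: amino-acid nutritional and taste
    scoring (ratio coefficients RAA/RC/SRC against the WHO/FAO reference
    pattern, fuzzy closeness to egg protein, taste activity values), internal
    standard semi-quantification of GC-MS volatile compounds with chemical
    class aggregation, lightweight full-length 16S rRNA community profiling
    (barcode demultiplexing, length and accuracy QC, dereplication, greedy 97
    percent OTU clustering, diversity and rarefaction), and taxa-metabolite
    Spearman correlation heatmaps and co-occurrence networks. A seeded
    synthetic-data generator emulates every input so the whole chain is
    testable without raw instrument or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
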