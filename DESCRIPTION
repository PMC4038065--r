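Package: gosets
Title: Build GSEA-Compatible Gene Set Collections from Gene Ontology Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds MSigDB-format (.gmt/.gmx) gene set collections for any
    species from a Gene Ontology OBO file and gene-GO association data
    (NCBI gene2go, GAF 2.x, or Affymetrix/Agilent array annotation files).
    Annotations are propagated up the ontology graph following the true-path
    rule, filtered by evidence code and set size, and duplicate sets with
    identical gene content are collapsed to a single set whose description
    records every contributing term together with its distance from the
    ontology root.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
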