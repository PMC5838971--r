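Package: tipsort
Title: Partition FASTA Sequences by FigTree Tip Colors and Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch extraction of FASTA sequences from exploratory phylogenetic
    trees edited in the FigTree tree viewer. Parses the taxa block of a
    FigTree-saved NEXUS file to recover per-tip color and annotation
    attributes, cross-checks tip labels against the FASTA headers of the
    alignment used to build the tree, and fully deconstructs the selection
    scheme into per-color, per-annotation and combined sequence subsets
    (including the unselected complements), written as sequential FASTA files
    under COLOR, ANNOT and COMBO output folders. Discrepancies between tree
    and FASTA (duplicates, missing labels) are reported as warnings and the
    extraction proceeds on the matched intersection. A seeded fixture
    generator produces matched synthetic Newick/NEXUS/FASTA triples with a
    known ground-truth scheme for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
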