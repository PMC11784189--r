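Package: amfphylo
Title: Phylogeny-Based Taxonomy Assignment and Community Profiling for
    Arbuscular Mycorrhizal Fungal 18S Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogeny-based analysis of arbuscular mycorrhizal
    fungal (AMF, phylum Glomeromycota) communities profiled with long-read
    18S (SSU) rRNA amplicons.  Curates reference sequence sets with
    four-rank lineages, trims multiple sequence alignments to the AML1/AML2
    amplicon window and by gap-fraction stringency, detects clade-exclusive
    insertion columns, roots trees on a designated outgroup, assigns
    taxonomy to amplicon sequence variants (ASVs) from the smallest
    monophyletic group housing them together with reference sequences,
    flags query-only novel clades and long branches, filters and normalises
    ASV count tables into relative-abundance and clade-level profiles, and
    compares communities with Bray-Curtis ANOSIM.  A synthetic-data
    generator emulates the full study design (intragenomic rRNA variants,
    planted treatment effects, off-target lineages) so every stage is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
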