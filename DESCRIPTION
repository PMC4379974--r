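Package: isgapr
Title: Evidence-Based Structural Gene Annotation for De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an integrated structural gene annotation pipeline
    (ISGAP) for de novo transcriptome assemblies. Gene structures are built
    from spliced protein-to-transcript alignments, merged by identical
    exon-exon junction sets, filtered for frameshifts and premature stop
    codons, extended codon-by-codon in a fixed reading frame, and integrated
    with ab initio gene models; a representative model is selected per locus.
    Includes the classical six-frame translation baseline, a strand- and
    frame-aware validation procedure against reference-protein alignment
    regions, transcript-space variant classification with bi-directional
    k-mer flank confirmation between two assemblies, and a synthetic fixture
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
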