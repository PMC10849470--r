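Package: hlakir
Title: Gene-Structure Annotation and Allele Typing of Polymorphic Immune
    Genes on Assembled Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates gene structures and types alleles of highly
    polymorphic immune genes (HLA-class, KIR-class and complement C4) on
    assembled contigs.  Full-length reference allele sequences are aligned
    to contigs, alignments are clustered into candidate loci by a greedy
    best-first procedure ranked on gap-compressed identity, a template
    allele is selected by a four-tier priority scheme and its exon/CDS
    structure is lifted onto the contig.  Alleles are then called from the
    extracted coding sequence by edit distance against all full and
    partial CDS records, with hierarchical 'new'-field nomenclature for
    novel alleles.  C4 genes are annotated by spliced placement of a
    reference transcript, typed C4A/C4B from diagnostic exon-26 residues
    and long/short form from intron-9 length.  Companion statistics
    include population CDS diversity with permutation tests, read-depth
    deletion genotyping, and copy-number inference from genotyper allele
    abundances.  A seeded synthetic-fixture generator produces reference
    databases and contigs with planted alleles and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
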