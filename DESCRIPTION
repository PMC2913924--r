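Package: VariantHierarchy
Title: Hierarchical Annotation-Driven Classification of Sequence Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies substitutions, insertions and deletions discovered on a
    region of interest of an annotated genome. Each query variant is walked
    through a decision tree of genomic feature contexts (known-variant and
    repeat collocation; intergenic; upstream promoter and downstream
    transcript windows; intronic with donor/acceptor splice-site windows;
    exonic with 5' UTR / CDS / 3' UTR subregions) and, for coding variants,
    a codon-level consequence is predicted: synonymous or non-synonymous,
    conserved or unconserved under BLOSUM30, frameshift or in-frame indel,
    impacted Pfam domains, and the full mutant protein sequence. Results are
    written both as a tab-indented hierarchical report and as a flat
    tab-separated table. A deterministic synthetic-fixture generator and an
    independent brute-force position labeler support testing without any
    external data, and a GFF3/BED adapter converts standard annotation into
    the package's region-local format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'coords.R'
    'reference.R'
    'annotation.R'
    'adapter.R'
    'variants.R'
    'blosum.R'
    'protein.R'
    'classify.R'
    'report.R'
    'fixtures.R'
    'oracle.R'
    'cli.R'
    'VariantHierarchy-package.R'
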