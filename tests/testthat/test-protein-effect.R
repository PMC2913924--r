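test_that("spliced CDS extraction handles multi-exon and minus strand", {
  toy <- makeToyGene()
  expect_equal(splicedCdsSequence(toy$tr, toy$ref), toy$cds)
  toyM <- makeToyGene("-")
  expect_equal(splicedCdsSequence(toyM$tr, toyM$ref), toy$cds)

  ## single-exon slice: CDS (10, 19) is residues 11..19
  ref <- referenceRegion(paste0(strrep("A", 10), "TTTGGGCCC", strrep("A", 10)))
  tr1 <- new("TranscriptModel", transcriptId = "t", strand = "+",
             exons = matrix(c(5L, 25L), 1, 2,
                            dimnames = list(NULL, c("begin", "end"))),
             cdsSpan = c(10L, 19L))
  expect_equal(splicedCdsSequence(tr1, ref), "TTTGGGCCC")
  tr1@strand <- "-"
  expect_equal(splicedCdsSequence(tr1, ref), "GGGCCCAAA")
})

test_that("genomic/CDS/amino-acid coordinate maps are mutually inverse", {
  toy <- makeToyGene()
  tr <- toy$tr  # exon1 contributes 7 coding bases
  expect_equal(genomicToCds(15, tr), 1L)
  expect_equal(genomicToCds(21, tr), 7L)
  expect_equal(genomicToCds(42, tr), 8L)  # first coding base of exon 2
  expect_equal(genomicToCds(49, tr), 15L)
  expect_error(genomicToCds(30, tr), "not a coding base")
  for (i in 1:15) expect_equal(genomicToCds(cdsToGenomic(i, tr), tr), i)

  toyM <- makeToyGene("-")
  trM <- toyM$tr
  expect_equal(genomicToCds(cdsToGenomic(1L, trM), trM), 1L)
  expect_equal(genomicToCds(cdsToGenomic(15L, trM), trM), 15L)
  ## last CDS base on the minus strand is the leftmost coding position
  expect_equal(genomicToCds(min(cdsPieces(trM)[, 1]), trM), 15L)

  expect_equal(cdsToAa(1L), list(aaPosition = 1L, offsetInCodon = 0L))
  expect_equal(cdsToAa(3L), list(aaPosition = 1L, offsetInCodon = 2L))
  expect_equal(cdsToAa(4L), list(aaPosition = 2L, offsetInCodon = 0L))
})

test_that("translation truncates at stops and maps ambiguity to X", {
  expect_equal(translateCds("ATGTAA")$protein, "M")
  expect_equal(translateCds("ATGAATTGACCCGGG")$protein, "MN")
  expect_equal(translateCds("ATGNNG")$protein, "MX")
  expect_equal(translateCds("ATGAA")$protein, "M")   # partial codon dropped
  expect_equal(translateCds("ATGTAA")$stoppedAt, 2L)
  expect_true(is.na(translateCds("ATGAAT")$stoppedAt))
})

test_that("codon substitution calls agree with a translate-and-compare oracle", {
  expect_equal(classifySubstitution("CTG", "CTA")$class, "synonymous")
  sub <- classifySubstitution("ATG", "ATA")
  expect_equal(sub$class, "nonsynonymous")
  expect_equal(c(sub$refAa, sub$altAa), c("M", "I"))
  expect_equal(classifySubstitution("TAA", "TAG")$class, "synonymous")
  expect_equal(classifySubstitution("ANG", "AAG")$note, "ambiguous_codon")

  ## exhaustive: all 64 codons x 9 single-base mutations
  bases <- c("A", "C", "G", "T")
  codons <- names(Biostrings::GENETIC_CODE)
  code <- Biostrings::GENETIC_CODE
  for (ref in codons) {
    for (pos in 1:3) {
      for (alt in setdiff(bases, substr(ref, pos, pos))) {
        mut <- ref
        substr(mut, pos, pos) <- alt
        got <- classifySubstitution(ref, mut)$class
        want <- if (unname(code[ref]) == unname(code[mut])) "synonymous"
                else "nonsynonymous"
        expect_equal(got, want)
      }
    }
  }
})

test_that("conservation calls follow the matrix sign and the stop rule", {
  m <- readSubstitutionMatrix()
  expect_equal(m["A", "A"], 4L)   # published BLOSUM30 diagonal spot checks
  expect_equal(m["W", "W"], 20L)
  expect_equal(m["I", "V"], 4L)
  expect_equal(m["N", "W"], -7L)
  expect_equal(conservationClass("I", "V", m), "conserved")
  expect_equal(conservationClass("N", "W", m), "unconserved")
  aas <- rownames(m)[rownames(m) %in% VariantHierarchy:::.AA20]
  for (a in aas) expect_equal(conservationClass(a, "*", m), "unconserved")
  expect_error(conservationClass("B", "J", m), "not in matrix")

  ## symmetry over all 380 ordered non-identical standard pairs
  for (a in aas) for (b in setdiff(aas, a))
    expect_identical(conservationClass(a, b, m), conservationClass(b, a, m))
})

test_that("indel frame classification is a mod-3 rule", {
  expect_equal(classifyIndel(3L), "amino_acid_indel")
  expect_equal(classifyIndel(-1L), "frameshift")
  expect_equal(classifyIndel(6L), "amino_acid_indel")
  expect_equal(classifyIndel(-4L), "frameshift")
})

test_that("impacted domains use inclusive aa overlap; frameshifts extend", {
  dom <- data.frame(domain_name = c("d1", "d2"),
                    aa_begin = c(40L, 100L), aa_end = c(60L, 120L),
                    stringsAsFactors = FALSE)
  expect_equal(impactedDomains(50, 50, dom), "d1")
  expect_equal(impactedDomains(39, 39, dom), character())
  expect_equal(impactedDomains(40, 40, dom), "d1")
  ## frameshift at aa 10 on a 150-aa protein: affected range 10..150
  expect_equal(impactedDomains(10, 150, dom), c("d1", "d2"))
  expect_equal(impactedDomains(10, 150, dom[0, ]), character())
})

test_that("mutant protein prediction covers substitutions and indels", {
  toy <- makeToyGene()
  fx <- list(ann = toy$ann, ref = toy$ref)

  ## synonymous SNP: CDS base 6 (AAT -> AAC), protein unchanged
  tree <- classifyAt(20, fx, allele = "C")
  e <- firstEffect(tree)
  expect_equal(e@substitutionClass, "synonymous")
  expect_equal(e@predictedProtein, toy$protein)
  expect_equal(e@cdsPosition, 6L)
  expect_equal(e@aaPosition, 2L)
  expect_equal(c(e@refCodon, e@altCodon), c("AAT", "AAC"))

  ## stop gain at codon 4 (TGC -> TGA): protein truncates to 3 residues
  tree <- classifyAt(46, fx, allele = "A")
  e <- firstEffect(tree)
  expect_equal(e@substitutionClass, "nonsynonymous")
  expect_equal(e@conservationClass, "unconserved")
  expect_equal(e@altAa, "*")
  expect_equal(e@predictedProtein, "MNG")

  ## in-frame deletion of codon 3, spanning the intron: protein loses G
  v <- queryVariant("del3", 21, 44, "+", "")
  e <- firstEffect(classifyVariant(v, toy$ann, toy$ref, PARAMS))
  expect_equal(e@indelClass, "amino_acid_indel")
  expect_equal(e@predictedProtein, "MNC")
  expect_true("dom1" %in% e@impactedDomains)  # codon 3 hits aa 2..3 domain

  ## frameshift: single-base deletion in codon 2
  v <- queryVariant("fs", 20, 21, "+", "")
  e <- firstEffect(classifyVariant(v, toy$ann, toy$ref, PARAMS))
  expect_equal(e@indelClass, "frameshift")
  expect_true("stop_lost" %in% e@notes)  # shifted frame runs off the end
  expect_equal(substr(e@predictedProtein, 1, 1), "M")

  ## in-frame insertion of one codon after codon 1
  v <- queryVariant("ins", 18, 18, "+", "GTA")
  e <- firstEffect(classifyVariant(v, toy$ann, toy$ref, PARAMS))
  expect_equal(e@indelClass, "amino_acid_indel")
  expect_equal(e@predictedProtein, "MVNGC")

  ## start loss: the initiator ATG is destroyed
  v <- queryVariant("sl", 15, 16, "+", "C")
  e <- firstEffect(classifyVariant(v, toy$ann, toy$ref, PARAMS))
  expect_equal(e@predictedProtein, "")
  expect_true("start_lost" %in% e@notes)

  ## stop loss: TAA -> CAA reads through into the 3' UTR (GGGGG, no stop)
  v <- queryVariant("stl", 47, 48, "+", "C")
  e <- firstEffect(classifyVariant(v, toy$ann, toy$ref, PARAMS))
  expect_true("stop_lost" %in% e@notes)
  expect_equal(substr(e@predictedProtein, 1, 4), "MNGC")
  expect_gt(nchar(e@predictedProtein), 4L)

  ## multi-codon block substitution: class omitted, note attached
  v <- queryVariant("mc", 20, 22, "+", "CC")  # CDS bases 6-7: codons 2 and 3
  e <- firstEffect(classifyVariant(v, toy$ann, toy$ref, PARAMS))
  expect_true(is.na(e@substitutionClass))
  expect_true("multi_codon_substitution" %in% e@notes)
  expect_equal(nchar(e@predictedProtein), 4L)

  ## everything mirrors on the minus strand
  toyM <- makeToyGene("-")
  s <- regionLength(toyM$ref)
  vM <- queryVariant("synM", s - 21, s - 20, "+", "G")
  e <- firstEffect(classifyVariant(vM, toyM$ann, toyM$ref, PARAMS))
  expect_equal(e@substitutionClass, "synonymous")
  expect_equal(e@predictedProtein, toy$protein)
  expect_equal(e@cdsPosition, 6L)
})

test_that("reference translation fidelity holds across seeded fixtures", {
  for (seed in c(2, 8, 21)) {
    fx <- generateFixture(fixtureSpec(seed = seed))
    for (tr in transcripts(fx$ann)) {
      cds <- splicedCdsSequence(tr, fx$ref)
      expect_equal(substr(cds, 1, 3), "ATG")
      expect_equal(nchar(cds) %% 3, 0)
      expect_equal(translateCds(cds)$protein,
                   unname(fx$proteins[[tr@transcriptId]]))
    }
  }
})
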