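# Hand-built two-exon toy gene with fully known coordinates, used by the
# unit tests so that every expected value can be counted by hand.
#
# layout (0-space):
#   0..10   pad "AAAAAAAAAA"
#   10..22  exon1 = 5' UTR "CCCCC" + CDS bases 1-7 "ATGAATG"
#   22..42  intron (20 x T)
#   42..55  exon2 = CDS bases 8-15 "GCTGCTAA" + 3' UTR "GGGGG"
#   55..65  pad "AAAAAAAAAA"
# CDS span (15, 50); spliced CDS "ATGAATGGCTGCTAA"; protein "MNGC".
makeToyGene <- function(strand = "+") {
  seq <- paste0("AAAAAAAAAA", "CCCCCATGAATG", strrep("T", 20),
                "GCTGCTAAGGGGG", "AAAAAAAAAA")
  exons <- matrix(c(10L, 22L, 42L, 55L), 2, 2, byrow = TRUE,
                  dimnames = list(NULL, c("begin", "end")))
  cds <- c(15L, 50L)
  if (strand == "-") {
    s <- nchar(seq)
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    exons <- matrix(c(s - exons[2, 2], s - exons[2, 1],
                      s - exons[1, 2], s - exons[1, 1]),
                    2, 2, byrow = TRUE,
                    dimnames = list(NULL, c("begin", "end")))
    cds <- c(s - 50L, s - 15L)
  }
  ref <- referenceRegion(seq, name = "toy")
  tr <- new("TranscriptModel", transcriptId = "t1", strand = strand,
            exons = exons, cdsSpan = cds, proteinId = "t1_p")
  gene <- new("GeneModel", geneId = "g1", strand = strand,
              span = c(min(exons[, 1]), max(exons[, 2])),
              transcripts = list(tr))
  domains <- data.frame(transcript_id = "t1", domain_name = "dom1",
                        aa_begin = 2L, aa_end = 3L, stringsAsFactors = FALSE)
  ann <- annotationSet(genes = list(gene), domains = domains)
  list(ref = ref, ann = ann, tr = tr, gene = gene, protein = "MNGC",
       cds = "ATGAATGGCTGCTAA")
}

# Mirror a fixture end-to-end: reverse-complement the sequence, map every
# interval (b, e) -> (s - e, s - b) and flip strands.  Amino-acid (domain)
# coordinates are orientation-free and stay put.
mirrorFixture <- function(fx) {
  s <- regionLength(fx$ref)
  seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(regionSequence(fx$ref))))
  flipStrand <- function(x) if (x == "+") "-" else "+"
  genes <- lapply(fx$ann@genes, function(g) {
    trs <- lapply(g@transcripts, function(tr) {
      ex <- cbind(begin = s - tr@exons[, 2], end = s - tr@exons[, 1])
      ex <- ex[order(ex[, 1]), , drop = FALSE]
      storage.mode(ex) <- "integer"
      new("TranscriptModel", transcriptId = tr@transcriptId,
          strand = flipStrand(tr@strand), exons = ex,
          cdsSpan = if (length(tr@cdsSpan))
            as.integer(c(s - tr@cdsSpan[2], s - tr@cdsSpan[1]))
          else integer(),
          proteinId = tr@proteinId)
    })
    new("GeneModel", geneId = g@geneId, strand = flipStrand(g@strand),
        span = as.integer(c(s - g@span[2], s - g@span[1])),
        transcripts = trs)
  })
  rep2 <- fx$ann@repeats
  if (nrow(rep2)) {
    tmp <- rep2$begin
    rep2$begin <- s - rep2$end; rep2$end <- s - tmp
  }
  kn2 <- fx$ann@known
  if (nrow(kn2)) {
    tmp <- kn2$begin
    kn2$begin <- s - kn2$end; kn2$end <- s - tmp
  }
  list(ref = referenceRegion(seq, name = "mirrored"),
       ann = annotationSet(genes = genes, domains = fx$ann@domains,
                           repeats = rep2, known = kn2),
       proteins = fx$proteins, spec = fx$spec)
}

# First TranscriptEffect found in a tree (tests use single-gene contexts).
firstEffect <- function(tree) {
  for (gb in geneBranches(tree)) for (tb in gb@transcriptBranches)
    if (!is.null(tb@effect)) return(tb@effect)
  NULL
}

firstBranch <- function(tree) {
  for (gb in geneBranches(tree)) for (tb in gb@transcriptBranches)
    return(tb)
  NULL
}

# shared default parameters (packaged BLOSUM30), parsed once per test run
PARAMS <- classifierParams()

classifyAt <- function(p, fx, allele = "C", params = PARAMS) {
  classifyVariant(queryVariant("q", p, p + 1L, "+", allele),
                  fx$ann, fx$ref, params)
}
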