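test_that("gene context resolves promoter/downstream windows and distances", {
  ## plus-strand transcript whose first exon begins at 2000
  ex <- matrix(c(2000L, 2200L, 2400L, 2600L), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("begin", "end")))
  trP <- new("TranscriptModel", transcriptId = "tp", strand = "+",
             exons = ex, cdsSpan = integer())
  ctx <- geneContext(queryVariant("v", 1500, 1501, "+", "A"), trP, PARAMS)
  expect_equal(ctx$kind, "upstream_promoter")
  expect_equal(ctx$distance, 499L)  # 0-space gap 1501..2000

  ## the 1000th upstream base is still promoter; the 1001st is outside
  expect_equal(geneContext(queryVariant("v", 1000, 1001, "+", "A"),
                           trP, PARAMS)$kind, "upstream_promoter")
  expect_equal(geneContext(queryVariant("v", 999, 1000, "+", "A"),
                           trP, PARAMS)$kind, "outside")

  ## downstream mirror on the plus strand
  ctx2 <- geneContext(queryVariant("v", 2700, 2701, "+", "A"), trP, PARAMS)
  expect_equal(ctx2$kind, "downstream_transcript")
  expect_equal(ctx2$distance, 100L)

  ## minus strand: upstream promoter lies to the RIGHT of the last exon
  trM <- new("TranscriptModel", transcriptId = "tm", strand = "-",
             exons = ex, cdsSpan = integer())
  ctx3 <- geneContext(queryVariant("v", 2700, 2701, "+", "A"), trM, PARAMS)
  expect_equal(ctx3$kind, "upstream_promoter")
  expect_equal(ctx3$distance, 100L)
  expect_equal(geneContext(queryVariant("v", 1500, 1501, "+", "A"),
                           trM, PARAMS)$kind, "downstream_transcript")

  ## overlap with the exon envelope is "within", even between exons
  expect_equal(geneContext(queryVariant("v", 2300, 2301, "+", "A"),
                           trP, PARAMS)$kind, "within")
})

test_that("transcript context separates intronic and exonic, spans get both", {
  toy <- makeToyGene()
  tr <- toy$tr
  expect_equal(transcriptContext(queryVariant("v", 30, 31, "+", "A"),
                                 tr)$labels, "intronic")
  expect_equal(transcriptContext(queryVariant("v", 12, 13, "+", "A"),
                                 tr)$labels, "exonic")
  ## deletion spanning exon1/intron boundary reports both, with a note
  span <- transcriptContext(queryVariant("v", 20, 25, "+", ""), tr)
  expect_setequal(span$labels, c("exonic", "intronic"))
  expect_true("exon_intron_boundary" %in% span$notes)
  ## intronic distance is the 0-space gap to the nearest exon
  expect_equal(transcriptContext(queryVariant("v", 30, 31, "+", "A"),
                                 tr)$distance, 8L)   # min(30-22, 42-31)
  expect_equal(transcriptContext(queryVariant("v", 22, 23, "+", "A"),
                                 tr)$distance, 0L)
})

test_that("splice windows are closed, 1-based and strand-aware", {
  toy <- makeToyGene()
  tr <- toy$tr  # intron (22, 42), 20 bases
  donorAt <- function(o) spliceSiteClass(
    queryVariant("v", 22 + o - 1L, 22 + o, "+", "A"), tr, PARAMS)
  expect_equal(donorAt(1), "five_prime_splice_site")
  expect_equal(donorAt(10), "five_prime_splice_site")
  expect_length(donorAt(11), 0L)
  acceptorAt <- function(o) spliceSiteClass(
    queryVariant("v", 42 - o, 42 - o + 1L, "+", "A"), tr, PARAMS)
  expect_equal(acceptorAt(1), "three_prime_splice_site")
  expect_equal(acceptorAt(6), "three_prime_splice_site")
  expect_length(acceptorAt(7), 0L)

  ## minus strand: donor window sits LEFT of an exon's left edge
  toyM <- makeToyGene("-")
  trM <- toyM$tr
  introns <- VariantHierarchy:::.txIntrons(trM)
  ib <- introns[1, 1]; ie <- introns[1, 2]
  expect_equal(spliceSiteClass(queryVariant("v", ie - 3, ie - 2, "+", "A"),
                               trM, PARAMS), "five_prime_splice_site")
  expect_equal(spliceSiteClass(queryVariant("v", ib + 2, ib + 3, "+", "A"),
                               trM, PARAMS), "three_prime_splice_site")

  ## an intron shorter than both windows attaches both labels
  trShort <- new("TranscriptModel", transcriptId = "ts", strand = "+",
                 exons = matrix(c(0L, 10L, 18L, 30L), 2, 2, byrow = TRUE,
                                dimnames = list(NULL, c("begin", "end"))),
                 cdsSpan = integer())
  expect_setequal(
    spliceSiteClass(queryVariant("v", 14, 15, "+", "A"), trShort, PARAMS),
    c("five_prime_splice_site", "three_prime_splice_site"))
})

test_that("exon subregions split at the CDS span and mirror with strand", {
  toy <- makeToyGene()
  tr <- toy$tr  # cds (15, 50)
  expect_equal(exonSubregion(queryVariant("v", 12, 13, "+", "A"), tr),
               "five_prime_UTR")
  expect_equal(exonSubregion(queryVariant("v", 16, 17, "+", "A"), tr),
               "CDS")
  expect_equal(exonSubregion(queryVariant("v", 51, 52, "+", "A"), tr),
               "three_prime_UTR")
  ## block substitution straddling the UTR/CDS boundary: both labels
  expect_setequal(exonSubregion(queryVariant("v", 13, 17, "+", "AAAA"), tr),
                  c("five_prime_UTR", "CDS"))
  ## insertion point exactly at the CDS start attaches to both sides
  expect_setequal(exonSubregion(queryVariant("v", 15, 15, "+", "AAA"), tr),
                  c("five_prime_UTR", "CDS"))

  ## minus strand: positions right of cds end are 5' UTR
  toyM <- makeToyGene("-")
  trM <- toyM$tr
  s <- regionLength(toyM$ref)
  expect_equal(exonSubregion(queryVariant("v", s - 13, s - 12, "+", "A"),
                             trM), "five_prime_UTR")
  expect_equal(exonSubregion(queryVariant("v", s - 52, s - 51, "+", "A"),
                             trM), "three_prime_UTR")

  ## transcript without CDS: noncoding exon
  trNc <- new("TranscriptModel", transcriptId = "nc", strand = "+",
              exons = toy$tr@exons, cdsSpan = integer())
  expect_equal(exonSubregion(queryVariant("v", 16, 17, "+", "A"), trNc),
               "noncoding_exon")
})

test_that("classify assembles the full tree with known/repeat first", {
  toy <- makeToyGene()
  known <- data.frame(begin = 16L, end = 17L, dbsnp_id = "rs123",
                      stringsAsFactors = FALSE)
  reps <- data.frame(begin = 0L, end = 30L, repeat_name = "rep1",
                     stringsAsFactors = FALSE)
  ann <- annotationSet(genes = list(toy$gene),
                       domains = proteinDomains(toy$ann),
                       repeats = reps, known = known)
  tree <- classifyVariant(queryVariant("v", 16, 17, "+", "C"), ann,
                          toy$ref, PARAMS)
  expect_equal(knownIds(tree), "rs123")
  expect_equal(repeatNames(tree), "rep1")
  expect_false(isIntergenic(tree))
  br <- firstBranch(tree)
  expect_equal(br@regionLabels, "exonic")
  expect_equal(br@exonSublabels, "CDS")
  expect_false(is.null(br@effect))

  ## a SNP far from everything is intergenic with no branches
  tree2 <- classifyAt(62, list(ann = annotationSet(), ref = toy$ref))
  expect_true(isIntergenic(tree2))
  expect_length(geneBranches(tree2), 0L)
})

test_that("every in-range variant gets an exhaustive classification", {
  fx <- generateFixture(fixtureSpec(seed = 5))
  set.seed(9)
  ps <- sample(0:(regionLength(fx$ref) - 2L), 150)
  for (p in ps) {
    tree <- classifyAt(p, fx)
    expect_equal(isIntergenic(tree), length(geneBranches(tree)) == 0L)
    for (gb in geneBranches(tree))
      for (tb in gb@transcriptBranches) {
        expect_true(tb@contextKind %in%
          c("within", "upstream_promoter", "downstream_transcript"))
        if (tb@contextKind == "within")
          expect_gt(length(tb@regionLabels), 0L)
        else
          expect_false(is.na(tb@distanceToExon))
      }
  }
})

test_that("moving a SNP away from an exon crosses each window exactly once", {
  toy <- makeToyGene()
  fx <- list(ann = toy$ann, ref = toy$ref)
  donorLabels <- vapply(1:20, function(o) {
    tb <- firstBranch(classifyAt(22 + o - 1L, fx))
    "five_prime_splice_site" %in% tb@spliceLabels
  }, TRUE)
  expect_equal(donorLabels, c(rep(TRUE, 10), rep(FALSE, 10)))
  expect_equal(sum(diff(donorLabels) != 0), 1L)

  ## promoter window: single transition at the configured edge
  params <- classifierParams(promoterWindow = 8L)
  promoter <- vapply(1:10, function(k) {
    tb <- firstBranch(classifyVariant(
      queryVariant("v", 10 - k, 10 - k + 1L, "+", "A"),
      toy$ann, toy$ref, params))
    !is.null(tb) && tb@contextKind == "upstream_promoter"
  }, TRUE)
  expect_equal(promoter, c(rep(TRUE, 8), rep(FALSE, 2)))
})

test_that("mirrored fixtures yield mirrored classifications", {
  fx <- generateFixture(fixtureSpec(seed = 13))
  mfx <- mirrorFixture(fx)
  s <- regionLength(fx$ref)
  for (p in seq(0, s - 1L, by = 17)) {
    orig <- labelSet(classifyAt(p, fx, allele = "A"))
    mirr <- labelSet(classifyAt(s - p - 1L, mfx, allele = "T"))
    expect_identical(mirr, orig)
  }
})

test_that("a variant in two overlapping feature contexts reports both", {
  ## gene A's exon overlaps gene B's promoter window
  exA <- matrix(c(100L, 300L), 1, 2, dimnames = list(NULL, c("begin", "end")))
  exB <- matrix(c(500L, 700L), 1, 2, dimnames = list(NULL, c("begin", "end")))
  gA <- new("GeneModel", geneId = "gA", strand = "+", span = c(100L, 300L),
            transcripts = list(new("TranscriptModel", transcriptId = "tA",
                                   strand = "+", exons = exA,
                                   cdsSpan = integer())))
  gB <- new("GeneModel", geneId = "gB", strand = "+", span = c(500L, 700L),
            transcripts = list(new("TranscriptModel", transcriptId = "tB",
                                   strand = "+", exons = exB,
                                   cdsSpan = integer())))
  ann <- annotationSet(genes = list(gA, gB))
  ref <- referenceRegion(strrep("ACGT", 250))
  ls <- labelSet(classifyVariant(queryVariant("v", 200, 201, "+", "C"),
                                 ann, ref, PARAMS))
  expect_true("gA:tA:exonic" %in% ls)
  expect_true("gB:tB:upstream_promoter" %in% ls)
})
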