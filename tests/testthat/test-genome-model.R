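test_that("FASTA reader uppercases, masks non-ACGTN and sets the length", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">roi some description", "acgtACGT", "NNAA"), fa)
  ref <- readReferenceFasta(fa)
  expect_equal(regionLength(ref), 12L)
  expect_equal(regionSequence(ref), "ACGTACGTNNAA")
  expect_equal(ref@name, "roi")

  writeLines(c(">r", "ACGTRY"), fa)
  expect_warning(ref2 <- readReferenceFasta(fa), "2 non-ACGTN")
  expect_equal(regionSequence(ref2), "ACGTNN")

  writeLines(c(">empty", ""), fa)
  expect_error(readReferenceFasta(fa), "zero-length|empty")
})

test_that("annotation TSV parses hierarchies and rejects broken parents", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "feature_type\tfeature_id\tparent_id\tbegin\tend\tstrand\tattributes",
    "gene\tg1\t\t100\t400\t+\t",
    "transcript\tt1\tg1\t100\t400\t+\t",
    "exon\t\tt1\t100\t200\t+\t",
    "exon\t\tt1\t300\t400\t+\t",
    "cds\t\tt1\t150\t350\t+\t",
    "repeat\t\t\t10\t60\t\tname=AluY",
    "known_variant\trs99\t\t120\t121\t\t"), tsv)
  ann <- readAnnotationTsv(tsv)
  expect_length(genes(ann), 1L)
  tr <- transcripts(ann)[["t1"]]
  expect_equal(nrow(tr@exons), 2L)
  expect_equal(tr@cdsSpan, c(150L, 350L))
  expect_equal(repeatFeatures(ann)$repeat_name, "AluY")
  expect_equal(knownVariants(ann)$dbsnp_id, "rs99")

  ## header-only file: zero features, classifier still runs (intergenic)
  writeLines("feature_type\tfeature_id\tparent_id\tbegin\tend\tstrand\tattributes",
             tsv)
  empty <- readAnnotationTsv(tsv)
  expect_length(genes(empty), 0L)
  ref <- referenceRegion(strrep("A", 500))
  tree <- classifyVariant(queryVariant("v", 5, 6, "+", "C"), empty, ref)
  expect_true(isIntergenic(tree))

  ## exon pointing at an absent transcript is fatal, naming the line
  writeLines(c(
    "feature_type\tfeature_id\tparent_id\tbegin\tend\tstrand\tattributes",
    "gene\tg1\t\t100\t400\t+\t",
    "exon\t\ttMISSING\t100\t200\t+\t"), tsv)
  expect_error(readAnnotationTsv(tsv), "line 3.*unknown transcript")

  ## inverted interval is fatal
  writeLines(c(
    "feature_type\tfeature_id\tparent_id\tbegin\tend\tstrand\tattributes",
    "gene\tg1\t\t400\t100\t+\t"), tsv)
  expect_error(readAnnotationTsv(tsv), "begin > end")
})

test_that("annotation TSV round-trips through write and re-read", {
  fx <- generateFixture(fixtureSpec(seed = 7))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotationTsv(fx$ann, tsv)
  ann2 <- readAnnotationTsv(tsv)
  expect_equal(length(genes(ann2)), length(genes(fx$ann)))
  for (tid in names(transcripts(fx$ann))) {
    a <- transcripts(fx$ann)[[tid]]; b <- transcripts(ann2)[[tid]]
    expect_identical(unname(a@exons), unname(b@exons))
    expect_identical(a@cdsSpan, b@cdsSpan)
    expect_identical(a@strand, b@strand)
  }
  expect_equal(proteinDomains(ann2), proteinDomains(fx$ann))
  expect_equal(repeatFeatures(ann2), repeatFeatures(fx$ann))
  expect_equal(knownVariants(ann2), knownVariants(fx$ann))
})

test_that("interval index agrees with a brute-force all-pairs scan", {
  fx <- generateFixture(fixtureSpec(seed = 3, repeatCount = 20,
                                    knownVariantCount = 20))
  s <- regionLength(fx$ref)
  reps <- repeatFeatures(fx$ann)
  set.seed(42)
  for (i in 1:1000) {
    b <- sample(0:(s - 1L), 1L)
    e <- b + sample(0:30, 1L)
    idx <- VariantHierarchy:::.overlapIndex(fx$ann@repeatIndex, b, e)
    brute <- which(vapply(seq_len(nrow(reps)), function(j)
      spanOverlap(b, e, reps$begin[j], reps$end[j]), TRUE))
    expect_identical(idx, brute)
  }
})

test_that("validateAnnotation reports range, exon and CDS violations", {
  toy <- makeToyGene()
  expect_equal(nrow(validateAnnotation(toy$ann, toy$ref)), 0L)

  ## exon beyond the reference
  bad <- new("TranscriptModel", transcriptId = "tb", strand = "+",
             exons = matrix(c(10L, 900L), 1, 2,
                            dimnames = list(NULL, c("begin", "end"))),
             cdsSpan = integer())
  g <- new("GeneModel", geneId = "gb", strand = "+", span = c(10L, 900L),
           transcripts = list(bad))
  v <- validateAnnotation(annotationSet(genes = list(g)), toy$ref)
  expect_true(any(grepl("out of range", v$message)))

  ## CDS whose concatenated length is 10: warning, not error
  tr <- new("TranscriptModel", transcriptId = "tc", strand = "+",
            exons = matrix(c(10L, 30L), 1, 2,
                           dimnames = list(NULL, c("begin", "end"))),
            cdsSpan = c(12L, 22L))
  g2 <- new("GeneModel", geneId = "gc", strand = "+", span = c(10L, 30L),
            transcripts = list(tr))
  v2 <- validateAnnotation(annotationSet(genes = list(g2)), toy$ref)
  expect_equal(v2$severity, "warning")
  expect_match(v2$message, "not a multiple of 3")
})

test_that("GFF3/BED adapter projects, clips and inverts correctly", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t1100\t.\t+\t.\tID=gX",
    "chr1\tsrc\tmRNA\t1001\t1100\t.\t+\t.\tID=tX;Parent=gX",
    "chr1\tsrc\texon\t1001\t1040\t.\t+\t.\tParent=tX",
    "chr1\tsrc\texon\t1061\t1100\t.\t+\t.\tParent=tX",
    "chr1\tsrc\tCDS\t1010\t1040\t.\t+\t0\tParent=tX",
    "chr1\tsrc\tCDS\t1061\t1090\t.\t+\t0\tParent=tX"), gff)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t1010\t1020\tAluY", bed)

  tsv <- gff3ToAnnotation(gff, "chr1", 1001L, 1200L, repeatsBed = bed)
  out <- withr::local_tempfile(fileext = ".tsv")
  writeLines(tsv, out)
  ann <- readAnnotationTsv(out)

  g <- genes(ann)[[1]]
  expect_equal(g@span, c(0L, 100L))          # 1001..1100 -> (0, 100)
  tr <- transcripts(ann)[["tX"]]
  expect_identical(unname(tr@exons),
                   matrix(c(0L, 40L, 60L, 100L), 2, 2, byrow = TRUE))
  expect_equal(tr@cdsSpan, c(9L, 90L))       # fragments normalized to a span
  ## BED is 0-based half-open: 1010..1020 in a region starting at 1001
  expect_equal(repeatFeatures(ann)$begin, 10L)
  expect_equal(repeatFeatures(ann)$end, 20L)

  ## projection inverse recovers genomic 1-based coordinates
  expect_equal(localToGenomic(0L, 100L, 1001L), c(1001L, 1100L))
  expect_equal(localToGenomic(9L, 90L, 1001L), c(1010L, 1090L))

  ## feature straddling the region's right edge is clipped with a warning
  w <- testthat::capture_warnings(
    tsv2 <- gff3ToAnnotation(gff, "chr1", 1001L, 1080L))
  expect_true(any(grepl("clipped", w)))
  writeLines(tsv2, out)
  ann2 <- readAnnotationTsv(out)
  expect_equal(max(transcripts(ann2)[["tX"]]@exons), 80L)

  ## region name absent from the GFF3 is fatal
  expect_error(gff3ToAnnotation(gff, "chrZ", 1L, 100L), "not found")
})

test_that("zero-width known features attach to both flanking bases", {
  ref <- referenceRegion(strrep("ACGT", 25))
  known <- data.frame(begin = 50L, end = 50L, dbsnp_id = "rs_ins",
                      stringsAsFactors = FALSE)
  ann <- annotationSet(known = known)
  expect_equal(knownIds(classifyVariant(queryVariant("a", 49, 50, "+", "T"),
                                        ann, ref)), "rs_ins")
  expect_equal(knownIds(classifyVariant(queryVariant("b", 50, 51, "+", "T"),
                                        ann, ref)), "rs_ins")
  expect_length(knownIds(classifyVariant(queryVariant("c", 48, 49, "+", "T"),
                                         ann, ref)), 0L)
})
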