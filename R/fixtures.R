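## Deterministic synthetic fixtures: annotated toy genomes whose CDSs are
## built codon-wise (ATG start, uniform sense codons, one terminal stop),
## so the generator's contracts — CDS length divisible by 3, no internal
## stop, stored protein == translation of the spliced CDS — hold by
## construction.

#' Fixture generator specification
#'
#' All sizes are in bases unless noted.  The defaults produce a compact
#' two-gene region (one gene per strand) whose intergenic pads exceed the
#' 1000-base promoter/downstream window and whose introns are long enough
#' (>= 40) that the 10-base donor and 6-base acceptor windows never
#' collide; `intronLength` can be lowered (to a minimum of 8) for
#' window-collision experiments.
#'
#' @param seed integer seed; the generator has no global random state.
#' @param regionLength minimum region length (padded with random sequence
#'   to at least this).
#' @param geneCount number of genes (one transcript each).
#' @param strandMix fraction of minus-strand genes; the trailing
#'   `round(geneCount * strandMix)` genes are minus-strand.
#' @param exonsPerTranscript integer range (min, max) of exons.
#' @param intronLength integer range of intron lengths (min >= 8).
#' @param utrLength integer range of 5'/3' UTR lengths.
#' @param cdsCodons integer range of CDS codon counts (incl. start and
#'   stop).
#' @param domainsPerProtein protein domains annotated per transcript.
#' @param repeatCount,knownVariantCount auxiliary feature counts.
#' @param upstreamPad bases of intergenic sequence before the first gene
#'   (>= 1601 leaves room for a full promoter-window sweep).
#' @param interGenePad integer range of pad between genes.
#' @param tailPad bases after the last gene.
#' @return a list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(seed = 1L, regionLength = 6000L, geneCount = 2L,
                        strandMix = 0.5, exonsPerTranscript = c(2L, 4L),
                        intronLength = c(40L, 80L), utrLength = c(15L, 50L),
                        cdsCodons = c(40L, 80L), domainsPerProtein = 2L,
                        repeatCount = 2L, knownVariantCount = 3L,
                        upstreamPad = 1700L, interGenePad = c(1300L, 1800L),
                        tailPad = 1300L) {
  spec <- list(seed = as.integer(seed),
               regionLength = as.integer(regionLength),
               geneCount = as.integer(geneCount), strandMix = strandMix,
               exonsPerTranscript = as.integer(exonsPerTranscript),
               intronLength = as.integer(intronLength),
               utrLength = as.integer(utrLength),
               cdsCodons = as.integer(cdsCodons),
               domainsPerProtein = as.integer(domainsPerProtein),
               repeatCount = as.integer(repeatCount),
               knownVariantCount = as.integer(knownVariantCount),
               upstreamPad = as.integer(upstreamPad),
               interGenePad = as.integer(interGenePad),
               tailPad = as.integer(tailPad))
  stopifnot(spec$geneCount >= 1L, spec$intronLength[1L] >= 8L,
            spec$cdsCodons[1L] >= 10L, spec$utrLength[1L] >= 5L,
            spec$exonsPerTranscript[1L] >= 1L,
            all(vapply(spec[vapply(spec, is.numeric, TRUE)],
                       function(x) all(x >= 0), TRUE)))
  class(spec) <- "FixtureSpec"
  spec
}

## Run code under an explicit seed without leaking global random state.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

.randSeq <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.SENSE_CODONS <-
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
.STOP_CODONS <-
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]

.rint <- function(range) if (range[1L] >= range[2L]) range[1L] else
  sample(range[1L]:range[2L], 1L)

## One gene built in coding orientation, then mirrored for minus strand.
## Returns block sequence (plus strand) and block-local 0-space intervals.
.buildGene <- function(spec, geneId, strand) {
  u5 <- .rint(spec$utrLength); u3 <- .rint(spec$utrLength)
  ncod <- .rint(spec$cdsCodons)
  internal <- paste(sample(.SENSE_CODONS, ncod - 2L, replace = TRUE),
                    collapse = "")
  coding <- paste0("ATG", internal, sample(.STOP_CODONS, 1L))
  spliced <- paste0(.randSeq(u5), coding, .randSeq(u3))
  L <- nchar(spliced)
  k <- .rint(spec$exonsPerTranscript)
  cuts <- integer()
  if (k > 1L) {
    for (i in 1:100) {
      cuts <- sort(sample(2L:(L - 2L), k - 1L))
      if (all(diff(c(0L, cuts, L)) >= 2L)) break
    }
  }
  bounds <- c(0L, cuts, L)                 # spliced-coordinate exon bounds
  intronLens <- if (k > 1L)
    vapply(seq_len(k - 1L), function(i) .rint(spec$intronLength), 1L)
  else integer()

  ## block coordinates in coding orientation
  exons <- matrix(0L, k, 2L, dimnames = list(NULL, c("begin", "end")))
  blockSeq <- character()
  pos <- 0L
  for (i in seq_len(k)) {
    w <- bounds[i + 1L] - bounds[i]
    exons[i, ] <- c(pos, pos + w)
    blockSeq <- c(blockSeq, substr(spliced, bounds[i] + 1L, bounds[i + 1L]))
    pos <- pos + w
    if (i < k) {
      blockSeq <- c(blockSeq, .randSeq(intronLens[i]))
      pos <- pos + intronLens[i]
    }
  }
  blockLen <- pos
  blockSeq <- paste(blockSeq, collapse = "")

  ## spliced coordinate -> block coordinate (coding orientation)
  splicedToBlock <- function(x, isEnd) {
    for (i in seq_len(k)) {
      inside <- if (isEnd) x > bounds[i] && x <= bounds[i + 1L]
                else x >= bounds[i] && x < bounds[i + 1L]
      if (inside) return(exons[i, 1L] + (x - bounds[i]))
    }
    stop("spliced coordinate out of range: ", x)
  }
  cds <- c(splicedToBlock(u5, FALSE), splicedToBlock(u5 + 3L * ncod, TRUE))

  if (strand == "-") {
    blockSeq <- .revComp(blockSeq)
    exons <- cbind(begin = blockLen - exons[, 2L],
                   end = blockLen - exons[, 1L])
    exons <- exons[order(exons[, 1L]), , drop = FALSE]
    cds <- c(blockLen - cds[2L], blockLen - cds[1L])
  }
  storage.mode(exons) <- "integer"
  list(seq = blockSeq, exons = exons, cds = as.integer(cds),
       proteinLen = ncod - 1L, blockLen = blockLen)
}

#' Generate a deterministic annotated toy genome
#'
#' For a fixed seed the generated FASTA/TSV outputs are byte-identical
#' across runs.  Every transcript's CDS starts with ATG, ends with a stop
#' codon, has length divisible by 3 and no internal stop, and the stored
#' reference protein equals the translation of its spliced CDS.
#'
#' @param spec a [fixtureSpec()].
#' @return list of class `VariantFixture` with elements `ref`
#'   ([ReferenceRegion-class]), `ann` ([AnnotationSet-class]), `proteins`
#'   (named character: reference protein per transcript) and `spec`.
#' @export
generateFixture <- function(spec = fixtureSpec()) {
  .withSeed(spec$seed, {
    nMinus <- round(spec$geneCount * spec$strandMix)
    strands <- c(rep("+", spec$geneCount - nMinus), rep("-", nMinus))
    chunks <- character()
    genes <- list()
    proteins <- character()
    domains <- .emptyDomains()
    pos <- spec$upstreamPad
    chunks <- c(chunks, .randSeq(spec$upstreamPad))
    for (i in seq_len(spec$geneCount)) {
      gid <- paste0("g", i); tid <- paste0("t", i)
      gb <- .buildGene(spec, gid, strands[i])
      exons <- gb$exons
      exons[, ] <- exons + pos
      cds <- gb$cds + pos
      tr <- new("TranscriptModel", transcriptId = tid, strand = strands[i],
                exons = exons, cdsSpan = cds,
                proteinId = paste0(tid, "_p"))
      genes[[gid]] <- new("GeneModel", geneId = gid, strand = strands[i],
                          span = c(min(exons[, 1L]), max(exons[, 2L])),
                          transcripts = list(tr))
      for (d in seq_len(spec$domainsPerProtein)) {
        w <- .rint(c(5L, min(15L, gb$proteinLen - 2L)))
        a <- .rint(c(2L, gb$proteinLen - w))
        domains <- rbind(domains, data.frame(
          transcript_id = tid,
          domain_name = sprintf("PF%02d%02d", i, d),
          aa_begin = a, aa_end = a + w - 1L, stringsAsFactors = FALSE))
      }
      chunks <- c(chunks, gb$seq)
      pos <- pos + gb$blockLen
      pad <- if (i < spec$geneCount) .rint(spec$interGenePad) else
        spec$tailPad
      chunks <- c(chunks, .randSeq(pad))
      pos <- pos + pad
    }
    if (pos < spec$regionLength) {
      chunks <- c(chunks, .randSeq(spec$regionLength - pos))
      pos <- spec$regionLength
    }
    seq <- paste(chunks, collapse = "")
    stopifnot(nchar(seq) == pos)

    repeats <- .emptyRepeats()
    for (i in seq_len(spec$repeatCount)) {
      w <- .rint(c(50L, 120L))
      b <- .rint(c(0L, pos - w))
      repeats <- rbind(repeats, data.frame(
        begin = b, end = b + w, repeat_name = paste0("rep", i),
        stringsAsFactors = FALSE))
    }
    known <- .emptyKnown()
    for (i in seq_len(spec$knownVariantCount)) {
      b <- .rint(c(0L, pos - 1L))
      known <- rbind(known, data.frame(
        begin = b, end = b + 1L, dbsnp_id = paste0("rs", 1000L + i),
        stringsAsFactors = FALSE))
    }

    ref <- referenceRegion(seq, name = paste0("fixture_seed", spec$seed))
    names(genes) <- NULL
    ann <- annotationSet(genes = genes, domains = domains,
                         repeats = repeats, known = known)
    for (tr in transcripts(ann))
      proteins[[tr@transcriptId]] <-
        translateCds(splicedCdsSequence(tr, ref))$protein
    viol <- validateAnnotation(ann, ref)
    stopifnot(!any(viol$severity == "error"))
    structure(list(ref = ref, ann = ann, proteins = proteins, spec = spec),
              class = "VariantFixture")
  })
}

#' @export
print.VariantFixture <- function(x, ...) {
  cat("VariantFixture (seed ", x$spec$seed, "): region of ",
      regionLength(x$ref), " bp\n", sep = "")
  show(x$ann)
  invisible(x)
}

#' Write a fixture's FASTA and annotation TSV
#'
#' Emits the same dialects the classifier reads, so the generator
#' round-trips through the package's own parsers.
#'
#' @param fixture a [generateFixture()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "region.fa")
  writeLines(c(paste0(">", fixture$ref@name),
               regionSequence(fixture$ref)), fa)
  tsv <- file.path(dir, "annotation.tsv")
  writeAnnotationTsv(fixture$ann, tsv)
  c(fasta = fa, annotation = tsv)
}

.altBase <- function(b, avoid = b)
  setdiff(c("A", "C", "G", "T"), avoid)[1L]

.FOURFOLD_PREFIX <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

#' Generate a variant panel covering every leaf of the decision tree
#'
#' Constructs, on a fixture's first plus-strand coding gene, at least one
#' variant per classification leaf — intergenic; promoter at upstream base
#' distances 1/500/1000/1001; downstream; plain intronic; donor offsets
#' 1/10/11; acceptor offsets 1/6/7; 5' and 3' UTR; synonymous,
#' non-synonymous conserved and unconserved, and stop-gain substitutions;
#' in-frame and frameshift deletions; a domain-overlapping substitution —
#' each with its expected labels computed by construction.
#'
#' @param fixture a [generateFixture()] result whose first gene is
#'   plus-strand, has >= 2 exons and introns of length >= 18, and at least
#'   1002 bases of intergenic sequence upstream (the defaults guarantee
#'   this).
#' @param matrix substitution matrix used to *choose* the conserved /
#'   unconserved example pairs (default packaged BLOSUM30).
#' @return data.frame with the variant TSV columns (`variant_id`, `begin`,
#'   `end`, `orientation`, `allele`) plus `expect_present` and
#'   `expect_absent` (comma-joined label sets in the [labelSet()]
#'   vocabulary) and `expected_protein` (`""` when not asserted).
#' @export
generateVariantPanel <- function(fixture, matrix = readSubstitutionMatrix()) {
  ann <- fixture$ann; ref <- fixture$ref
  g <- NULL
  for (cand in ann@genes) {
    tr0 <- cand@transcripts[[1L]]
    introns <- .txIntrons(tr0)
    if (cand@strand == "+" && nrow(tr0@exons) >= 2L &&
        nrow(introns) >= 1L &&
        all(introns[, 2L] - introns[, 1L] >= 18L) &&
        min(tr0@exons[, 1L]) >= 1002L) { g <- cand; break }
  }
  if (is.null(g))
    stop("fixture has no plus-strand multi-exon gene with upstream room",
         call. = FALSE)
  tr <- g@transcripts[[1L]]
  pre <- paste0(g@geneId, ":", tr@transcriptId, ":")
  env <- .txEnvelope(tr)
  introns <- .txIntrons(tr)
  seq <- regionSequence(ref)
  refBase <- function(p) substr(seq, p + 1L, p + 1L)
  refCds <- splicedCdsSequence(tr, ref)
  refProt <- fixture$proteins[[tr@transcriptId]]
  nAa <- nchar(refProt)

  rows <- list()
  snp <- function(id, p, allele, present, absent = "", protein = "")
    rows[[length(rows) + 1L]] <<- data.frame(
      variant_id = id, begin = p, end = p + 1L, orientation = "+",
      allele = allele, expect_present = present, expect_absent = absent,
      expected_protein = protein, stringsAsFactors = FALSE)
  lastEnd <- max(vapply(ann@genes, function(x) x@span[2L], 1L))

  snp("intergenic", lastEnd + 1050L, .altBase(refBase(lastEnd + 1050L)),
      "intergenic")
  for (k in c(1L, 500L, 1000L)) {
    p <- env[1L] - k
    snp(paste0("promoter_", k), p, .altBase(refBase(p)),
        paste0(pre, "upstream_promoter"))
  }
  p <- env[1L] - 1001L
  snp("promoter_1001", p, .altBase(refBase(p)), "intergenic",
      paste0(pre, "upstream_promoter"))
  p <- env[2L] + 49L  # 50th base downstream of the last exon
  snp("downstream_50", p, .altBase(refBase(p)),
      paste0(pre, "downstream_transcript"))

  ib <- introns[1L, 1L]; ie <- introns[1L, 2L]
  mid <- ib + (ie - ib) %/% 2L
  snp("intronic_mid", mid, .altBase(refBase(mid)),
      paste0(pre, "intronic"),
      paste(paste0(pre, c("five_prime_splice_site",
                          "three_prime_splice_site")), collapse = ","))
  for (o in c(1L, 10L)) {
    p <- ib + o - 1L
    snp(paste0("donor_", o), p, .altBase(refBase(p)),
        paste0(pre, "intronic,", pre, "five_prime_splice_site"))
  }
  p <- ib + 10L
  snp("donor_11", p, .altBase(refBase(p)), paste0(pre, "intronic"),
      paste0(pre, "five_prime_splice_site"))
  for (o in c(1L, 6L)) {
    p <- ie - o
    snp(paste0("acceptor_", o), p, .altBase(refBase(p)),
        paste0(pre, "intronic,", pre, "three_prime_splice_site"))
  }
  p <- ie - 7L
  snp("acceptor_7", p, .altBase(refBase(p)), paste0(pre, "intronic"),
      paste0(pre, "three_prime_splice_site"))

  snp("utr5", env[1L], .altBase(refBase(env[1L])),
      paste0(pre, "exonic,", pre, "five_prime_UTR"))
  snp("utr3", env[2L] - 1L, .altBase(refBase(env[2L] - 1L)),
      paste0(pre, "exonic,", pre, "three_prime_UTR"))

  codon <- function(a) substr(refCds, 3L * a - 2L, 3L * a)
  aaOf <- function(cod) unname(GENETIC_CODE[cod])
  ## scan codons/positions for the constructed coding substitutions
  syn <- cons <- uncons <- stopgain <- NULL
  for (a in 2:nAa) {
    cod <- codon(a)
    for (posInCodon in 1:3) {
      for (alt in setdiff(c("A", "C", "G", "T"),
                          substr(cod, posInCodon, posInCodon))) {
        altCod <- cod
        substr(altCod, posInCodon, posInCodon) <- alt
        refAa <- aaOf(cod); altAa <- aaOf(altCod)
        cdsIdx <- 3L * (a - 1L) + posInCodon
        hit <- list(a = a, cdsIdx = cdsIdx, alt = alt, refAa = refAa,
                    altAa = altAa)
        if (is.null(syn) && altAa == refAa) syn <- hit
        else if (altAa == "*" && refAa != "*") {
          if (is.null(stopgain)) stopgain <- hit
        } else if (altAa != refAa && refAa != "*" && altAa != "*") {
          if (matrix[refAa, altAa] >= 0 && is.null(cons)) cons <- hit
          if (matrix[refAa, altAa] < 0 && is.null(uncons)) uncons <- hit
        }
      }
    }
    if (!is.null(syn) && !is.null(cons) && !is.null(uncons) &&
        !is.null(stopgain)) break
  }
  addCodingSnp <- function(id, hit, extraPresent = "", protein = "") {
    p <- cdsToGenomic(hit$cdsIdx, tr)
    snp(id, p, hit$alt,
        paste0(pre, "exonic,", pre, "CDS",
               if (nzchar(extraPresent)) paste0(",", extraPresent)),
        protein = protein)
  }
  if (!is.null(syn))
    addCodingSnp("cds_synonymous", syn, protein = refProt)
  if (!is.null(cons)) addCodingSnp("cds_nonsyn_conserved", cons)
  if (!is.null(uncons)) addCodingSnp("cds_nonsyn_unconserved", uncons)
  if (!is.null(stopgain))
    addCodingSnp("cds_stop_gain", stopgain,
                 protein = substr(refProt, 1L, stopgain$a - 1L))

  ## an internal codon whose three bases are genomically consecutive
  del <- NULL
  for (a in 3:(nAa - 1L)) {
    g1 <- cdsToGenomic(3L * a - 2L, tr)
    if (cdsToGenomic(3L * a, tr) == g1 + 2L) { del <- list(a = a, g = g1);
      break }
  }
  if (!is.null(del)) {
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = "cds_inframe_del", begin = del$g, end = del$g + 3L,
      orientation = "+", allele = "",
      expect_present = paste0(pre, "exonic,", pre, "CDS"),
      expect_absent = "",
      expected_protein = paste0(substr(refProt, 1L, del$a - 1L),
                                substr(refProt, del$a + 1L, nAa)),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = "cds_frameshift_del", begin = del$g, end = del$g + 1L,
      orientation = "+", allele = "",
      expect_present = paste0(pre, "exonic,", pre, "CDS"),
      expect_absent = "", expected_protein = "", stringsAsFactors = FALSE)
  }

  dom <- ann@domains[ann@domains$transcript_id == tr@transcriptId, ,
                     drop = FALSE]
  if (nrow(dom)) {
    a <- dom$aa_begin[1L]
    p <- cdsToGenomic(3L * a - 2L, tr)
    snp("domain_overlap", p, .altBase(refBase(p)),
        paste0(pre, "exonic,", pre, "CDS"))
    rows[[length(rows)]]$expected_domain <- dom$domain_name[1L]
  }
  panel <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$expected_domain)) r$expected_domain <- ""
    r
  }))
  rownames(panel) <- NULL
  panel
}
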