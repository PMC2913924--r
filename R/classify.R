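#' Construct classifier parameters
#'
#' @param promoterWindow upstream-promoter / downstream-transcript window
#'   in bases (default 1000).
#' @param donorWindow 5'-splice-site (donor) window in intronic bases,
#'   coding orientation (default 10).
#' @param acceptorWindow 3'-splice-site (acceptor) window in intronic
#'   bases (default 6).
#' @param flankLen reported flanking-sequence length (default 50).
#' @param matrix amino-acid substitution matrix (default: packaged
#'   BLOSUM30 via [readSubstitutionMatrix()]).
#' @return a [ClassifierParams-class].
#' @export
classifierParams <- function(promoterWindow = 1000L, donorWindow = 10L,
                             acceptorWindow = 6L, flankLen = 50L,
                             matrix = NULL) {
  if (is.null(matrix)) matrix <- readSubstitutionMatrix()
  new("ClassifierParams", promoterWindow = as.integer(promoterWindow),
      donorWindow = as.integer(donorWindow),
      acceptorWindow = as.integer(acceptorWindow),
      flankLen = as.integer(flankLen), matrix = matrix)
}

## Exon envelope of a transcript: (first exon begin, last exon end).
.txEnvelope <- function(transcript)
  c(min(transcript@exons[, 1L]), max(transcript@exons[, 2L]))

#' Gene-level context of a variant on one transcript
#'
#' Resolves whether the variant overlaps the transcript's exon envelope
#' (`"within"`), falls in the upstream promoter window (up to
#' `promoterWindow` bases 5' of the first exon in coding orientation), in
#' the downstream transcript window (the mirror region 3' of the last
#' exon), or is outside all of these.  "First exon" is the 5'-most exon on
#' the transcript's strand, so the promoter of a minus-strand transcript
#' lies to the right of its rightmost exon.  The window test asks whether
#' the variant's nearest base is among the `promoterWindow` bases abutting
#' the envelope; the reported distance is the 0-space gap between the
#' variant span and the envelope (an abutting SNP has gap 0).
#'
#' @param v a [QueryVariant-class].
#' @param transcript a [TranscriptModel-class].
#' @param params a [ClassifierParams-class].
#' @return list with `kind` (`"within"`, `"upstream_promoter"`,
#'   `"downstream_transcript"` or `"outside"`) and `distance` (0-space
#'   gap in bases, `NA` for `"within"`).
#' @export
geneContext <- function(v, transcript, params = classifierParams()) {
  env <- .txEnvelope(transcript)
  if (spanOverlap(v@begin, v@end, env[1L], env[2L]))
    return(list(kind = "within", distance = NA_integer_))
  onLeft <- v@end <= env[1L]
  gap <- if (onLeft) env[1L] - v@end else v@begin - env[2L]
  upstreamSide <- if (transcript@strand == "+") onLeft else !onLeft
  if (gap + 1L > params@promoterWindow)
    return(list(kind = "outside", distance = as.integer(gap)))
  list(kind = if (upstreamSide) "upstream_promoter"
       else "downstream_transcript",
       distance = as.integer(gap))
}

## Intron intervals (0-space) of a transcript, ascending.
.txIntrons <- function(transcript) {
  ex <- transcript@exons
  if (nrow(ex) < 2L)
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("begin", "end"))))
  out <- cbind(begin = ex[-nrow(ex), 2L], end = ex[-1L, 1L])
  storage.mode(out) <- "integer"
  out
}

#' Intronic / exonic context of a variant within a transcript
#'
#' For a variant overlapping the transcript's exon envelope: `"exonic"`
#' when it touches any exon, `"intronic"` when it touches any intron, both
#' (with an `"exon_intron_boundary"` note) when it spans a boundary.  For
#' intronic variants the 0-space gap to the nearest exon boundary is
#' reported.
#'
#' @param v a [QueryVariant-class].
#' @param transcript a [TranscriptModel-class].
#' @return list with `labels` (subset of `c("exonic", "intronic")`),
#'   `distance` (gap to nearest exon for intronic variants, else `NA`) and
#'   `notes`.
#' @export
transcriptContext <- function(v, transcript) {
  ex <- transcript@exons
  introns <- .txIntrons(transcript)
  exonic <- any(spanOverlap(v@begin, v@end, ex[, 1L], ex[, 2L]))
  intronHits <- if (nrow(introns))
    which(spanOverlap(v@begin, v@end, introns[, 1L], introns[, 2L]))
  else integer()
  labels <- c(if (exonic) "exonic", if (length(intronHits)) "intronic")
  notes <- if (exonic && length(intronHits)) "exon_intron_boundary"
           else character()
  distance <- NA_integer_
  if (length(intronHits)) {
    d <- vapply(intronHits, function(i) {
      min(max(0L, v@begin - introns[i, 1L]),
          max(0L, introns[i, 2L] - v@end))
    }, 1L)
    distance <- as.integer(min(d))
  }
  list(labels = labels, distance = distance, notes = notes)
}

#' Splice-site windows for an intronic variant
#'
#' An intronic variant is a 5' splice site (donor) when it lies within
#' `donorWindow` intronic bases immediately downstream — in coding
#' orientation — of the preceding exon, and a 3' splice site (acceptor)
#' when within `acceptorWindow` intronic bases immediately upstream of the
#' following exon.  Offsets are 1-based from the exon boundary (the first
#' intronic base is offset 1) and the windows are closed (offset == window
#' is inside).  In an intron shorter than the two windows combined both
#' labels can attach.
#'
#' @param v a [QueryVariant-class] classified intronic.
#' @param transcript a [TranscriptModel-class].
#' @param params a [ClassifierParams-class].
#' @return character vector: subset of `c("five_prime_splice_site",
#'   "three_prime_splice_site")`.
#' @export
spliceSiteClass <- function(v, transcript, params = classifierParams()) {
  introns <- .txIntrons(transcript)
  labels <- character()
  for (i in seq_len(nrow(introns))) {
    ib <- introns[i, 1L]; ie <- introns[i, 2L]
    if (!spanOverlap(v@begin, v@end, ib, ie)) next
    if (transcript@strand == "+") {
      donorOffset <- max(1L, v@begin - ib + 1L)
      acceptorOffset <- max(1L, ie - v@end + 1L)
    } else {
      donorOffset <- max(1L, ie - v@end + 1L)
      acceptorOffset <- max(1L, v@begin - ib + 1L)
    }
    if (donorOffset <= params@donorWindow)
      labels <- c(labels, "five_prime_splice_site")
    if (acceptorOffset <= params@acceptorWindow)
      labels <- c(labels, "three_prime_splice_site")
  }
  unique(labels)
}

#' Exon subregion labels for an exonic variant
#'
#' Splits the exonic space of a coding transcript at the genomic CDS span:
#' in coding orientation, exonic positions before the CDS are 5' UTR,
#' inside it CDS, after it 3' UTR (mirrored for minus-strand transcripts).
#' A span touching several subregions receives every touched label; an
#' exonic variant on a transcript without CDS annotation is labelled
#' `"noncoding_exon"`.
#'
#' @param v a [QueryVariant-class] classified exonic.
#' @param transcript a [TranscriptModel-class].
#' @return character vector of labels.
#' @export
exonSubregion <- function(v, transcript) {
  if (!length(transcript@cdsSpan)) return("noncoding_exon")
  cb <- transcript@cdsSpan[1L]; ce <- transcript@cdsSpan[2L]
  ex <- transcript@exons
  labels <- character()
  for (i in seq_len(nrow(ex))) {
    if (!spanOverlap(v@begin, v@end, ex[i, 1L], ex[i, 2L])) next
    ## restrict the variant to this exon (insertion points stay points)
    ob <- max(v@begin, ex[i, 1L]); oe <- min(v@end, ex[i, 2L])
    if (ob > oe) { ob <- oe <- max(ex[i, 1L], min(ex[i, 2L], v@begin)) }
    if (ob == oe) {  # insertion point: a boundary attaches to both sides
      leftUtr <- ob <= cb
      inCds <- cb <= ob && ob <= ce
      rightUtr <- ob >= ce
    } else {         # covered residues are ob+1 .. oe
      leftUtr <- ob < cb
      inCds <- ob < ce && cb < oe
      rightUtr <- oe > ce
    }
    if (transcript@strand == "+") {
      if (leftUtr) labels <- c(labels, "five_prime_UTR")
      if (rightUtr) labels <- c(labels, "three_prime_UTR")
    } else {
      if (leftUtr) labels <- c(labels, "three_prime_UTR")
      if (rightUtr) labels <- c(labels, "five_prime_UTR")
    }
    if (inCds) labels <- c(labels, "CDS")
  }
  unique(labels)
}

#' Classify one variant against the annotation
#'
#' Walks the decision tree for one query variant.  Known-variant and
#' repeat collocations (positional overlap, insertion points attaching to
#' both flanking features) are assessed first, independently of gene
#' context.  The variant is then classified independently against every
#' overlapping gene and, within each gene, against every alternative
#' transcript: upstream promoter / downstream transcript windows (with the
#' gap to the nearest exon), intronic with donor/acceptor splice-site
#' windows, or exonic with 5' UTR / CDS / 3' UTR sublabels.  Variants
#' touching the CDS of a coding transcript additionally receive a
#' [TranscriptEffect-class] with the codon-level consequence and the
#' predicted mutant protein.  A variant overlapping no gene (nor any
#' promoter/downstream window) is intergenic.
#'
#' @param v a [QueryVariant-class].
#' @param ann an [AnnotationSet-class].
#' @param ref the [ReferenceRegion-class].
#' @param params a [ClassifierParams-class].
#' @return a [ClassificationTree-class].
#' @export
classifyVariant <- function(v, ann, ref, params = classifierParams()) {
  if (v@end > regionLength(ref))
    stop("variant ", v@variantId, " extends beyond the reference",
         call. = FALSE)
  kIdx <- .overlapIndex(ann@knownIndex, v@begin, v@end)
  rIdx <- .overlapIndex(ann@repeatIndex, v@begin, v@end)

  ## candidate genes: expand the query by the promoter window so that
  ## promoter/downstream contexts are reachable through the index
  w <- params@promoterWindow
  gIdx <- .overlapIndex(ann@geneIndex, max(0L, v@begin - w), v@end + w)

  geneBranches <- list()
  for (gi in gIdx) {
    g <- ann@genes[[gi]]
    txBranches <- list()
    for (tr in g@transcripts) {
      ctx <- geneContext(v, tr, params)
      if (ctx$kind == "outside") next
      br <- new("TranscriptBranch", transcriptId = tr@transcriptId,
                contextKind = ctx$kind, distanceToExon = ctx$distance)
      if (ctx$kind == "within") {
        tc <- transcriptContext(v, tr)
        br@regionLabels <- tc$labels
        br@notes <- c(br@notes, tc$notes)
        if ("intronic" %in% tc$labels) {
          br@distanceToExon <- tc$distance
          br@spliceLabels <- spliceSiteClass(v, tr, params)
        }
        if ("exonic" %in% tc$labels) {
          br@exonSublabels <- exonSubregion(v, tr)
          if ("CDS" %in% br@exonSublabels && length(tr@cdsSpan))
            br@effect <- .transcriptEffect(v, tr, ref, ann@domains, params)
        }
        env <- .txEnvelope(tr)
        if (v@begin < env[1L] || v@end > env[2L])
          br@notes <- c(br@notes, "extends_beyond_transcript")
      }
      txBranches[[length(txBranches) + 1L]] <- br
    }
    if (length(txBranches))
      geneBranches[[length(geneBranches) + 1L]] <-
        new("GeneBranch", geneId = g@geneId,
            transcriptBranches = txBranches)
  }

  fl <- flankingSequence(v, ref, params@flankLen)
  new("ClassificationTree", variant = v,
      knownIds = ann@known$dbsnp_id[kIdx],
      repeatNames = unique(ann@repeats$repeat_name[rIdx]),
      geneBranches = geneBranches,
      intergenic = length(geneBranches) == 0L,
      leftFlank = fl$left, rightFlank = fl$right)
}

#' Classify a list of variants
#'
#' @param variants list of [QueryVariant-class] objects.
#' @param ann an [AnnotationSet-class].
#' @param ref the [ReferenceRegion-class].
#' @param params a [ClassifierParams-class].
#' @return list of [ClassificationTree-class] objects.
#' @export
classifyVariants <- function(variants, ann, ref,
                             params = classifierParams()) {
  lapply(variants, classifyVariant, ann = ann, ref = ref, params = params)
}

#' @rdname tree-accessors
#' @export
setMethod("isIntergenic", "ClassificationTree", function(x) x@intergenic)

#' @rdname tree-accessors
#' @export
setMethod("knownIds", "ClassificationTree", function(x) x@knownIds)

#' @rdname tree-accessors
#' @export
setMethod("repeatNames", "ClassificationTree", function(x) x@repeatNames)

#' Classification-tree accessors
#'
#' `isIntergenic()`, `knownIds()`, `repeatNames()` and `geneBranches()`
#' read the tree's first-level assessments; `labelSet()` flattens the tree
#' into a character set of labels (`"known"`, `"repeat"`, `"intergenic"`,
#' and `"<gene>:<transcript>:<label>"` entries) convenient for set-wise
#' comparison.
#'
#' @param x a [ClassificationTree-class].
#' @name tree-accessors
#' @return see description.
#' @rdname tree-accessors
#' @export
setMethod("geneBranches", "ClassificationTree", function(x) x@geneBranches)

#' @rdname tree-accessors
#' @export
setMethod("labelSet", "ClassificationTree", function(x) {
  out <- character()
  if (length(x@knownIds)) out <- c(out, "known")
  if (length(x@repeatNames)) out <- c(out, "repeat")
  if (x@intergenic) out <- c(out, "intergenic")
  for (gb in x@geneBranches) {
    for (tb in gb@transcriptBranches) {
      pre <- paste0(gb@geneId, ":", tb@transcriptId, ":")
      labs <- if (tb@contextKind == "within")
        c(tb@regionLabels, tb@spliceLabels, tb@exonSublabels)
      else tb@contextKind
      out <- c(out, paste0(pre, labs))
    }
  }
  sort(unique(out))
})

setMethod("show", "ClassificationTree", function(object) {
  v <- object@variant
  cat("ClassificationTree for ", v@variantId, " (", v@begin, ", ", v@end,
      ") ", v@variantType, "\n", sep = "")
  if (length(object@knownIds))
    cat("  known: ", paste(object@knownIds, collapse = ","), "\n", sep = "")
  if (length(object@repeatNames))
    cat("  repeat: ", paste(object@repeatNames, collapse = ","), "\n",
        sep = "")
  if (object@intergenic) cat("  intergenic\n")
  for (gb in object@geneBranches) {
    cat("  gene ", gb@geneId, "\n", sep = "")
    for (tb in gb@transcriptBranches) {
      cat("    transcript ", tb@transcriptId, ": ",
          if (tb@contextKind == "within")
            paste(c(tb@regionLabels, tb@spliceLabels, tb@exonSublabels),
                  collapse = ", ")
          else paste0(tb@contextKind, " (distance ", tb@distanceToExon, ")"),
          "\n", sep = "")
      if (!is.null(tb@effect)) {
        e <- tb@effect
        cat("      aa ", e@aaPosition, sep = "")
        if (!is.na(e@substitutionClass))
          cat(": ", e@refAa, " -> ", e@altAa, " (", e@substitutionClass,
              if (!is.na(e@conservationClass))
                paste0(", ", e@conservationClass), ")", sep = "")
        if (!is.na(e@indelClass)) cat(": ", e@indelClass, sep = "")
        cat("\n")
      }
    }
  }
})
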