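#' Per-exon coding pieces of a transcript
#'
#' Intersects the transcript's genomic CDS span with its exons, yielding
#' the coding pieces in ascending genomic order.
#'
#' @param transcript a [TranscriptModel-class] with a CDS span.
#' @return integer matrix with columns `begin`, `end` (0-space), rows in
#'   ascending genomic order.
#' @export
cdsPieces <- function(transcript) {
  if (!length(transcript@cdsSpan))
    stop("transcript ", transcript@transcriptId, " has no CDS",
         call. = FALSE)
  cb <- transcript@cdsSpan[1L]; ce <- transcript@cdsSpan[2L]
  ex <- transcript@exons
  b <- pmax(ex[, 1L], cb); e <- pmin(ex[, 2L], ce)
  keep <- b < e
  if (!any(keep))
    stop("CDS span of ", transcript@transcriptId,
         " does not intersect its exons", call. = FALSE)
  out <- cbind(begin = b[keep], end = e[keep])
  storage.mode(out) <- "integer"
  out
}

#' Spliced CDS sequence
#'
#' Concatenates the exon-and-CDS intersection pieces in coding order:
#' ascending genomic order on the plus strand, reverse complemented for
#' minus-strand transcripts.
#'
#' @param transcript a [TranscriptModel-class] with a CDS span.
#' @param ref the [ReferenceRegion-class].
#' @return the CDS as a character scalar, 5' to 3' in coding orientation.
#' @export
splicedCdsSequence <- function(transcript, ref) {
  p <- cdsPieces(transcript)
  seq <- paste(vapply(seq_len(nrow(p)),
                      function(i) regionSlice(ref, p[i, 1L], p[i, 2L]), ""),
               collapse = "")
  if (transcript@strand == "-") .revComp(seq) else seq
}

#' Map a genomic position to its CDS base index
#'
#' @param position 0-space coordinate of the base (the base covers
#'   residues `position+1`, i.e. the span `(position, position+1)`); must
#'   lie within an exon-CDS intersection piece.
#' @param transcript a [TranscriptModel-class] with a CDS span.
#' @return 1-based index of the base among coding bases, counted in coding
#'   orientation.
#' @export
genomicToCds <- function(position, transcript) {
  p <- cdsPieces(transcript)
  w <- p[, 2L] - p[, 1L]
  hit <- which(p[, 1L] <= position & position < p[, 2L])
  if (!length(hit))
    stop("position ", position, " is not a coding base of ",
         transcript@transcriptId, call. = FALSE)
  if (transcript@strand == "+") {
    before <- if (hit > 1L) sum(w[seq_len(hit - 1L)]) else 0L
    as.integer(before + (position - p[hit, 1L]) + 1L)
  } else {
    after <- if (hit < nrow(p)) sum(w[(hit + 1L):nrow(p)]) else 0L
    as.integer(after + (p[hit, 2L] - position - 1L) + 1L)
  }
}

#' Map a CDS base index back to its genomic position
#'
#' Inverse of [genomicToCds()].
#'
#' @param cdsIndex 1-based coding-base index.
#' @param transcript a [TranscriptModel-class] with a CDS span.
#' @return 0-space coordinate of the base (the base spans
#'   `(position, position+1)`).
#' @export
cdsToGenomic <- function(cdsIndex, transcript) {
  p <- cdsPieces(transcript)
  w <- p[, 2L] - p[, 1L]
  if (cdsIndex < 1L || cdsIndex > sum(w))
    stop("CDS index out of range: ", cdsIndex, call. = FALSE)
  if (transcript@strand == "-") {
    p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    w <- rev(w)
  }
  cum <- cumsum(w)
  piece <- which(cdsIndex <= cum)[1L]
  off <- cdsIndex - (if (piece > 1L) cum[piece - 1L] else 0L) - 1L
  if (transcript@strand == "+") as.integer(unname(p[piece, 1L] + off))
  else as.integer(unname(p[piece, 2L] - off - 1L))
}

#' Map a CDS base index to amino-acid coordinates
#'
#' @param cdsIndex 1-based coding-base index.
#' @return list with `aaPosition` (`ceiling(cdsIndex / 3)`) and
#'   `offsetInCodon` (`(cdsIndex - 1) %% 3`).
#' @export
cdsToAa <- function(cdsIndex) {
  if (any(cdsIndex < 1L)) stop("cdsIndex must be >= 1", call. = FALSE)
  list(aaPosition = as.integer(ceiling(cdsIndex / 3)),
       offsetInCodon = as.integer((cdsIndex - 1L) %% 3L))
}

#' Translate a CDS with stop-codon truncation
#'
#' Standard genetic code; translation stops at the first stop codon (not
#' included in the returned protein), codons containing N (or any
#' ambiguity) translate to `X`, and a trailing partial codon is ignored.
#'
#' @param cds DNA string (character scalar), length >= 3 for a non-empty
#'   product.
#' @return list with `protein` (character scalar), `stoppedAt` (1-based
#'   codon index of the terminating stop, `NA` when translation ran off
#'   the end of `cds`).
#' @examples
#' translateCds("ATGTAA")$protein    # "M"
#' translateCds("ATGAATTGACCC")$protein  # "MN"
#' translateCds("ATGNNG")$protein    # "MX"
#' @export
translateCds <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(list(protein = "", stoppedAt = NA_integer_))
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aas <- unname(GENETIC_CODE[codons])
  aas[is.na(aas)] <- "X"
  stop1 <- which(aas == "*")[1L]
  if (!is.na(stop1))
    list(protein = paste(aas[seq_len(stop1 - 1L)], collapse = ""),
         stoppedAt = as.integer(stop1))
  else
    list(protein = paste(aas, collapse = ""), stoppedAt = NA_integer_)
}

#' Synonymous / non-synonymous call for a codon substitution
#'
#' @param refCodon,altCodon trinucleotide strings differing in at least
#'   one position.
#' @return list with `class` (`"synonymous"`/`"nonsynonymous"`, or `NA`
#'   with a note when a codon contains an ambiguity), `refAa`, `altAa`.
#' @examples
#' classifySubstitution("CTG", "CTA")$class  # synonymous (both Leu)
#' classifySubstitution("ATG", "ATA")$class  # nonsynonymous M -> I
#' @export
classifySubstitution <- function(refCodon, altCodon) {
  stopifnot(nchar(refCodon) == 3L, nchar(altCodon) == 3L)
  refAa <- unname(GENETIC_CODE[toupper(refCodon)])
  altAa <- unname(GENETIC_CODE[toupper(altCodon)])
  if (is.na(refAa) || is.na(altAa))
    return(list(class = NA_character_,
                refAa = if (is.na(refAa)) "X" else refAa,
                altAa = if (is.na(altAa)) "X" else altAa,
                note = "ambiguous_codon"))
  list(class = if (refAa == altAa) "synonymous" else "nonsynonymous",
       refAa = refAa, altAa = altAa, note = NULL)
}

#' Frameshift / in-frame call for an indel
#'
#' @param netLengthChange signed net change (in bases) of the coding
#'   sequence length; must be non-zero.
#' @return `"frameshift"` when the change is not a multiple of 3,
#'   `"amino_acid_indel"` otherwise.
#' @export
classifyIndel <- function(netLengthChange) {
  stopifnot(netLengthChange != 0L)
  if (abs(netLengthChange) %% 3L != 0L) "frameshift" else "amino_acid_indel"
}

#' Protein domains overlapping an affected amino-acid range
#'
#' @param aaBegin,aaEnd 1-based inclusive amino-acid range affected by the
#'   variant; for frameshifts the caller extends the range to the end of
#'   the reference protein.
#' @param domains data.frame with columns `domain_name`, `aa_begin`,
#'   `aa_end` (already restricted to the transcript of interest).
#' @return character vector of overlapping domain names.
#' @export
impactedDomains <- function(aaBegin, aaEnd, domains) {
  if (!nrow(domains)) return(character())
  hit <- domains$aa_begin <= aaEnd & aaBegin <= domains$aa_end
  unique(domains$domain_name[hit])
}

## Coordinate shift through a variant replacing the 0-space span (b, e)
## with an allele of length m: positions left of the span are unchanged,
## positions right of it shift by m - (e - b), positions inside map onto
## the replacement (identity for substitutions, collapse for deletions).
.mapThroughVariant <- function(x, b, e, m) {
  delta <- m - (e - b)
  ifelse(x <= b, x,
         ifelse(x >= e, x + delta,
                b + pmin(m, x - b)))
}

## Mutant spliced sequence over a set of genomic pieces: applies the
## variant to the genomic sequence and re-extracts the pieces with their
## coordinates mapped through the variant (intronic bases of a spanning
## deletion disappear; an insertion lands in the piece whose interior or
## right boundary contains the insertion point).
.mutantSplice <- function(pieces, ref, v) {
  seq <- regionSequence(ref)
  m <- nchar(v@plusAllele)
  mseq <- paste0(substr(seq, 1L, v@begin), v@plusAllele,
                 substr(seq, v@end + 1L, nchar(seq)))
  b2 <- .mapThroughVariant(pieces[, 1L], v@begin, v@end, m)
  e2 <- .mapThroughVariant(pieces[, 2L], v@begin, v@end, m)
  paste(vapply(seq_len(nrow(pieces)),
               function(i) if (b2[i] >= e2[i]) ""
                           else substr(mseq, b2[i] + 1L, e2[i]), ""),
        collapse = "")
}

## Exon pieces from the CDS start through the transcript's 3' end in
## coding orientation (CDS plus spliced 3' UTR), ascending genomic order.
.cdsAndDownstreamPieces <- function(transcript) {
  ex <- transcript@exons
  cb <- transcript@cdsSpan[1L]; ce <- transcript@cdsSpan[2L]
  if (transcript@strand == "+") {
    b <- pmax(ex[, 1L], cb); e <- ex[, 2L]
  } else {
    b <- ex[, 1L]; e <- pmin(ex[, 2L], ce)
  }
  keep <- b < e
  out <- cbind(begin = b[keep], end = e[keep])
  storage.mode(out) <- "integer"
  out
}

## 1-based CDS index range affected by a variant (coding orientation).
## Substitutions/deletions: indices of overlapped coding bases.
## Insertions: index of the first coding base at-or-after the insertion
## point in coding orientation (clamped into the CDS).
.affectedCdsRange <- function(v, transcript) {
  p <- cdsPieces(transcript)
  total <- sum(p[, 2L] - p[, 1L])
  idx <- integer()
  for (i in seq_len(nrow(p))) {
    lo <- max(v@begin, p[i, 1L]); hi <- min(v@end, p[i, 2L])
    if (lo < hi)
      idx <- c(idx, vapply(lo:(hi - 1L),
                           function(pos) genomicToCds(pos, transcript), 1L))
  }
  if (!length(idx)) {
    ## insertion point (or boundary-abutting variant): nearest coding base
    c0 <- v@begin
    cand <- c()
    for (i in seq_len(nrow(p))) {
      if (p[i, 1L] <= c0 && c0 < p[i, 2L]) cand <- c0
    }
    if (is.null(cand) || !length(cand)) {
      ## point at a piece boundary: take the closest coding base
      dists <- pmin(abs(p[, 1L] - c0), abs(p[, 2L] - 1L - c0))
      i <- which.min(dists)
      cand <- if (abs(p[i, 1L] - c0) <= abs(p[i, 2L] - 1L - c0))
        p[i, 1L] else p[i, 2L] - 1L
    }
    idx <- genomicToCds(cand, transcript)
  }
  r <- range(idx)
  c(max(1L, r[1L]), min(total, r[2L]))
}

#' Predict the mutant protein for a CDS-overlapping variant
#'
#' Splices the variant's plus-strand allele into the genomic sequence,
#' rebuilds the spliced coding sequence from the same exon structure
#' (intronic portions of a spanning deletion are removed; an insertion is
#' placed at its point), and translates with stop-codon truncation.  When
#' the mutant CDS has lost its stop codon, translation continues into the
#' spliced 3' UTR until the next stop or the end of the transcript
#' (`"stop_lost"` note); when the variant destroys the initiator ATG the
#' predicted protein is empty (`"start_lost"` note).
#'
#' @param transcript a [TranscriptModel-class] with a CDS span.
#' @param v a [QueryVariant-class] overlapping the CDS.
#' @param ref the [ReferenceRegion-class].
#' @return list with `protein` (the predicted mutant protein) and `notes`
#'   (character vector, possibly empty).
#' @export
predictMutantProtein <- function(transcript, v, ref) {
  pieces <- .cdsAndDownstreamPieces(transcript)
  refCds <- splicedCdsSequence(transcript, ref)
  mutExt <- .mutantSplice(pieces, ref, v)
  if (transcript@strand == "-") mutExt <- .revComp(mutExt)

  ## length of the mutant CDS proper (pieces clipped at the CDS end)
  cdsP <- cdsPieces(transcript)
  m <- nchar(v@plusAllele)
  b2 <- .mapThroughVariant(cdsP[, 1L], v@begin, v@end, m)
  e2 <- .mapThroughVariant(cdsP[, 2L], v@begin, v@end, m)
  mutCdsLen <- sum(pmax(0L, e2 - b2))

  notes <- character()
  if (substr(refCds, 1L, 3L) == "ATG" && substr(mutExt, 1L, 3L) != "ATG") {
    return(list(protein = "", notes = "start_lost"))
  }
  tr <- translateCds(mutExt)
  protein <- tr$protein
  if (is.na(tr$stoppedAt)) {
    notes <- c(notes, "stop_lost")
  } else if (tr$stoppedAt * 3L > mutCdsLen) {
    ## terminating stop found only beyond the (mutant) CDS: read-through
    notes <- c(notes, "stop_lost")
  }
  list(protein = protein, notes = notes)
}

## Full protein-level consequence for one variant on one transcript.
## Called by classifyVariant() once the variant is known to touch the CDS.
.transcriptEffect <- function(v, transcript, ref, domains, params) {
  refCds <- splicedCdsSequence(transcript, ref)
  refProt <- translateCds(refCds)$protein
  rng <- .affectedCdsRange(v, transcript)
  cdsPos <- rng[1L]
  aaFirst <- cdsToAa(rng[1L])$aaPosition
  aaLast <- cdsToAa(rng[2L])$aaPosition

  eff <- new("TranscriptEffect", cdsPosition = cdsPos,
             aaPosition = aaFirst)

  mut <- predictMutantProtein(transcript, v, ref)
  eff@predictedProtein <- mut$protein
  eff@notes <- c(eff@notes, mut$notes)

  ## net change in coding length decides substitution vs indel handling
  cdsP <- cdsPieces(transcript)
  m <- nchar(v@plusAllele)
  b2 <- .mapThroughVariant(cdsP[, 1L], v@begin, v@end, m)
  e2 <- .mapThroughVariant(cdsP[, 2L], v@begin, v@end, m)
  net <- as.integer(sum(pmax(0L, e2 - b2)) - sum(cdsP[, 2L] - cdsP[, 1L]))

  if (net != 0L) {
    eff@indelClass <- classifyIndel(net)
  } else if (v@variantType == "substitution") {
    if (aaFirst == aaLast) {
      mutCds <- .mutantSplice(cdsP, ref, v)
      if (transcript@strand == "-") mutCds <- .revComp(mutCds)
      refCodon <- substr(refCds, 3L * aaFirst - 2L, 3L * aaFirst)
      altCodon <- substr(mutCds, 3L * aaFirst - 2L, 3L * aaFirst)
      eff@refCodon <- refCodon; eff@altCodon <- altCodon
      cls <- classifySubstitution(refCodon, altCodon)
      eff@refAa <- cls$refAa; eff@altAa <- cls$altAa
      if (!is.null(cls$note)) eff@notes <- c(eff@notes, cls$note)
      if (!is.na(cls$class)) {
        eff@substitutionClass <- cls$class
        if (identical(cls$class, "nonsynonymous")) {
          if (cls$altAa == "*") {
            eff@conservationClass <- "unconserved"
          } else if (cls$refAa == "*") {
            ## stop-loss substitution: the matrix has no entry for stop;
            ## both classes are omitted (the stop_lost note carries it)
            eff@substitutionClass <- NA_character_
          } else {
            eff@conservationClass <-
              conservationClass(cls$refAa, cls$altAa, params@matrix)
          }
        }
      }
    } else {
      eff@notes <- c(eff@notes, "multi_codon_substitution")
    }
  } else {
    ## insertion/deletion whose coding length change is zero (e.g. an
    ## insertion point resolved to the intron side of an exon boundary)
    eff@notes <- c(eff@notes, "no_cds_length_change")
  }

  ## impacted domains: frameshifts affect everything downstream
  aaEnd <- if (identical(eff@indelClass, "frameshift"))
    max(aaLast, nchar(refProt)) else aaLast
  dom <- domains[domains$transcript_id == transcript@transcriptId, ,
                 drop = FALSE]
  eff@impactedDomains <- impactedDomains(aaFirst, aaEnd, dom)
  validObject(eff)
  eff
}
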