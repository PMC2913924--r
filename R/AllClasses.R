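#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   reverseComplement GENETIC_CODE
#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom IRanges IRanges
NULL

## All genomic coordinates in this package are region-local and
## 0-space-based: an interval (begin, end) covers residues begin+1 .. end
## of the region (1-residue-based), and begin == end is an insertion point
## between residues.  See ?spanOverlap for the overlap semantics.

#' Reference region of interest
#'
#' Holds the nucleotide sequence of the region of interest, which provides
#' the local 0-space-based coordinate frame (0 .. `length`) for every
#' annotation feature and query variant.  Characters outside A/C/G/T/N are
#' masked to N on load.
#'
#' @slot name region (record) name.
#' @slot sequence a [Biostrings::DNAString] over A,C,G,T,N, uppercase.
#' @slot genomeOffset optional 1-based genomic start of the region on its
#'   source chromosome (`NA` when unknown); used only by the GFF3 adapter
#'   to project genomic coordinates into the local frame.
#'
#' @seealso [readReferenceFasta()]
#' @exportClass ReferenceRegion
setClass("ReferenceRegion",
  slots = c(name = "character", sequence = "DNAString",
            genomeOffset = "integer", cache = "environment"),
  prototype = prototype(name = NA_character_, genomeOffset = NA_integer_))

setValidity("ReferenceRegion", function(object) {
  msg <- character()
  if (length(object@sequence) < 1L)
    msg <- c(msg, "region sequence must be non-empty")
  if (length(object@name) != 1L)
    msg <- c(msg, "name must be a single string")
  bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("sequence contains characters outside ACGTN: ",
                         paste(bad, collapse = "")))
  if (length(msg)) msg else TRUE
})

#' Transcript model
#'
#' One alternative transcript of a gene: its exon intervals (0-space,
#' sorted, pairwise disjoint) and, for coding transcripts, the genomic CDS
#' span (translation start/stop).  Per-exon coding pieces are derived by
#' intersecting the CDS span with the exons (see [cdsPieces()]).
#'
#' @slot transcriptId transcript identifier.
#' @slot strand `"+"` or `"-"` (inherited from the gene).
#' @slot exons integer matrix with columns `begin`, `end` (0-space),
#'   rows sorted ascending by `begin`.
#' @slot cdsSpan integer vector of length 2 (`begin`, `end`, 0-space) or
#'   length 0 for non-coding transcripts.
#' @slot proteinId optional protein identifier (`NA` when absent).
#' @exportClass TranscriptModel
setClass("TranscriptModel",
  slots = c(transcriptId = "character", strand = "character",
            exons = "matrix", cdsSpan = "integer", proteinId = "character"),
  prototype = prototype(cdsSpan = integer(), proteinId = NA_character_))

setValidity("TranscriptModel", function(object) {
  msg <- character()
  ex <- object@exons
  if (!is.numeric(ex) || ncol(ex) != 2L || nrow(ex) < 1L)
    msg <- c(msg, "exons must be a numeric matrix with >= 1 row, 2 columns")
  else {
    if (any(ex[, 1L] > ex[, 2L])) msg <- c(msg, "exon begin > end")
    if (any(ex[, 1L] < 0L)) msg <- c(msg, "negative exon coordinate")
    if (nrow(ex) > 1L) {
      o <- order(ex[, 1L])
      if (!identical(o, seq_len(nrow(ex))))
        msg <- c(msg, "exons not sorted by begin")
      else if (any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
        msg <- c(msg, "overlapping exons within a transcript")
    }
  }
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  cs <- object@cdsSpan
  if (length(cs) && (length(cs) != 2L || cs[1L] > cs[2L]))
    msg <- c(msg, "cdsSpan must be length-2 with begin <= end")
  if (length(msg)) msg else TRUE
})

#' Gene model
#'
#' @slot geneId gene identifier.
#' @slot strand `"+"` or `"-"`.
#' @slot span integer vector of length 2: the 0-space envelope of all
#'   transcript exons.
#' @slot transcripts list of [TranscriptModel-class] objects.
#' @exportClass GeneModel
setClass("GeneModel",
  slots = c(geneId = "character", strand = "character",
            span = "integer", transcripts = "list"))

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@span) != 2L || object@span[1L] > object@span[2L])
    msg <- c(msg, "span must be length-2 with begin <= end")
  for (tr in object@transcripts) {
    if (!is(tr, "TranscriptModel")) {
      msg <- c(msg, "transcripts must be TranscriptModel objects")
      break
    }
    if (min(tr@exons[, 1L]) < object@span[1L] ||
        max(tr@exons[, 2L]) > object@span[2L])
      msg <- c(msg, paste0("gene span does not contain transcript ",
                           tr@transcriptId))
  }
  if (length(msg)) msg else TRUE
})

#' Annotation set
#'
#' All annotated features of the region of interest, in local 0-space
#' coordinates, plus interval indexes (nested containment lists via
#' [IRanges::findOverlaps()]) for fast overlap queries.
#'
#' Construct with [annotationSet()] or read from disk with
#' [readAnnotationTsv()].
#'
#' @slot genes list of [GeneModel-class] objects.
#' @slot domains data.frame with columns `transcript_id`, `domain_name`,
#'   `aa_begin`, `aa_end` (1-based inclusive amino-acid coordinates on the
#'   reference protein, Pfam convention).
#' @slot repeats data.frame with columns `begin`, `end`, `repeat_name`.
#' @slot known data.frame with columns `begin`, `end`, `dbsnp_id`.
#' @slot geneIndex,repeatIndex,knownIndex [IRanges::IRanges] indexes over
#'   gene spans, repeats and known variants (internal).
#' @exportClass AnnotationSet
setClass("AnnotationSet",
  slots = c(genes = "list", domains = "data.frame", repeats = "data.frame",
            known = "data.frame", geneIndex = "IRanges",
            repeatIndex = "IRanges", knownIndex = "IRanges"))

#' Query variant
#'
#' One assayed allele at a 0-space span of the reference region.  The span
#' length is the reference-allele length, so the variant type follows from
#' comparing it with the assayed-allele length: equal (and > 0) is a
#' (block) substitution, longer allele an insertion, shorter a deletion.
#' `begin == end` is an insertion point between residues.
#'
#' @slot variantId variant identifier.
#' @slot begin,end 0-space span on the plus strand of the region.
#' @slot orientation `"+"` or `"-"`: the strand on which `allele` is given.
#' @slot allele the assayed allele as given (`""` for a pure deletion).
#' @slot plusAllele the allele expressed on the plus strand (reverse
#'   complement of `allele` when `orientation == "-"`).
#' @slot variantType `"substitution"`, `"insertion"` or `"deletion"`.
#' @slot notes character vector of qualifications (e.g. `"complex"` for
#'   mixed-length events classified by the pure length rule).
#' @seealso [queryVariant()], [readVariantsTsv()]
#' @exportClass QueryVariant
setClass("QueryVariant",
  slots = c(variantId = "character", begin = "integer", end = "integer",
            orientation = "character", allele = "character",
            plusAllele = "character", variantType = "character",
            notes = "character"),
  prototype = prototype(notes = character()))

setValidity("QueryVariant", function(object) {
  msg <- character()
  if (object@begin > object@end) msg <- c(msg, "begin > end")
  if (object@begin < 0L) msg <- c(msg, "negative begin")
  if (!object@orientation %in% c("+", "-"))
    msg <- c(msg, "orientation must be '+' or '-'")
  if (grepl("[^ACGTN]", object@plusAllele))
    msg <- c(msg, "allele contains non-DNA characters")
  span <- object@end - object@begin
  n <- nchar(object@plusAllele)
  if (span == 0L && n == 0L) msg <- c(msg, "no-op variant (empty span and allele)")
  want <- if (n == span) "substitution" else if (n > span) "insertion" else "deletion"
  if (span > 0L || n > 0L) {
    if (!identical(object@variantType, want))
      msg <- c(msg, "variantType inconsistent with span/allele lengths")
  }
  if (length(msg)) msg else TRUE
})

#' Classifier parameters
#'
#' Tunable windows of the decision tree, defaulting to the classifier's
#' standard constants: a 1000-base upstream-promoter / downstream window,
#' a 10-base donor (5' splice site) window, a 6-base acceptor (3' splice
#' site) window, and 50 bases of reported flanking sequence.
#'
#' @slot promoterWindow bases upstream of the first exon (and downstream of
#'   the last) still assigned to the promoter / downstream-transcript region.
#' @slot donorWindow intronic bases immediately 3' of an exon (coding
#'   orientation) labelled 5' splice site; offsets are 1-based from the
#'   exon boundary and the window is closed (offset == window is inside).
#' @slot acceptorWindow intronic bases immediately 5' of the next exon
#'   labelled 3' splice site.
#' @slot flankLen flanking-sequence length reported for assay design.
#' @slot matrix amino-acid substitution matrix used for the
#'   conserved/unconserved call (defaults to the packaged BLOSUM30).
#' @seealso [classifierParams()]
#' @exportClass ClassifierParams
setClass("ClassifierParams",
  slots = c(promoterWindow = "integer", donorWindow = "integer",
            acceptorWindow = "integer", flankLen = "integer",
            matrix = "matrix"))

setValidity("ClassifierParams", function(object) {
  msg <- character()
  for (s in c("promoterWindow", "donorWindow", "acceptorWindow", "flankLen"))
    if (slot(object, s) < 0L) msg <- c(msg, paste(s, "must be >= 0"))
  if (length(msg)) msg else TRUE
})

#' Protein-level consequence of one variant on one transcript
#'
#' Computed only for variants touching the coding sequence.  Single-codon
#' substitutions carry ref/alt codons and amino acids plus the
#' synonymous/non-synonymous and conserved/unconserved calls; indels carry
#' the frameshift / amino-acid-indel call.  The predicted mutant protein
#' (translation of the mutant spliced CDS, truncated at the first stop) is
#' always present.
#'
#' @slot cdsPosition 1-based CDS base index of the first affected coding
#'   base (coding orientation).
#' @slot aaPosition 1-based index of the first affected codon.
#' @slot refCodon,altCodon reference/mutant codon (single-codon
#'   substitutions only, else `NA`).
#' @slot refAa,altAa single-letter amino acids, `"*"` for stop.
#' @slot substitutionClass `"synonymous"`/`"nonsynonymous"` or `NA`.
#' @slot conservationClass `"conserved"`/`"unconserved"` or `NA`; present
#'   iff `substitutionClass == "nonsynonymous"`.
#' @slot indelClass `"frameshift"`/`"amino_acid_indel"` or `NA`.
#' @slot impactedDomains names of protein domains overlapping the affected
#'   amino-acid range (for frameshifts: from the first affected codon to
#'   the end of the reference protein).
#' @slot predictedProtein the mutant protein sequence (stop excluded).
#' @slot notes qualifications such as `"start_lost"`, `"stop_lost"`,
#'   `"multi_codon_substitution"`, `"ambiguous_codon"`.
#' @exportClass TranscriptEffect
setClass("TranscriptEffect",
  slots = c(cdsPosition = "integer", aaPosition = "integer",
            refCodon = "character", altCodon = "character",
            refAa = "character", altAa = "character",
            substitutionClass = "character", conservationClass = "character",
            indelClass = "character", impactedDomains = "character",
            predictedProtein = "character", notes = "character"),
  prototype = prototype(refCodon = NA_character_, altCodon = NA_character_,
    refAa = NA_character_, altAa = NA_character_,
    substitutionClass = NA_character_, conservationClass = NA_character_,
    indelClass = NA_character_, impactedDomains = character(),
    predictedProtein = NA_character_, notes = character()))

setValidity("TranscriptEffect", function(object) {
  msg <- character()
  hasCons <- !is.na(object@conservationClass)
  nonsyn <- identical(object@substitutionClass, "nonsynonymous")
  if (hasCons && !nonsyn)
    msg <- c(msg, "conservationClass present but substitution not nonsynonymous")
  if (nonsyn && !hasCons)
    msg <- c(msg, "nonsynonymous substitution lacks conservationClass")
  if (length(msg)) msg else TRUE
})

#' Per-transcript branch of a classification tree
#'
#' @slot transcriptId transcript identifier.
#' @slot contextKind `"upstream_promoter"`, `"downstream_transcript"` or
#'   `"within"` (the variant overlaps the transcript's exon envelope).
#' @slot distanceToExon 0-space gap (in bases) between the variant span and
#'   the nearest exon boundary; reported for promoter, downstream and
#'   intronic contexts, `NA` otherwise.
#' @slot regionLabels for `"within"`: the touched region(s),
#'   `"intronic"` and/or `"exonic"` (both for boundary-spanning variants).
#' @slot spliceLabels `"five_prime_splice_site"` and/or
#'   `"three_prime_splice_site"` for intronic variants inside a splice
#'   window.
#' @slot exonSublabels `"five_prime_UTR"`, `"CDS"`, `"three_prime_UTR"`
#'   and/or `"noncoding_exon"` for exonic variants.
#' @slot notes qualifications (e.g. `"exon_intron_boundary"`).
#' @slot effect a [TranscriptEffect-class] or `NULL`.
#' @exportClass TranscriptBranch
setClass("TranscriptBranch",
  slots = c(transcriptId = "character", contextKind = "character",
            distanceToExon = "integer", regionLabels = "character",
            spliceLabels = "character", exonSublabels = "character",
            notes = "character", effect = "ANY"),
  prototype = prototype(distanceToExon = NA_integer_,
    regionLabels = character(), spliceLabels = character(),
    exonSublabels = character(), notes = character(), effect = NULL))

#' Per-gene branch of a classification tree
#'
#' @slot geneId gene identifier.
#' @slot transcriptBranches list of [TranscriptBranch-class] objects.
#' @exportClass GeneBranch
setClass("GeneBranch",
  slots = c(geneId = "character", transcriptBranches = "list"))

#' Hierarchical classification of one variant
#'
#' The root of the decision tree for one query variant: known-variant and
#' repeat collocations are assessed first (independently of gene context),
#' then one branch per overlapping gene with one sub-branch per alternative
#' transcript; a variant overlapping no gene (nor any promoter/downstream
#' window) is intergenic.  Flanking sequence is reported for assay design.
#'
#' @slot variant the classified [QueryVariant-class].
#' @slot knownIds dbSNP ids of collocated known variants.
#' @slot repeatNames names of overlapped repeats.
#' @slot geneBranches list of [GeneBranch-class] objects.
#' @slot intergenic `TRUE` iff `geneBranches` is empty.
#' @slot leftFlank,rightFlank plus-strand flanking sequence (up to
#'   `flankLen` bases, truncated at region edges).
#' @seealso [classifyVariant()]
#' @exportClass ClassificationTree
setClass("ClassificationTree",
  slots = c(variant = "QueryVariant", knownIds = "character",
            repeatNames = "character", geneBranches = "list",
            intergenic = "logical", leftFlank = "character",
            rightFlank = "character"))

setValidity("ClassificationTree", function(object) {
  if (object@intergenic != (length(object@geneBranches) == 0L))
    "intergenic must be TRUE iff there are no gene branches"
  else TRUE
})
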