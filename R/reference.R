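#' Read the reference region FASTA
#'
#' Reads the first record of a FASTA file into a [ReferenceRegion-class].
#' The sequence is uppercased and any character outside A/C/G/T/N is masked
#' to N (a warning reports how many); masking rather than rejecting keeps
#' the classifier total over references containing IUPAC ambiguity codes.
#'
#' @param path path to a FASTA file; only the first record is used.
#' @param genomeOffset optional 1-based genomic start of the region on its
#'   source chromosome.
#' @return a [ReferenceRegion-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">roi", "acgtACGT"), fa)
#' ref <- readReferenceFasta(fa)
#' regionLength(ref)  # 8
#' @export
readReferenceFasta <- function(path, genomeOffset = NA_integer_) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  recs <- tryCatch(readDNAStringSet(path, format = "fasta"),
                   error = function(e) {
                     ## fall back to a permissive reader so that non-IUPAC
                     ## characters can be masked instead of rejected
                     lines <- readLines(path)
                     hdr <- grep("^>", lines)
                     if (!length(hdr)) stop("not a FASTA file: ", path,
                                            call. = FALSE)
                     body <- if (length(hdr) > 1L)
                       lines[(hdr[1L] + 1L):(hdr[2L] - 1L)]
                     else lines[-seq_len(hdr[1L])]
                     seq <- gsub("[^A-Za-z]", "", paste(body, collapse = ""))
                     x <- DNAStringSet(character())
                     attr(x, ".raw") <- seq
                     attr(x, ".name") <- sub("^>", "", lines[hdr[1L]])
                     x
                   })
  if (!is.null(attr(recs, ".raw"))) {
    name <- attr(recs, ".name")
    seq <- attr(recs, ".raw")
  } else {
    if (length(recs) == 0L)
      stop("empty FASTA file: ", path, call. = FALSE)
    name <- names(recs)[1L]
    seq <- as.character(recs[[1L]])
  }
  name <- sub("\\s.*$", "", name)
  referenceRegion(seq, name = name, genomeOffset = genomeOffset)
}

#' Construct a reference region from a sequence string
#'
#' @param sequence DNA sequence (character scalar or
#'   [Biostrings::DNAString]); uppercased, non-ACGTN characters masked to N
#'   with a warning.
#' @param name region name.
#' @param genomeOffset optional 1-based genomic start (see
#'   [ReferenceRegion-class]).
#' @return a [ReferenceRegion-class].
#' @export
referenceRegion <- function(sequence, name = "region",
                            genomeOffset = NA_integer_) {
  seq <- toupper(as.character(sequence))
  if (nchar(seq) == 0L)
    stop("zero-length reference sequence", call. = FALSE)
  nbad <- nchar(gsub("[ACGTN]", "", seq))
  if (nbad > 0L) {
    warning(nbad, " non-ACGTN character(s) masked to N", call. = FALSE)
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  new("ReferenceRegion", name = as.character(name),
      sequence = DNAString(seq),
      genomeOffset = as.integer(genomeOffset),
      cache = new.env(parent = emptyenv()))
}

#' Region length
#'
#' Number of residues `s` in the region of interest; local 0-space
#' coordinates run 0 .. `s`.
#'
#' @param x a [ReferenceRegion-class].
#' @return integer scalar.
#' @rdname regionLength
#' @export
setMethod("regionLength", "ReferenceRegion",
          function(x) length(x@sequence))

#' Region sequence
#'
#' @param x a [ReferenceRegion-class].
#' @return the sequence as a character scalar.
#' @rdname regionSequence
#' @export
setMethod("regionSequence", "ReferenceRegion", function(x) {
  ## character rendering is cached: slicing is on the hot classify path
  if (is.null(x@cache$chr)) x@cache$chr <- as.character(x@sequence)
  x@cache$chr
})

#' Extract a 0-space slice of the region
#'
#' @param ref a [ReferenceRegion-class].
#' @param begin,end 0-space coordinates; the slice covers residues
#'   `begin+1 .. end`.
#' @return character scalar (possibly empty).
#' @export
regionSlice <- function(ref, begin, end) {
  .checkSpan(begin, end, "slice")
  s <- regionLength(ref)
  if (end > s) stop("slice end ", end, " beyond region length ", s,
                    call. = FALSE)
  if (begin == end) return("")
  substr(regionSequence(ref), begin + 1L, end)
}

setMethod("show", "ReferenceRegion", function(object) {
  cat("ReferenceRegion '", object@name, "': ", regionLength(object),
      " bp (0-space coordinates 0..", regionLength(object), ")\n", sep = "")
  s <- regionSequence(object)
  if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
  cat("  ", s, "\n", sep = "")
  if (!is.na(object@genomeOffset))
    cat("  genomic offset (1-based): ", object@genomeOffset, "\n", sep = "")
})
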