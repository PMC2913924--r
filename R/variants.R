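#' Construct a query variant
#'
#' Builds a [QueryVariant-class] from a 0-space span and an assayed allele,
#' inferring the variant type from the length rule: the reference-allele
#' length is `end - begin`, so equal lengths (> 0) give a (block)
#' substitution, a longer assayed allele an insertion, a shorter one a
#' deletion.  Mixed-length events that are really indel+substitution
#' composites are classified by the same length rule and flagged with a
#' `"complex"` note.  A minus-orientation allele is reverse-complemented
#' into `plusAllele`; the span itself is always on the plus strand.
#'
#' @param variantId variant identifier.
#' @param begin,end 0-space span on the region (`begin == end` for an
#'   insertion point).
#' @param orientation `"+"` or `"-"`: strand of `allele`.
#' @param allele assayed allele; `""` or `"-"` denotes a pure deletion.
#' @return a [QueryVariant-class].
#' @examples
#' variantType(queryVariant("v1", 5, 6, "+", "A"))     # substitution
#' variantType(queryVariant("v2", 5, 5, "+", "ACGT"))  # insertion
#' variantType(queryVariant("v3", 5, 9, "+", ""))      # deletion
#' @export
queryVariant <- function(variantId, begin, end, orientation = "+",
                         allele = "") {
  begin <- as.integer(begin); end <- as.integer(end)
  .checkSpan(begin, end, paste0("variant ", variantId))
  allele <- toupper(as.character(allele))
  if (allele == "-") allele <- ""
  if (grepl("[^ACGTN]", allele))
    stop("variant ", variantId, ": allele contains non-DNA characters",
         call. = FALSE)
  span <- end - begin
  n <- nchar(allele)
  if (span == 0L && n == 0L)
    stop("variant ", variantId, ": no-op variant (empty span and allele)",
         call. = FALSE)
  type <- if (n == span) "substitution" else if (n > span) "insertion"
          else "deletion"
  notes <- character()
  if (span > 0L && n > 0L && n != span)
    notes <- "complex"  # composite indel+substitution; length rule applied
  v <- new("QueryVariant", variantId = as.character(variantId),
           begin = begin, end = end, orientation = orientation,
           allele = allele, plusAllele = allele, variantType = type,
           notes = notes)
  orientToPlus(v)
}

#' Express a variant's allele on the plus strand
#'
#' Sets `plusAllele` to the reverse complement of `allele` when the
#' orientation is `"-"`, and to `allele` itself otherwise.  Coordinates
#' are unchanged: spans are always given on the plus strand.  Applying the
#' transform twice with flipped orientation returns the original allele.
#'
#' @param v a [QueryVariant-class].
#' @return `v` with `plusAllele` set.
#' @export
orientToPlus <- function(v) {
  v@plusAllele <- if (v@orientation == "-") .revComp(v@allele) else v@allele
  validObject(v)
  v
}

.revComp <- function(x) {
  if (!nchar(x)) return("")
  as.character(reverseComplement(DNAString(x)))
}

#' @rdname variant-accessors
#' @export
setMethod("variantType", "QueryVariant", function(x) x@variantType)

#' Variant accessors
#'
#' `variantType()` returns `"substitution"`, `"insertion"` or
#' `"deletion"`; `plusAllele()` the assayed allele expressed on the plus
#' strand.
#'
#' @param x a [QueryVariant-class].
#' @name variant-accessors
#' @return see description.
#' @rdname variant-accessors
#' @export
setMethod("plusAllele", "QueryVariant", function(x) x@plusAllele)

setMethod("show", "QueryVariant", function(object) {
  cat("QueryVariant ", object@variantId, ": (", object@begin, ", ",
      object@end, ") ", object@variantType, sep = "")
  if (nchar(object@plusAllele))
    cat(" allele(+): ", object@plusAllele, sep = "")
  if (length(object@notes)) cat(" [", paste(object@notes, collapse = ","),
                                "]", sep = "")
  cat("\n")
})

#' Read the query-variants TSV
#'
#' Parses a five-column TSV (`variant_id`, `begin`, `end`, `orientation`,
#' `allele`); a header row is auto-detected by a non-numeric `begin`
#' field.  Rows violating the contract (begin > end, no-op span+allele,
#' non-DNA allele, coordinates outside the reference when `ref` is given)
#' are rejected individually and reported, not fatal.
#'
#' @param path path to the variants TSV.
#' @param ref optional [ReferenceRegion-class] for bounds checking.
#' @return list with elements `variants` (list of [QueryVariant-class])
#'   and `rejected` (data.frame with columns `line`, `reason`).
#' @export
readVariantsTsv <- function(path, ref = NULL) {
  if (!file.exists(path))
    stop("variants file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  variants <- list()
  rejected <- data.frame(line = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  reject <- function(i, reason)
    rejected <<- rbind(rejected, data.frame(line = i, reason = reason,
                                            stringsAsFactors = FALSE))
  first <- TRUE
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    length(f) <- 5L
    f[is.na(f)] <- ""
    if (first) {
      first <- FALSE
      if (is.na(suppressWarnings(as.integer(f[2L])))) next  # header row
    }
    v <- tryCatch(queryVariant(f[1L], f[2L], f[3L],
                               if (nzchar(f[4L])) f[4L] else "+", f[5L]),
                  error = function(e) conditionMessage(e))
    if (is.character(v)) { reject(i, v); next }
    if (!is.null(ref) && v@end > regionLength(ref)) {
      reject(i, paste0("variant ", v@variantId,
                       ": coordinates outside the reference (end ", v@end,
                       " > ", regionLength(ref), ")"))
      next
    }
    variants[[length(variants) + 1L]] <- v
  }
  list(variants = variants, rejected = rejected)
}

#' Write query variants to TSV
#'
#' @param variants list of [QueryVariant-class] objects.
#' @param path output path.
#' @param header write a header row (default `TRUE`).
#' @return `path`, invisibly.
#' @export
writeVariantsTsv <- function(variants, path, header = TRUE) {
  rows <- character()
  if (header)
    rows <- "variant_id\tbegin\tend\torientation\tallele"
  for (v in variants)
    rows <- c(rows, paste(v@variantId, v@begin, v@end, v@orientation,
                          if (nchar(v@allele)) v@allele else "-",
                          sep = "\t"))
  writeLines(rows, path)
  invisible(path)
}
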