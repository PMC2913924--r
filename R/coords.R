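#' 0-space interval overlap
#'
#' Overlap predicate for the package's 0-space-based coordinate system.
#' Two non-degenerate intervals overlap when they share at least one
#' residue (`b1 < e2 && b2 < e1`).  A degenerate interval
#' (`begin == end`, an insertion point) overlaps every feature it touches,
#' *including* features it merely abuts: an insertion point sitting exactly
#' on a feature boundary attaches to the features on both sides, so both
#' classifications are reported.
#'
#' @param b1,e1 0-space begin/end of the first interval.
#' @param b2,e2 0-space begin/end of the second interval (vectorised).
#' @return logical vector.
#' @examples
#' spanOverlap(5, 6, 6, 10)   # adjacent residues: FALSE
#' spanOverlap(6, 6, 6, 10)   # insertion point at boundary: TRUE
#' spanOverlap(6, 6, 2, 6)    # ...and to the feature on the other side: TRUE
#' @export
spanOverlap <- function(b1, e1, b2, e2) {
  ifelse(b1 == e1 | b2 == e2,
         b1 <= e2 & b2 <= e1,
         b1 < e2 & b2 < e1)
}

## Map a 0-space span to 1-residue-based IRanges coordinates such that
## IRanges::findOverlaps reproduces spanOverlap exactly:
## width > 0: residues begin+1 .. end; insertion point c: pseudo-range
## (c, c+1), which hits every feature (b, e) with b <= c <= e.
.spanToRange <- function(begin, end) {
  ins <- begin == end
  IRanges(start = ifelse(ins, begin, begin + 1L),
          end   = ifelse(ins, begin + 1L, end))
}

## Indexed overlap query: which rows of the feature index does the 0-space
## span (b, e) touch?  The query span is mapped like .spanToRange and
## compared against the index's (1-based, closed) start/end vectors; this
## is equivalent to findOverlaps() on the same ranges but avoids per-query
## IRanges construction on the hot path.
.overlapIndex <- function(index, b, e) {
  n <- length(index)
  if (n == 0L) return(integer())
  if (b == e) { qs <- b; qe <- b + 1L } else { qs <- b + 1L; qe <- e }
  s <- IRanges::start(index); en <- IRanges::end(index)
  which(qs <= en & s <= qe)
}

## 0-space gap between two disjoint spans (0 when they abut).
.spanGap <- function(b1, e1, b2, e2) {
  if (e1 <= b2) b2 - e1 else if (e2 <= b1) b1 - e2 else 0L
}

.checkSpan <- function(begin, end, what = "interval") {
  if (is.na(begin) || is.na(end) || begin > end || begin < 0L)
    stop(what, " must satisfy 0 <= begin <= end, got (",
         begin, ", ", end, ")", call. = FALSE)
  invisible(TRUE)
}
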