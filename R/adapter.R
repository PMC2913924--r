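#' Convert GFF3/BED annotation to the region-local annotation TSV
#'
#' Projects standard genomic annotation into the local 0-space coordinate
#' frame of a region of interest and writes the package's annotation TSV.
#' GFF3 coordinates are 1-based inclusive; a feature at genomic
#' `start..end` inside a region starting at genomic position
#' `region_start` maps to the local 0-space interval
#' `(start - region_start, end - region_start + 1)`.  BED inputs (0-based
#' half-open) are already 0-space-compatible and are shifted by
#' `region_start - 1`.  Features partially outside the region are clipped
#' with a warning; features entirely outside are dropped with a warning.
#' Fragmented GFF3 CDS rows are normalized into a single CDS span per
#' transcript.
#'
#' @param gff3Path path to a GFF3 file with gene / mRNA (or transcript) /
#'   exon / CDS rows linked by `ID`/`Parent` attributes.
#' @param regionName sequence (chromosome) name of the region of interest.
#' @param regionStart,regionEnd 1-based inclusive genomic interval of the
#'   region.
#' @param repeatsBed optional BED file of repeats (name column used as the
#'   repeat name).
#' @param knownBed optional BED file of known variants (name column used
#'   as the dbSNP id).
#' @param outPath optional path; when given the TSV is written there.
#' @return the annotation TSV as a character vector of lines (invisibly
#'   when `outPath` is given).
#' @seealso [readAnnotationTsv()]
#' @export
gff3ToAnnotation <- function(gff3Path, regionName, regionStart, regionEnd,
                             repeatsBed = NULL, knownBed = NULL,
                             outPath = NULL) {
  if (!file.exists(gff3Path))
    stop("GFF3 file not found: ", gff3Path, call. = FALSE)
  gr <- rtracklayer::import(gff3Path, format = "gff3")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == regionName]
  if (!length(gr))
    stop("region sequence '", regionName, "' not found in ", gff3Path,
         call. = FALSE)
  regionLen <- regionEnd - regionStart + 1L

  ## project 1-based inclusive genomic coords into local 0-space, clipping
  project <- function(start, end, label) {
    b <- start - regionStart
    e <- end - regionStart + 1L
    if (e <= 0L || b >= regionLen) {
      warning("feature ", label, " entirely outside region; dropped",
              call. = FALSE)
      return(NULL)
    }
    clipped <- b < 0L || e > regionLen
    if (clipped)
      warning("feature ", label, " partially outside region; clipped",
              call. = FALSE)
    c(max(0L, b), min(regionLen, e), as.integer(clipped))
  }

  type <- as.character(gr$type)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_,
                                                           length(gr))
  parents <- if (!is.null(gr$Parent))
    vapply(gr$Parent, function(p) if (length(p)) as.character(p)[1L]
           else NA_character_, "")
  else rep(NA_character_, length(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))

  rows <- list(paste(.ANN_HEADER, collapse = "\t"))
  add <- function(...) rows[[length(rows) + 1L]] <<-
    paste(c(...), collapse = "\t")

  isTx <- type %in% c("mRNA", "transcript")
  txGene <- ids[isTx]; names(txGene) <- ids[isTx]  # tx id -> gene id below
  txGene[] <- parents[isTx]

  for (i in which(type == "gene")) {
    p <- project(starts[i], ends[i], ids[i])
    if (is.null(p)) next
    add("gene", ids[i], "", p[1L], p[2L], strands[i],
        if (p[3L]) "clipped=1" else "")
  }
  for (i in which(isTx)) {
    p <- project(starts[i], ends[i], ids[i])
    if (is.null(p)) next
    add("transcript", ids[i], parents[i], p[1L], p[2L], strands[i],
        if (p[3L]) "clipped=1" else "")
  }
  for (i in which(type == "exon")) {
    p <- project(starts[i], ends[i], paste0("exon@", starts[i]))
    if (is.null(p)) next
    add("exon", "", parents[i], p[1L], p[2L], strands[i],
        if (p[3L]) "clipped=1" else "")
  }
  ## normalize CDS fragments into one span per transcript
  cdsIdx <- which(type == "CDS")
  if (length(cdsIdx)) {
    byTx <- split(cdsIdx, parents[cdsIdx])
    for (tx in names(byTx)) {
      i <- byTx[[tx]]
      p <- project(min(starts[i]), max(ends[i]), paste0("CDS/", tx))
      if (is.null(p)) next
      add("cds", "", tx, p[1L], p[2L], strands[i[1L]],
          if (p[3L]) "clipped=1" else "")
    }
  }

  readBed <- function(path, what) {
    if (is.null(path)) return(NULL)
    bed <- rtracklayer::import(path, format = "bed")
    bed <- bed[as.character(GenomicRanges::seqnames(bed)) == regionName]
    lapply(seq_along(bed), function(i) {
      nm <- if (!is.null(bed$name)) bed$name[i] else paste0(what, i)
      p <- project(GenomicRanges::start(bed)[i], GenomicRanges::end(bed)[i],
                   nm)
      if (is.null(p)) NULL else list(begin = p[1L], end = p[2L], name = nm)
    })
  }
  for (r in readBed(repeatsBed, "repeat"))
    if (!is.null(r)) add("repeat", "", "", r$begin, r$end, "",
                         paste0("name=", r$name))
  for (r in readBed(knownBed, "known"))
    if (!is.null(r)) add("known_variant", r$name, "", r$begin, r$end, "", "")

  tsv <- unlist(rows)
  if (!is.null(outPath)) {
    writeLines(tsv, outPath)
    return(invisible(tsv))
  }
  tsv
}

#' Project local 0-space coordinates back to genomic 1-based coordinates
#'
#' Inverse of the adapter's projection: a local 0-space interval
#' `(b, e)` in a region starting at genomic `regionStart` covers genomic
#' residues `regionStart + b .. regionStart + e - 1` (1-based inclusive).
#'
#' @param begin,end local 0-space coordinates.
#' @param regionStart 1-based genomic start of the region.
#' @return integer vector `c(start, end)` in 1-based inclusive genomic
#'   coordinates.
#' @export
localToGenomic <- function(begin, end, regionStart) {
  c(regionStart + begin, regionStart + end - 1L)
}
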