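#' Flanking sequence around a variant
#'
#' Plus-strand sequence flanking the variant span, for assay design: up to
#' `flankLen` residues ending at `begin` on the left and starting at `end`
#' on the right, truncated (not padded) at the region edges.
#'
#' @param v a [QueryVariant-class].
#' @param ref the [ReferenceRegion-class].
#' @param flankLen maximum flank length in bases.
#' @return list with `left` and `right` character scalars.
#' @export
flankingSequence <- function(v, ref, flankLen = 50L) {
  s <- regionLength(ref)
  list(left = regionSlice(ref, max(0L, v@begin - flankLen), v@begin),
       right = regionSlice(ref, min(s, v@end), min(s, v@end + flankLen)))
}

.join <- function(x) paste(x, collapse = ",")
.orEmpty <- function(x) if (length(x) == 0L || all(is.na(x))) "" else
  .join(x[!is.na(x)])

## Fixed column schema of the denormalized report.
.DENORM_COLUMNS <- c(
  "variant_id", "begin", "end", "variant_type", "known_ids", "repeat_names",
  "gene_id", "transcript_id", "gene_context", "distance_to_exon",
  "transcript_region", "splice_site", "exon_region", "impacted_domains",
  "cds_position", "aa_position", "ref_codon", "alt_codon", "ref_aa",
  "alt_aa", "substitution_class", "conservation_class", "indel_class",
  "predicted_protein")

#' Column names of the denormalized report
#'
#' @param flanks include the two flank columns appended when flanking
#'   sequence is enabled.
#' @return character vector of column names, in file order.
#' @export
denormalizedColumns <- function(flanks = TRUE) {
  if (flanks) c(.DENORM_COLUMNS, "left_flank", "right_flank")
  else .DENORM_COLUMNS
}

#' Flatten classification trees into the denormalized table
#'
#' One row per (variant, gene, transcript) branch; intergenic variants
#' contribute a single row with empty gene/transcript columns.  Cells that
#' do not apply are empty strings; multi-valued cells are comma-joined.
#'
#' @param trees list of [ClassificationTree-class] objects.
#' @param flanks include flank columns.
#' @return data.frame (all character) with [denormalizedColumns()].
#' @export
flattenClassification <- function(trees, flanks = TRUE) {
  cols <- denormalizedColumns(flanks)
  rows <- list()
  for (tree in trees) {
    v <- tree@variant
    base <- c(variant_id = v@variantId, begin = as.character(v@begin),
              end = as.character(v@end), variant_type = v@variantType,
              known_ids = .orEmpty(tree@knownIds),
              repeat_names = .orEmpty(tree@repeatNames))
    flankCells <- if (flanks)
      c(left_flank = tree@leftFlank, right_flank = tree@rightFlank)
    else NULL
    emptyTail <- stats::setNames(rep("", 18L), .DENORM_COLUMNS[7:24])
    if (tree@intergenic) {
      row <- c(base, emptyTail, flankCells)
      rows[[length(rows) + 1L]] <- row[cols]
      next
    }
    for (gb in tree@geneBranches) {
      for (tb in gb@transcriptBranches) {
        cells <- emptyTail
        cells["gene_id"] <- gb@geneId
        cells["transcript_id"] <- tb@transcriptId
        cells["gene_context"] <- tb@contextKind
        if (!is.na(tb@distanceToExon))
          cells["distance_to_exon"] <- as.character(tb@distanceToExon)
        cells["transcript_region"] <- .orEmpty(tb@regionLabels)
        cells["splice_site"] <- .orEmpty(tb@spliceLabels)
        cells["exon_region"] <- .orEmpty(tb@exonSublabels)
        if (!is.null(tb@effect)) {
          e <- tb@effect
          cells["impacted_domains"] <- .orEmpty(e@impactedDomains)
          cells["cds_position"] <- as.character(e@cdsPosition)
          cells["aa_position"] <- as.character(e@aaPosition)
          cells["ref_codon"] <- .orEmpty(e@refCodon)
          cells["alt_codon"] <- .orEmpty(e@altCodon)
          cells["ref_aa"] <- .orEmpty(e@refAa)
          cells["alt_aa"] <- .orEmpty(e@altAa)
          cells["substitution_class"] <- .orEmpty(e@substitutionClass)
          cells["conservation_class"] <- .orEmpty(e@conservationClass)
          cells["indel_class"] <- .orEmpty(e@indelClass)
          cells["predicted_protein"] <- .orEmpty(e@predictedProtein)
        }
        row <- c(base, cells, flankCells)
        rows[[length(rows) + 1L]] <- row[cols]
      }
    }
  }
  df <- if (length(rows))
    as.data.frame(do.call(rbind, c(rows, list(deparse.level = 0))),
                  stringsAsFactors = FALSE)
  else
    as.data.frame(matrix(character(), 0L, length(cols)),
                  stringsAsFactors = FALSE)
  names(df) <- cols
  rownames(df) <- NULL
  df
}

#' Write the denormalized (flat) report
#'
#' One tab-separated line per (variant, gene, transcript) branch — see
#' [flattenClassification()] — with no header row; every line carries the
#' same fixed column count ([denormalizedColumns()]).  Designed for
#' line-based parsers and spreadsheet sorting.
#'
#' @param trees list of [ClassificationTree-class] objects.
#' @param path output path.
#' @param flanks include flank columns (default `TRUE`).
#' @return `path`, invisibly.
#' @export
writeDenormalized <- function(trees, path, flanks = TRUE) {
  df <- flattenClassification(trees, flanks = flanks)
  lines <- vapply(seq_len(nrow(df)),
                  function(i) paste(unlist(df[i, ]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a denormalized report back into a data.frame
#'
#' @param path path written by [writeDenormalized()].
#' @param flanks whether the file carries the flank columns.
#' @return data.frame with [denormalizedColumns()] (all character).
#' @export
readDenormalized <- function(path, flanks = TRUE) {
  cols <- denormalizedColumns(flanks)
  lines <- readLines(path)
  m <- matrix("", length(lines), length(cols))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    length(f) <- length(cols)
    f[is.na(f)] <- ""
    m[i, ] <- f
  }
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

.effectFacts <- function(e) {
  facts <- list(c("cds_position", as.character(e@cdsPosition)),
                c("aa_position", as.character(e@aaPosition)))
  if (!is.na(e@refCodon))
    facts <- c(facts, list(c("codon_change",
                             paste0(e@refCodon, "/", e@altCodon))))
  if (!is.na(e@refAa))
    facts <- c(facts, list(c("amino_acid_change",
                             paste0(e@refAa, "/", e@altAa))))
  if (!is.na(e@substitutionClass))
    facts <- c(facts, list(c("substitution_class", e@substitutionClass)))
  if (!is.na(e@conservationClass))
    facts <- c(facts, list(c("conservation_class", e@conservationClass)))
  if (!is.na(e@indelClass))
    facts <- c(facts, list(c("indel_class", e@indelClass)))
  if (length(e@impactedDomains))
    facts <- c(facts, list(c("impacted_domains", .join(e@impactedDomains))))
  if (length(e@notes))
    facts <- c(facts, list(c("notes", .join(e@notes))))
  if (!is.na(e@predictedProtein))
    facts <- c(facts, list(c("predicted_protein", e@predictedProtein)))
  facts
}

#' Write the normalized (hierarchical) report
#'
#' One block per variant; a fact at hierarchy depth *d* is prefixed with
#' exactly *d* tab characters, so that a tab-respecting viewer (a
#' spreadsheet) displays equal classification levels at equal indentation.
#' Depths: variant header 0; known/repeat/intergenic 1; gene 1; transcript
#' 2; region label 3; splice / exon sublabel 4; protein-effect facts 5.
#' The file opens with a single header line naming the variant-header
#' fields.
#'
#' @param trees list of [ClassificationTree-class] objects.
#' @param path output path.
#' @param flanks include flank fields on the variant header line.
#' @return `path`, invisibly.
#' @export
writeNormalized <- function(trees, path, flanks = TRUE) {
  out <- c(paste(c("variant_id", "begin", "end", "variant_type",
                   "plus_allele",
                   if (flanks) c("left_flank", "right_flank")),
                 collapse = "\t"))
  line <- function(depth, ...) paste0(strrep("\t", depth),
                                      paste(c(...), collapse = "\t"))
  for (tree in trees) {
    v <- tree@variant
    out <- c(out, line(0L, v@variantId, v@begin, v@end, v@variantType,
                       if (nchar(v@plusAllele)) v@plusAllele else "-",
                       if (flanks) c(tree@leftFlank, tree@rightFlank)))
    if (length(tree@knownIds))
      out <- c(out, line(1L, "known_variant", .join(tree@knownIds)))
    if (length(tree@repeatNames))
      out <- c(out, line(1L, "repeat", .join(tree@repeatNames)))
    if (tree@intergenic) {
      out <- c(out, line(1L, "intergenic"))
      next
    }
    for (gb in tree@geneBranches) {
      out <- c(out, line(1L, "gene", gb@geneId))
      for (tb in gb@transcriptBranches) {
        out <- c(out, line(2L, "transcript", tb@transcriptId))
        if (tb@contextKind != "within") {
          out <- c(out, line(3L, tb@contextKind,
                             paste0("distance=", tb@distanceToExon)))
          next
        }
        if ("intronic" %in% tb@regionLabels) {
          out <- c(out, line(3L, "intronic",
                             paste0("distance=", tb@distanceToExon)))
          for (sl in tb@spliceLabels) out <- c(out, line(4L, sl))
        }
        if ("exonic" %in% tb@regionLabels) {
          out <- c(out, line(3L, "exonic"))
          for (el in tb@exonSublabels) {
            out <- c(out, line(4L, el))
            if (el == "CDS" && !is.null(tb@effect))
              for (f in .effectFacts(tb@effect))
                out <- c(out, line(5L, f[1L], f[2L]))
          }
        }
        if (length(tb@notes))
          out <- c(out, line(3L, "notes", .join(tb@notes)))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}
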