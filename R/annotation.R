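## Annotation TSV schema (documented in the README with a worked example):
## feature_type  feature_id  parent_id  begin  end  strand  attributes
##   gene          <gene id>    ""       0-space span        -
##   transcript    <tx id>    <gene id>  exon envelope       -
##   exon            ""       <tx id>    0-space span        -
##   cds             ""       <tx id>    genomic CDS span    -  (one per tx)
##   domain          ""       <tx id>    aa_begin aa_end  "" name=<Pfam>
##   repeat          ""         ""       0-space span     "" name=<repeat>
##   known_variant <dbSNP id>   ""       0-space span     "" -
## attributes: semicolon-separated key=value pairs.

.ANN_HEADER <- c("feature_type", "feature_id", "parent_id",
                 "begin", "end", "strand", "attributes")

.emptyDomains <- function()
  data.frame(transcript_id = character(), domain_name = character(),
             aa_begin = integer(), aa_end = integer(),
             stringsAsFactors = FALSE)
.emptyRepeats <- function()
  data.frame(begin = integer(), end = integer(), repeat_name = character(),
             stringsAsFactors = FALSE)
.emptyKnown <- function()
  data.frame(begin = integer(), end = integer(), dbsnp_id = character(),
             stringsAsFactors = FALSE)

## Same 0-space -> IRanges mapping as .spanToRange, so that zero-width
## features (insertion-point known variants) keep the attach-to-both-sides
## overlap semantics through the index.
.featureIndex <- function(begin, end) {
  if (!length(begin)) return(IRanges())
  begin <- as.integer(begin); end <- as.integer(end)
  ins <- begin == end
  IRanges(start = ifelse(ins, begin, begin + 1L),
          end = ifelse(ins, begin + 1L, end))
}

#' Construct an annotation set
#'
#' Assembles gene models and auxiliary feature tables into an
#' [AnnotationSet-class], building the interval indexes used by
#' [classifyVariant()].
#'
#' @param genes list of [GeneModel-class] objects.
#' @param domains data.frame with columns `transcript_id`, `domain_name`,
#'   `aa_begin`, `aa_end` (1-based inclusive amino-acid coordinates).
#' @param repeats data.frame with columns `begin`, `end`, `repeat_name`
#'   (0-space).
#' @param known data.frame with columns `begin`, `end`, `dbsnp_id`
#'   (0-space).
#' @return an [AnnotationSet-class].
#' @export
annotationSet <- function(genes = list(), domains = .emptyDomains(),
                          repeats = .emptyRepeats(), known = .emptyKnown()) {
  spans <- if (length(genes))
    vapply(genes, function(g) g@span, integer(2L))
  else matrix(integer(), 2L, 0L)
  new("AnnotationSet", genes = genes, domains = domains,
      repeats = repeats, known = known,
      geneIndex = .featureIndex(spans[1L, ], spans[2L, ]),
      repeatIndex = .featureIndex(repeats$begin, repeats$end),
      knownIndex = .featureIndex(known$begin, known$end))
}

#' @rdname annotation-accessors
#' @param x an [AnnotationSet-class].
#' @export
setMethod("genes", "AnnotationSet", function(x) x@genes)

#' Annotation accessors
#'
#' `genes()` returns the list of [GeneModel-class] objects;
#' `transcripts()` a flat named list of all [TranscriptModel-class]
#' objects; `proteinDomains()`, `repeatFeatures()` and `knownVariants()`
#' the respective feature tables.
#'
#' @name annotation-accessors
#' @return see description.
#' @rdname annotation-accessors
#' @export
setMethod("transcripts", "AnnotationSet", function(x) {
  out <- list()
  for (g in x@genes)
    for (tr in g@transcripts)
      out[[tr@transcriptId]] <- tr
  out
})

#' @rdname annotation-accessors
#' @export
setMethod("proteinDomains", "AnnotationSet", function(x) x@domains)

#' @rdname annotation-accessors
#' @export
setMethod("repeatFeatures", "AnnotationSet", function(x) x@repeats)

#' @rdname annotation-accessors
#' @export
setMethod("knownVariants", "AnnotationSet", function(x) x@known)

setMethod("show", "AnnotationSet", function(object) {
  ntx <- sum(vapply(object@genes, function(g) length(g@transcripts), 1L))
  cat("AnnotationSet: ", length(object@genes), " gene(s), ", ntx,
      " transcript(s), ", nrow(object@domains), " domain(s), ",
      nrow(object@repeats), " repeat(s), ", nrow(object@known),
      " known variant(s)\n", sep = "")
})

.parseInt <- function(x, line, field) {
  v <- suppressWarnings(as.integer(x))
  if (is.na(v))
    stop("line ", line, ": non-integer ", field, " '", x, "'", call. = FALSE)
  v
}

.attr1 <- function(attributes, key) {
  if (is.na(attributes) || attributes == "") return(NA_character_)
  for (kv in strsplit(attributes, ";", fixed = TRUE)[[1L]]) {
    p <- strsplit(kv, "=", fixed = TRUE)[[1L]]
    if (length(p) == 2L && p[1L] == key) return(p[2L])
  }
  NA_character_
}

#' Read the region-local annotation TSV
#'
#' Parses the package's seven-column annotation format (see the README for
#' the schema and a worked example) into an [AnnotationSet-class].  Parent
#' links (exon/CDS -> transcript -> gene, domain -> transcript) are
#' resolved; an unresolvable parent or an inverted interval is a fatal
#' error naming the offending line.
#'
#' @param path path to the annotation TSV.
#' @return an [AnnotationSet-class].
#' @export
readAnnotationTsv <- function(path) {
  if (!file.exists(path))
    stop("annotation file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("annotation file is empty (header row required): ", path,
         call. = FALSE)
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(hdr, .ANN_HEADER))
    stop("annotation header mismatch; expected: ",
         paste(.ANN_HEADER, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    length(f) <- 7L
    f[is.na(f)] <- ""
    list(line = i, type = f[1L], id = f[2L], parent = f[3L],
         begin = f[4L], end = f[5L], strand = f[6L], attributes = f[7L])
  })

  geneRows <- list(); txRows <- list()
  exonRows <- list(); cdsRows <- list()
  domains <- .emptyDomains(); repeats <- .emptyRepeats(); known <- .emptyKnown()

  for (r in rows) {
    b <- .parseInt(r$begin, r$line, "begin")
    e <- .parseInt(r$end, r$line, "end")
    if (b > e)
      stop("line ", r$line, ": begin > end (", b, " > ", e, ")",
           call. = FALSE)
    switch(r$type,
      gene = { geneRows[[r$id]] <- list(id = r$id, strand = r$strand,
                                        span = c(b, e), line = r$line) },
      transcript = { txRows[[r$id]] <- list(id = r$id, parent = r$parent,
                                            strand = r$strand, line = r$line) },
      exon = { exonRows[[length(exonRows) + 1L]] <-
                 list(parent = r$parent, begin = b, end = e, line = r$line) },
      cds = { cdsRows[[length(cdsRows) + 1L]] <-
                list(parent = r$parent, begin = b, end = e, line = r$line) },
      domain = {
        nm <- .attr1(r$attributes, "name")
        if (is.na(nm)) nm <- r$id
        domains <- rbind(domains, data.frame(
          transcript_id = r$parent, domain_name = nm,
          aa_begin = b, aa_end = e, stringsAsFactors = FALSE))
        if (b < 1L)
          stop("line ", r$line, ": domain aa_begin must be >= 1",
               call. = FALSE)
      },
      "repeat" = {
        nm <- .attr1(r$attributes, "name")
        if (is.na(nm)) nm <- r$id
        repeats <- rbind(repeats, data.frame(
          begin = b, end = e, repeat_name = nm, stringsAsFactors = FALSE))
      },
      known_variant = {
        known <- rbind(known, data.frame(
          begin = b, end = e, dbsnp_id = r$id, stringsAsFactors = FALSE))
      },
      stop("line ", r$line, ": unknown feature_type '", r$type, "'",
           call. = FALSE)
    )
  }

  ## resolve parent links
  for (tx in txRows)
    if (!tx$parent %in% names(geneRows))
      stop("line ", tx$line, ": transcript '", tx$id,
           "' references unknown gene '", tx$parent, "'", call. = FALSE)
  resolveTx <- function(r, what) {
    if (!r$parent %in% names(txRows))
      stop("line ", r$line, ": ", what, " references unknown transcript '",
           r$parent, "'", call. = FALSE)
    r$parent
  }
  exonsByTx <- list(); cdsByTx <- list()
  for (r in exonRows) {
    id <- resolveTx(r, "exon")
    exonsByTx[[id]] <- rbind(exonsByTx[[id]], c(r$begin, r$end))
  }
  for (r in cdsRows) {
    id <- resolveTx(r, "cds")
    cdsByTx[[id]] <- rbind(cdsByTx[[id]], c(r$begin, r$end))
  }
  if (nrow(domains))
    for (i in seq_len(nrow(domains)))
      if (!domains$transcript_id[i] %in% names(txRows))
        stop("domain references unknown transcript '",
             domains$transcript_id[i], "'", call. = FALSE)

  genes <- list()
  for (g in geneRows) {
    txs <- Filter(function(t) t$parent == g$id, txRows)
    trList <- lapply(txs, function(t) {
      ex <- exonsByTx[[t$id]]
      if (is.null(ex))
        stop("transcript '", t$id, "' has no exons", call. = FALSE)
      ex <- ex[order(ex[, 1L]), , drop = FALSE]
      storage.mode(ex) <- "integer"
      colnames(ex) <- c("begin", "end")
      cs <- cdsByTx[[t$id]]
      cds <- if (is.null(cs)) integer() else {
        ## normalize possibly fragmented CDS rows into a single span
        as.integer(c(min(cs[, 1L]), max(cs[, 2L])))
      }
      strand <- if (nzchar(t$strand)) t$strand else g$strand
      new("TranscriptModel", transcriptId = t$id, strand = strand,
          exons = ex, cdsSpan = cds, proteinId = NA_character_)
    })
    names(trList) <- NULL
    genes[[g$id]] <- new("GeneModel", geneId = g$id, strand = g$strand,
                         span = as.integer(g$span), transcripts = trList)
  }
  names(genes) <- NULL
  annotationSet(genes = genes, domains = domains, repeats = repeats,
                known = known)
}

#' Write an annotation set back to TSV
#'
#' Inverse of [readAnnotationTsv()]: re-reading the written file yields
#' feature-identical records.
#'
#' @param ann an [AnnotationSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationTsv <- function(ann, path) {
  rows <- list(paste(.ANN_HEADER, collapse = "\t"))
  add <- function(...) rows[[length(rows) + 1L]] <<-
    paste(c(...), collapse = "\t")
  for (g in ann@genes) {
    add("gene", g@geneId, "", g@span[1L], g@span[2L], g@strand, "")
    for (tr in g@transcripts) {
      env <- c(min(tr@exons[, 1L]), max(tr@exons[, 2L]))
      add("transcript", tr@transcriptId, g@geneId, env[1L], env[2L],
          tr@strand, "")
      for (i in seq_len(nrow(tr@exons)))
        add("exon", "", tr@transcriptId, tr@exons[i, 1L], tr@exons[i, 2L],
            tr@strand, "")
      if (length(tr@cdsSpan))
        add("cds", "", tr@transcriptId, tr@cdsSpan[1L], tr@cdsSpan[2L],
            tr@strand, "")
    }
  }
  d <- ann@domains
  for (i in seq_len(nrow(d)))
    add("domain", "", d$transcript_id[i], d$aa_begin[i], d$aa_end[i], "",
        paste0("name=", d$domain_name[i]))
  r <- ann@repeats
  for (i in seq_len(nrow(r)))
    add("repeat", "", "", r$begin[i], r$end[i], "",
        paste0("name=", r$repeat_name[i]))
  k <- ann@known
  for (i in seq_len(nrow(k)))
    add("known_variant", k$dbsnp_id[i], "", k$begin[i], k$end[i], "", "")
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Validate an annotation set against the reference region
#'
#' Reports (rather than throws) human-readable violations: intervals
#' outside the region, exon overlaps within a transcript, a CDS span not
#' contained in the transcript's exons, and (warning class) a concatenated
#' CDS length not divisible by 3.
#'
#' @param ann an [AnnotationSet-class].
#' @param ref a [ReferenceRegion-class].
#' @return data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `feature`, `message`; zero rows when the annotation is consistent.
#' @export
validateAnnotation <- function(ann, ref) {
  s <- regionLength(ref)
  out <- data.frame(severity = character(), feature = character(),
                    message = character(), stringsAsFactors = FALSE)
  flag <- function(severity, feature, message)
    out <<- rbind(out, data.frame(severity = severity, feature = feature,
                                  message = message, stringsAsFactors = FALSE))
  checkRange <- function(b, e, feature) {
    if (b < 0L || e > s)
      flag("error", feature,
           paste0("interval (", b, ", ", e, ") out of range [0, ", s, "]"))
  }
  for (g in ann@genes) {
    checkRange(g@span[1L], g@span[2L], g@geneId)
    for (tr in g@transcripts) {
      ex <- tr@exons
      for (i in seq_len(nrow(ex)))
        checkRange(ex[i, 1L], ex[i, 2L], tr@transcriptId)
      if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
        flag("error", tr@transcriptId, "overlapping exons within transcript")
      if (length(tr@cdsSpan)) {
        cb <- tr@cdsSpan[1L]; ce <- tr@cdsSpan[2L]
        inExonB <- any(ex[, 1L] <= cb & cb < ex[, 2L])
        inExonE <- any(ex[, 1L] < ce & ce <= ex[, 2L])
        if (!inExonB || !inExonE)
          flag("error", tr@transcriptId,
               "CDS begin/end not inside an exon")
        else {
          len <- sum(pmax(0L, pmin(ex[, 2L], ce) - pmax(ex[, 1L], cb)))
          if (len %% 3L != 0L)
            flag("warning", tr@transcriptId,
                 paste0("CDS length ", len, " not a multiple of 3"))
        }
      }
    }
  }
  for (i in seq_len(nrow(ann@repeats)))
    checkRange(ann@repeats$begin[i], ann@repeats$end[i],
               ann@repeats$repeat_name[i])
  for (i in seq_len(nrow(ann@known)))
    checkRange(ann@known$begin[i], ann@known$end[i], ann@known$dbsnp_id[i])
  out
}
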