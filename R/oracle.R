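#' Brute-force position labeler (independent oracle)
#'
#' Labels a single-base substitution at 0-space position `p` (the base
#' covering the span `(p, p+1)`) by a straight-line linear scan over every
#' annotated feature, with naive per-rule arithmetic.  This function
#' deliberately shares no code with [classifyVariant()] and its helpers:
#' it exists as an independent verification path, and the test suite
#' asserts exact agreement of the two over every position of seeded
#' fixtures.
#'
#' @param position 0-space position of the substituted base.
#' @param fixture a [generateFixture()] result (only its annotation tables
#'   are consulted).
#' @param allele the substituted base; accepted for signature parity but
#'   unused — the positional labels of a single-base substitution do not
#'   depend on the allele.
#' @param promoterWindow,donorWindow,acceptorWindow window sizes in bases.
#' @return sorted character vector in the [labelSet()] vocabulary:
#'   `"known"`, `"repeat"`, `"intergenic"` and
#'   `"<gene>:<transcript>:<label>"` entries.
#' @export
oracleLabel <- function(position, fixture, allele = "N",
                        promoterWindow = 1000L, donorWindow = 10L,
                        acceptorWindow = 6L) {
  p <- as.integer(position)
  ann <- fixture$ann
  out <- character()

  k <- ann@known
  for (i in seq_len(nrow(k))) {
    kb <- k$begin[i]; ke <- k$end[i]
    hit <- if (kb == ke) (kb == p || kb == p + 1L) else (kb <= p && p < ke)
    if (hit) { out <- c(out, "known"); break }
  }
  r <- ann@repeats
  for (i in seq_len(nrow(r))) {
    rb <- r$begin[i]; re <- r$end[i]
    hit <- if (rb == re) (rb == p || rb == p + 1L) else (rb <= p && p < re)
    if (hit) { out <- c(out, "repeat"); break }
  }

  genic <- FALSE
  for (g in ann@genes) {
    for (tr in g@transcripts) {
      lab <- character()
      ex <- tr@exons
      envb <- min(ex[, 1L]); enve <- max(ex[, 2L])
      plus <- tr@strand == "+"
      if (p < envb) {
        kdist <- envb - p
        if (kdist <= promoterWindow)
          lab <- if (plus) "upstream_promoter" else "downstream_transcript"
      } else if (p >= enve) {
        kdist <- p - enve + 1L
        if (kdist <= promoterWindow)
          lab <- if (plus) "downstream_transcript" else "upstream_promoter"
      } else {
        exonHit <- FALSE
        for (i in seq_len(nrow(ex)))
          if (ex[i, 1L] <= p && p < ex[i, 2L]) exonHit <- TRUE
        if (exonHit) {
          lab <- "exonic"
          if (length(tr@cdsSpan) == 0L) {
            lab <- c(lab, "noncoding_exon")
          } else {
            cb <- tr@cdsSpan[1L]; ce <- tr@cdsSpan[2L]
            if (p < cb)
              lab <- c(lab, if (plus) "five_prime_UTR" else "three_prime_UTR")
            else if (p >= ce)
              lab <- c(lab, if (plus) "three_prime_UTR" else "five_prime_UTR")
            else lab <- c(lab, "CDS")
          }
        } else {
          lab <- "intronic"
          for (i in seq_len(nrow(ex) - 1L)) {
            el <- ex[i, 2L]; br <- ex[i + 1L, 1L]
            if (p >= el && p < br) {
              donorOff <- if (plus) p - el + 1L else br - p
              acceptorOff <- if (plus) br - p else p - el + 1L
              if (donorOff <= donorWindow)
                lab <- c(lab, "five_prime_splice_site")
              if (acceptorOff <= acceptorWindow)
                lab <- c(lab, "three_prime_splice_site")
            }
          }
        }
      }
      if (length(lab)) {
        genic <- TRUE
        out <- c(out, paste0(g@geneId, ":", tr@transcriptId, ":", lab))
      }
    }
  }
  if (!genic) out <- c(out, "intergenic")
  sort(unique(out))
}
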