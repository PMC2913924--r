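.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read an NCBI-format amino-acid substitution matrix
#'
#' Parses the standard NCBI text layout (`#` comment lines, a header row
#' of single-letter residue codes, one labelled row of integer scores per
#' residue).  The packaged BLOSUM30 — the matrix used by the default
#' conserved/unconserved call — ships at
#' `system.file("extdata", "BLOSUM30.txt", package = "VariantHierarchy")`;
#' any matrix in the same format (e.g. BLOSUM62) can be substituted.
#'
#' @param path path to the matrix file; defaults to the packaged BLOSUM30.
#' @return integer matrix with residue dimnames, restricted to rows and
#'   columns present in the file (includes ambiguity codes and `*` when the
#'   file carries them).
#' @export
readSubstitutionMatrix <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "BLOSUM30.txt",
                        package = "VariantHierarchy", mustWork = TRUE)
  if (!file.exists(path))
    stop("substitution matrix file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  m <- matrix(NA_integer_, length(lines) - 1L, length(cols))
  rows <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    f <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1L]]
    rows[i] <- f[1L]
    m[i, ] <- as.integer(f[-1L])
  }
  dimnames(m) <- list(rows, cols)
  if (!all(.AA20 %in% rows) || !all(.AA20 %in% cols))
    stop("matrix does not cover the 20 standard amino acids", call. = FALSE)
  if (!isSymmetric(unname(m[cols, cols])))
    stop("substitution matrix is not symmetric", call. = FALSE)
  m
}

#' Conserved / unconserved call for an amino-acid substitution
#'
#' A non-synonymous substitution is *unconserved* when the substitution
#' matrix score of the transition is negative, and *conserved* otherwise
#' (score >= 0).  Any shift to a stop codon (`alt == "*"`) is unconserved
#' regardless of the matrix.
#'
#' @param refAa,altAa single-letter amino acids; `"*"` denotes stop.
#' @param matrix substitution matrix from [readSubstitutionMatrix()]
#'   (default: packaged BLOSUM30).
#' @return `"conserved"` or `"unconserved"`.
#' @examples
#' conservationClass("I", "V")  # BLOSUM30 score 4: conserved
#' conservationClass("N", "W")  # BLOSUM30 score -7: unconserved
#' conservationClass("Q", "*")  # stop gain: unconserved
#' @export
conservationClass <- function(refAa, altAa,
                              matrix = readSubstitutionMatrix()) {
  if (identical(altAa, "*")) return("unconserved")
  if (!refAa %in% .AA20 || !altAa %in% .AA20)
    stop("amino acid not in matrix: ", refAa, "/", altAa, call. = FALSE)
  if (matrix[refAa, altAa] < 0L) "unconserved" else "conserved"
}
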