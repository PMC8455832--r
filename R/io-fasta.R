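#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased on read and validated against the alphabet
#' `{A,C,G,T,N}`. Record ids (the first whitespace-delimited token of the
#' header) must be unique.
#'
#' @param path path to a FASTA file.
#' @param permissive if `TRUE`, characters outside `ACGTN` (e.g. IUPAC
#'   ambiguity codes) are mapped to `N` with a warning instead of raising an
#'   error.
#' @return A data.frame with one row per record and columns `id`,
#'   `description` (remainder of the header, `""` when absent), `seq` and
#'   `length`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  if (file.size(path) == 0) {
    return(data.frame(id = character(), description = character(),
                      seq = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  # readBStringSet accepts any letters; validation is done here so errors
  # can report the offending record and position.
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stopf("FASTA record with empty id in %s", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("duplicate FASTA ids: %s", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(ss))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    if (!permissive) {
      stopf("non-ACGTN character '%s' in record '%s' at position %d",
            substr(seqs[i], bad[i], bad[i]), ids[i], bad[i])
    }
    warnf("mapping non-ACGTN characters to N (first: record '%s' position %d)",
          ids[i], bad[i])
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  data.frame(id = ids, description = desc, seq = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write DNA records to a FASTA file
#'
#' @param records a data.frame as returned by [read_fasta()] (columns `id`,
#'   `seq`, optionally `description`).
#' @param path output path.
#' @param wrap line width for the sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 80) {
  assert_cols(records, c("id", "seq"), "FASTA records")
  ss <- Biostrings::DNAStringSet(records$seq)
  desc <- records$description %||% rep("", nrow(records))
  names(ss) <- ifelse(is.na(desc) | desc == "", records$id,
                      paste(records$id, desc))
  Biostrings::writeXStringSet(ss, filepath = path, width = wrap)
  invisible(path)
}
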