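# Tabular local-alignment hit tables (BLAST outfmt-6 dialect).
#
# Column order: qseqid sseqid pident length mismatch gapopen qstart qend
# sstart send evalue bitscore [gaps]. The 13th column (total gapped columns)
# is optional; when absent, `gaps` is set to NA and divergence statistics
# fall back to `gapopen` with a warning.

aln_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
aln_num_cols <- setdiff(aln_cols, c("qseqid", "sseqid"))

#' Parse a tabular alignment hit table
#'
#' Reads the 12-column standard tabular alignment format, or the 13-column
#' variant whose extra column holds the total number of gapped columns.
#' Minus-strand hits are encoded in the input by `sstart > send`; on parse a
#' `strand` column is derived and normalized subject coordinates `s_lo <=
#' s_hi` are added (the printed `sstart`/`send` are kept as-is).
#'
#' @param path path to the tab-separated hit table (no header).
#' @param dialect `"auto"` (default; sniffed from the first line),
#'   `"standard"` (12 columns) or `"gapped"` (13 columns).
#' @return A data.frame with columns `qseqid, sseqid, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore, gaps,
#'   strand, s_lo, s_hi`. `gaps` is `NA` for the 12-column dialect.
#' @export
parse_alignment_table <- function(path, dialect = c("auto", "standard", "gapped")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("alignment table not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_alignment_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ncol_expected <- switch(dialect,
    auto = nf[1],
    standard = 12L,
    gapped = 13L)
  if (!ncol_expected %in% c(12L, 13L))
    stopf("line 1: expected 12 or 13 tab-separated columns, found %d", nf[1])
  bad <- which(nf != ncol_expected)
  if (length(bad))
    stopf("line %d: expected %d tab-separated columns, found %d",
          bad[1], ncol_expected, nf[bad[1]])
  m <- matrix(unlist(fields), ncol = ncol_expected, byrow = TRUE)
  df <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  for (i in 3:12) {
    v <- suppressWarnings(as.numeric(m[, i]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stopf("line %d: non-numeric value '%s' in column %d (%s)",
            j, m[j, i], i, aln_cols[i])
    }
    df[[aln_cols[i]]] <- v
  }
  df$gaps <- if (ncol_expected == 13L) {
    v <- suppressWarnings(as.numeric(m[, 13]))
    if (anyNA(v))
      stopf("line %d: non-numeric value '%s' in column 13 (gaps)",
            which(is.na(v))[1], m[which(is.na(v))[1], 13])
    v
  } else NA_real_
  for (col in c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send"))
    df[[col]] <- as.integer(df[[col]])
  df$gaps <- ifelse(is.na(df$gaps), NA_integer_, as.integer(df$gaps))
  validate_alignment_table(df)
}

empty_alignment_table <- function() {
  df <- data.frame(qseqid = character(), sseqid = character(),
                   pident = numeric(), length = integer(),
                   mismatch = integer(), gapopen = integer(),
                   qstart = integer(), qend = integer(),
                   sstart = integer(), send = integer(),
                   evalue = numeric(), bitscore = numeric(),
                   gaps = integer(), stringsAsFactors = FALSE)
  df$strand <- character()
  df$s_lo <- integer()
  df$s_hi <- integer()
  df
}

validate_alignment_table <- function(df) {
  if (any(df$qstart < 1) || any(df$qend < df$qstart))
    stopf("invalid query coordinates (need 1 <= qstart <= qend)")
  if (any(df$pident < 0 | df$pident > 100))
    stopf("pident outside [0, 100]")
  if (any(df$evalue < 0)) stopf("negative evalue")
  df$strand <- ifelse(df$sstart > df$send, "-", "+")
  df$s_lo <- pmin(df$sstart, df$send)
  df$s_hi <- pmax(df$sstart, df$send)
  df
}

#' Write an alignment hit table (13-column dialect)
#'
#' Inverse of [parse_alignment_table()]; minus-strand records are written
#' with `sstart > send`.
#'
#' @param records alignment data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(records, path) {
  assert_cols(records, aln_cols, "alignment table")
  gaps <- records$gaps
  if (is.null(gaps) || all(is.na(gaps))) gaps <- records$gapopen
  out <- data.frame(records$qseqid, records$sseqid,
                    formatC(records$pident, format = "fg", digits = 6),
                    records$length, records$mismatch, records$gapopen,
                    records$qstart, records$qend, records$sstart,
                    records$send,
                    formatC(records$evalue, format = "g", digits = 6),
                    formatC(records$bitscore, format = "fg", digits = 8),
                    gaps)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Construct alignment rows from components (used by the simulators).
make_alignment <- function(qseqid, sseqid, pident, length, mismatch, gapopen,
                           qstart, qend, sstart, send, evalue = 0,
                           bitscore = 2 * length, gaps = gapopen) {
  df <- data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
                   length = as.integer(length), mismatch = as.integer(mismatch),
                   gapopen = as.integer(gapopen), qstart = as.integer(qstart),
                   qend = as.integer(qend), sstart = as.integer(sstart),
                   send = as.integer(send), evalue = evalue,
                   bitscore = bitscore, gaps = as.integer(gaps),
                   stringsAsFactors = FALSE)
  validate_alignment_table(df)
}
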