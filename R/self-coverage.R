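# Haplotype-separation diagnostics from genome self-alignment.
#
# An assembly in which both haplotypes of a heterozygous region were kept as
# separate contigs aligns against itself twice over those regions. The
# multiplicity profile (fraction of bases covered exactly 0,1,2,... times by
# filtered self-hits, counting the trivial full-length self-hit) therefore
# diagnoses haplotype separation: a haplotype-merged genome is mostly 1x,
# a haplotype-separated one mostly 2x.

#' Filtering thresholds for self-alignment hits
#'
#' Hits are kept only when alignment length, percent identity and bitscore
#' all strictly exceed their thresholds.
#'
#' @param min_aln_length minimum alignment length (bp), exclusive.
#' @param min_identity minimum percent identity, exclusive.
#' @param min_bitscore minimum bitscore, exclusive.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_aln_length = 300, min_identity = 75,
                          min_bitscore = 1000) {
  stopifnot(min_aln_length >= 0, min_identity >= 0, min_bitscore >= 0)
  structure(list(min_aln_length = min_aln_length,
                 min_identity = min_identity,
                 min_bitscore = min_bitscore),
            class = "filter_params")
}

#' Filter alignment hits on length, identity and bitscore
#'
#' @param records alignment data.frame (see [parse_alignment_table()]).
#' @param params a [filter_params()] object. All three thresholds are
#'   strict: a hit with `length == min_aln_length` is dropped.
#' @return The kept rows, order preserved.
#' @export
filter_alignments <- function(records, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  assert_cols(records, c("length", "pident", "bitscore"), "alignment records")
  keep <- records$length > params$min_aln_length &
    records$pident > params$min_identity &
    records$bitscore > params$min_bitscore
  records[keep, , drop = FALSE]
}

# A hit is the trivial diagonal self-hit when query and subject are the same
# sequence over identical coordinates on the plus strand.
is_diagonal_hit <- function(records) {
  records$qseqid == records$sseqid &
    records$qstart == records$s_lo & records$qend == records$s_hi &
    records$strand == "+"
}

#' Self-coverage multiplicity profile
#'
#' For every sequence, the multiplicity of base `b` is the number of
#' filtered hits whose query interval covers `b` (the trivial diagonal
#' self-hit included, so unique sequence has multiplicity 1). Fractions of
#' bases at multiplicity 0, 1, 2, 3, 4 and 5+ are tabulated per sequence
#' and genome-wide (length-weighted). Computed by an endpoint sweep, not
#' per-base counting.
#'
#' @param records filtered alignment data.frame; multiplicity is counted on
#'   query coordinates only (the reciprocal direction of each hit covers the
#'   partner sequence when it is the query).
#' @param seq_lengths named numeric vector of sequence lengths; every
#'   `qseqid` must be present.
#' @return A list of class `multiplicity_profile` with `per_seq` (data.frame
#'   `id, length, f0..f5plus`), `genome` (one-row data.frame) and
#'   `total_bases`.
#' @export
multiplicity_profile <- function(records, seq_lengths) {
  assert_cols(records, c("qseqid", "qstart", "qend"), "alignment records")
  if (is.null(names(seq_lengths)) || any(!nzchar(names(seq_lengths))))
    stopf("seq_lengths must be a named vector")
  unknown <- setdiff(unique(records$qseqid), names(seq_lengths))
  if (length(unknown))
    stopf("query id(s) missing from seq_lengths: %s",
          paste(unknown, collapse = ", "))
  ids <- names(seq_lengths)
  counts <- matrix(0, nrow = length(ids), ncol = 6,
                   dimnames = list(ids, paste0("m", c(0:4, "5plus"))))
  by_seq <- split(seq_len(nrow(records)), records$qseqid)
  for (id in ids) {
    L <- seq_lengths[[id]]
    idx <- by_seq[[id]]
    if (is.null(idx)) {
      counts[id, 1] <- L
      next
    }
    qs <- records$qstart[idx]
    qe <- records$qend[idx]
    over <- which(qe > L)
    if (length(over))
      stopf("hit %s:[%d,%d] exceeds sequence length %d",
            id, qs[over[1]], qe[over[1]], L)
    # endpoint sweep: multiplicity is piecewise constant between breakpoints
    ev_pos <- c(1, qs, qe + 1, L + 1)
    bp <- sort(unique(ev_pos))
    delta <- numeric(length(bp))
    delta[match(qs, bp)] <- 0 # ensure slots exist
    for (k in seq_along(idx)) {
      delta[match(qs[k], bp)] <- delta[match(qs[k], bp)] + 1
      delta[match(qe[k] + 1, bp)] <- delta[match(qe[k] + 1, bp)] - 1
    }
    mult <- cumsum(delta)
    seg_len <- diff(c(bp, L + 1))
    keep <- bp <= L & seg_len > 0
    mult <- pmin(mult[keep], 5)
    seg_len <- seg_len[keep]
    for (m in 0:5)
      counts[id, m + 1] <- sum(seg_len[mult == m])
  }
  frac <- counts / as.numeric(seq_lengths)
  per_seq <- data.frame(id = ids, length = as.numeric(seq_lengths),
                        f0 = frac[, 1], f1 = frac[, 2], f2 = frac[, 3],
                        f3 = frac[, 4], f4 = frac[, 5], f5plus = frac[, 6],
                        row.names = NULL, stringsAsFactors = FALSE)
  total <- sum(seq_lengths)
  gfrac <- colSums(counts) / total
  genome <- data.frame(id = "genome", length = total,
                       f0 = gfrac[1], f1 = gfrac[2], f2 = gfrac[3],
                       f3 = gfrac[4], f4 = gfrac[5], f5plus = gfrac[6],
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_seq = per_seq, genome = genome, total_bases = total),
            class = "multiplicity_profile")
}

#' @export
print.multiplicity_profile <- function(x, ...) {
  g <- x$genome
  cat(sprintf(
    "multiplicity_profile: %d sequence(s), %.0f bp\n  genome-wide: 0x %.1f%%  1x %.1f%%  2x %.1f%%  3x %.1f%%  4x %.1f%%  5+x %.1f%%\n",
    nrow(x$per_seq), x$total_bases, 100 * g$f0, 100 * g$f1, 100 * g$f2,
    100 * g$f3, 100 * g$f4, 100 * g$f5plus))
  invisible(x)
}

#' Allele divergence (heterozygosity) from self-alignment hits
#'
#' Aggregates the off-diagonal filtered hits — the allelic alignments
#' between haplotype copies — into mismatches/kb, gaps/kb and
#' length-weighted mean percent identity. Each reciprocal direction of an
#' allelic pair is a distinct record and counts once. When the 13th `gaps`
#' column was absent from the input, `gapopen` is used as a lower bound with
#' a warning.
#'
#' @param records filtered alignment data.frame.
#' @param inter_contig_only if `TRUE`, restrict to hits between different
#'   sequences (excluding off-diagonal intra-contig hits from internal
#'   repeats).
#' @return A list of class `divergence_summary` with `mismatches_per_kb`,
#'   `gaps_per_kb`, `mean_identity_percent`, `total_allelic_aln_length`,
#'   `n_records` and `rates_defined`.
#' @export
allelic_divergence <- function(records, inter_contig_only = FALSE) {
  assert_cols(records, c("qseqid", "sseqid", "pident", "length", "mismatch"),
              "alignment records")
  off <- records[!is_diagonal_hit(records), , drop = FALSE]
  if (inter_contig_only)
    off <- off[off$qseqid != off$sseqid, , drop = FALSE]
  if (nrow(off) == 0) {
    return(structure(list(mismatches_per_kb = NA_real_,
                          gaps_per_kb = NA_real_,
                          mean_identity_percent = NA_real_,
                          total_allelic_aln_length = 0,
                          n_records = 0L, rates_defined = FALSE),
                     class = "divergence_summary"))
  }
  gaps <- off$gaps
  if (is.null(gaps) || anyNA(gaps)) {
    warnf("total-gap column absent; using gap opens as a lower bound for gaps/kb")
    gaps <- ifelse(is.na(off$gaps %||% NA), off$gapopen, off$gaps)
  }
  tot <- sum(off$length)
  structure(list(
    mismatches_per_kb = 1000 * sum(off$mismatch) / tot,
    gaps_per_kb = 1000 * sum(gaps) / tot,
    mean_identity_percent = sum(off$pident * off$length) / tot,
    total_allelic_aln_length = tot,
    n_records = nrow(off), rates_defined = TRUE),
    class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  if (!x$rates_defined) {
    cat("divergence_summary: no off-diagonal alignments (rates undefined)\n")
  } else {
    cat(sprintf(
      "divergence_summary: %.1f mismatches/kb, %.1f gaps/kb, %.1f%% identity over %.0f bp (%d hits)\n",
      x$mismatches_per_kb, x$gaps_per_kb, x$mean_identity_percent,
      x$total_allelic_aln_length, x$n_records))
  }
  invisible(x)
}

#' Genome-level self-coverage report
#'
#' Combines a multiplicity profile and a divergence summary into one report
#' object with TSV writers.
#'
#' @param profile a [multiplicity_profile()].
#' @param divergence optional [allelic_divergence()] summary.
#' @return A list of class `genome_summary`.
#' @export
genome_summary <- function(profile, divergence = NULL) {
  stopifnot(inherits(profile, "multiplicity_profile"))
  structure(list(profile = profile, divergence = divergence),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  print(x$profile)
  if (!is.null(x$divergence)) print(x$divergence)
  invisible(x)
}

#' Write a genome summary to a directory
#'
#' Writes `multiplicity_per_seq.tsv`, `multiplicity_genome.tsv` and
#' `selfcov_summary.json`.
#'
#' @param summary a [genome_summary()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "genome_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- summary$profile
  write.table(p$per_seq, file.path(dir, "multiplicity_per_seq.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(p$genome, file.path(dir, "multiplicity_genome.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  js <- list(genome = as.list(p$genome))
  if (!is.null(summary$divergence))
    js$divergence <- unclass(summary$divergence)
  jsonlite::write_json(js, file.path(dir, "selfcov_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
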