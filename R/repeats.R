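# Detection of high-copy repeat loci from read-depth tracks.
#
# When resequencing reads are mapped to a single-copy reference region, a
# repeat family collapses onto its one reference copy and shows up as a
# window of strongly elevated depth (up to ~100-fold in the motivating
# data). Loci are detected by tiling fixed windows over the track,
# thresholding window means against a robust background, merging runs of
# flagged windows, then segmented into uniformly-high vs mosaic parts, and
# characterised by copy counting and six-frame ORF scanning.

#' Parameters for depth-anomaly repeat scanning
#'
#' @param window tile width (bp).
#' @param fold_threshold windows whose mean depth reaches
#'   `fold_threshold * background` are flagged.
#' @param merge_gap maximum gap (bp) between flagged runs merged into one
#'   locus.
#' @param min_locus_len minimum locus length (bp).
#' @param low_fold sub-segmentation threshold: windows inside a locus with
#'   mean depth below `low_fold * background` are labelled `low`.
#' @param background optional fixed background depth; default (`NULL`) uses
#'   the median depth of the analysed track, which is robust to the loci
#'   themselves.
#' @return A list of class `repeat_scan_params`.
#' @export
repeat_scan_params <- function(window = 100, fold_threshold = 10,
                               merge_gap = 500, min_locus_len = 1000,
                               low_fold = 3, background = NULL) {
  stopifnot(window >= 1, fold_threshold > low_fold, low_fold >= 1)
  structure(list(window = as.integer(window),
                 fold_threshold = fold_threshold,
                 merge_gap = as.integer(merge_gap),
                 min_locus_len = as.integer(min_locus_len),
                 low_fold = low_fold, background = background),
            class = "repeat_scan_params")
}

track_background <- function(track, params) {
  bg <- params$background %||% stats::median(track$depth)
  if (bg <= 0) stopf("background depth is 0; cannot scan for enrichment")
  bg
}

# Tile non-overlapping windows over [1, L]; the trailing partial window (if
# any) is kept so every base belongs to exactly one window.
tile_windows <- function(L, window) {
  starts <- seq.int(1L, L, by = window)
  data.frame(start = starts, end = pmin(starts + window - 1L, L))
}

#' Detect high-coverage repeat loci in a depth track
#'
#' Non-overlapping windows are tiled over the track and flagged when their
#' mean depth reaches `fold_threshold * background`; runs of flagged windows
#' separated by gaps of at most `merge_gap` are merged and loci shorter than
#' `min_locus_len` are dropped.
#'
#' @param track a [depth_track()].
#' @param params a [repeat_scan_params()] object.
#' @return data.frame `seq_id`, `start`, `end`, `length`, `mean_fold`
#'   (locus mean depth / background), `max_fold` (highest window fold
#'   inside), `background`.
#' @export
detect_high_coverage_loci <- function(track, params = repeat_scan_params()) {
  stopifnot(inherits(track, "depth_track"))
  if (track$length < params$window)
    stopf("track shorter than one window (%d < %d)",
          track$length, params$window)
  bg <- track_background(track, params)
  w <- tile_windows(track$length, params$window)
  wmean <- vapply(seq_len(nrow(w)), function(i)
    mean(track$depth[w$start[i]:w$end[i]]), numeric(1))
  flagged <- wmean >= params$fold_threshold * bg
  if (!any(flagged)) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      mean_fold = numeric(), max_fold = numeric(),
                      background = numeric(), stringsAsFactors = FALSE))
  }
  fs <- w$start[flagged]
  fe <- w$end[flagged]
  # merge flagged runs whose inter-run gap is <= merge_gap
  merged <- list(c(fs[1], fe[1]))
  for (i in seq_along(fs)[-1]) {
    last <- merged[[length(merged)]]
    if (fs[i] - last[2] - 1L <= params$merge_gap) {
      merged[[length(merged)]][2] <- fe[i]
    } else merged[[length(merged) + 1]] <- c(fs[i], fe[i])
  }
  loci <- do.call(rbind, lapply(merged, function(x) {
    len <- x[2] - x[1] + 1L
    if (len < params$min_locus_len) return(NULL)
    seg <- track$depth[x[1]:x[2]]
    inside <- wmean[w$start >= x[1] & w$end <= x[2]]
    data.frame(seq_id = track$seq_id, start = x[1], end = x[2],
               length = len, mean_fold = mean(seg) / bg,
               max_fold = if (length(inside)) max(inside) / bg else
                 max(seg) / bg,
               background = bg, stringsAsFactors = FALSE)
  }))
  if (is.null(loci)) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      mean_fold = numeric(), max_fold = numeric(),
                      background = numeric(), stringsAsFactors = FALSE))
  }
  loci
}

#' Segment a repeat locus into high vs low windows
#'
#' Windows tiled inside the locus are labelled `low` when their mean depth
#' is below `low_fold * background` (the mosaic part) and `high` otherwise;
#' adjacent same-label windows are merged. The segments partition the locus
#' exactly.
#'
#' @param track the [depth_track()] the locus came from.
#' @param locus one row of [detect_high_coverage_loci()] output (or any
#'   data.frame/list with `start` and `end`).
#' @param params a [repeat_scan_params()] object.
#' @return data.frame `start`, `end`, `label` in `{high, low}`.
#' @export
segment_locus <- function(track, locus, params = repeat_scan_params()) {
  stopifnot(inherits(track, "depth_track"))
  bg <- track_background(track, params)
  lo <- as.integer(locus$start[1] %||% locus[["start"]])
  hi <- as.integer(locus$end[1] %||% locus[["end"]])
  stopifnot(1 <= lo, lo <= hi, hi <= track$length)
  w <- tile_windows(hi - lo + 1L, params$window)
  w$start <- w$start + lo - 1L
  w$end <- w$end + lo - 1L
  lab <- vapply(seq_len(nrow(w)), function(i) {
    if (mean(track$depth[w$start[i]:w$end[i]]) < params$low_fold * bg)
      "low" else "high"
  }, character(1))
  r <- rle(lab)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1L, head(ends_idx, -1) + 1L)
  data.frame(start = w$start[starts_idx], end = w$end[ends_idx],
             label = r$values, stringsAsFactors = FALSE)
}

#' Count repeat copies in an assembly from locus-query hits
#'
#' Hits of a locus part against an assembly are filtered with the standard
#' thresholds, overlapping subject intervals (>= 1 bp overlap; abutting
#' intervals stay separate) are merged per subject sequence, and the copy
#' count is the number of merged intervals summed over subjects.
#'
#' @param hits alignment data.frame (locus part as query, assembly contigs
#'   as subject).
#' @param params a [filter_params()] object.
#' @return Integer copy count.
#' @export
count_copies <- function(hits, params = filter_params()) {
  kept <- filter_alignments(hits, params)
  if (nrow(kept) == 0) return(0L)
  total <- 0L
  for (sid in unique(kept$sseqid)) {
    h <- kept[kept$sseqid == sid, , drop = FALSE]
    total <- total + nrow(merge_intervals(h$s_lo, h$s_hi, min_overlap = 1L))
  }
  total
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Six-frame open reading frame scan
#'
#' An ORF runs from the most-upstream ATG to the next in-frame stop codon
#' (one ORF per stop per frame). Codons containing `N` never match ATG or a
#' stop. Reverse-strand ORFs are reported in forward coordinates with
#' strand `-`; `start`/`end` span ATG through the stop codon and
#' `aa_length` excludes the stop.
#'
#' @param seq a DNA string, or a one-row data.frame from [read_fasta()].
#' @param min_aa minimum protein length in amino acids (default 100).
#' @param id sequence id for the output (taken from `seq$id` when a record
#'   is passed).
#' @return data.frame `seq_id`, `strand`, `frame` (0/1/2 on the reading
#'   strand), `start`, `end`, `aa_length`, ordered by `start`.
#' @export
find_orfs <- function(seq, min_aa = 100, id = NULL) {
  if (is.data.frame(seq)) {
    id <- id %||% seq$id[1]
    seq <- seq$seq[1]
  }
  id <- id %||% "seq"
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stopf("sequence contains non-ACGTN characters")
  L <- nchar(seq)
  scan_strand <- function(s, strand) {
    res <- list()
    for (frame in 0:2) {
      starts <- seq.int(1L + frame, L - 2L, by = 3L)
      if (length(starts) == 0 || starts[1] > L - 2L) next
      codons <- substring(s, starts, starts + 2L)
      open_atg <- NA_integer_ # codon index of most-upstream ATG since last stop
      for (k in seq_along(codons)) {
        cd <- codons[k]
        if (is.na(open_atg) && cd == "ATG") open_atg <- k
        if (cd %in% STOP_CODONS) {
          if (!is.na(open_atg)) {
            aa <- k - open_atg
            if (aa >= min_aa) {
              res[[length(res) + 1]] <- c(starts[open_atg],
                                          starts[k] + 2L, frame, aa)
            }
          }
          open_atg <- NA_integer_
        }
      }
    }
    if (length(res) == 0) return(NULL)
    m <- do.call(rbind, res)
    if (strand == "+") {
      data.frame(seq_id = id, strand = "+", frame = m[, 3],
                 start = m[, 1], end = m[, 2], aa_length = m[, 4],
                 stringsAsFactors = FALSE)
    } else {
      # map reverse-strand coordinates back to forward coordinates
      data.frame(seq_id = id, strand = "-", frame = m[, 3],
                 start = L - m[, 2] + 1L, end = L - m[, 1] + 1L,
                 aa_length = m[, 4], stringsAsFactors = FALSE)
    }
  }
  fwd <- scan_strand(seq, "+")
  rev <- scan_strand(rev_comp(seq), "-")
  out <- rbind(fwd, rev)
  if (is.null(out)) {
    return(data.frame(seq_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      aa_length = integer(), stringsAsFactors = FALSE))
  }
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

#' Annotate repeat loci by proximity to ARR17 features
#'
#' Flags each locus as `upstream_of_ARR17` when it lies 5' of the ARR17
#' gene (strand-aware) with a gap inside `upstream_window`, and as
#' `adjacent_to_repeats` when its gap to any ARR17 partial-repeat feature is
#' at most `adjacent_gap`.
#'
#' @param loci data.frame with `seq_id`, `start`, `end`.
#' @param features data.frame with `seq_id`, `start`, `end`, `strand` and
#'   `type` (`"ARR17_gene"` or `"ARR17_repeat"`).
#' @param upstream_window numeric length-2 vector: allowed gap (bp) between
#'   locus and gene start, default `c(15000, 40000)`.
#' @param adjacent_gap maximum gap to a repeat feature (default 10 kb).
#' @return `loci` with added columns `upstream_of_ARR17`, `gene_gap`
#'   (gap to the nearest same-sequence ARR17 gene, `NA` when none),
#'   `adjacent_to_repeats`, `repeat_gap`.
#' @export
annotate_proximity <- function(loci, features,
                               upstream_window = c(15000, 40000),
                               adjacent_gap = 10000) {
  assert_cols(loci, c("seq_id", "start", "end"), "loci")
  assert_cols(features, c("seq_id", "start", "end", "strand", "type"),
              "features")
  genes <- features[features$type == "ARR17_gene", , drop = FALSE]
  reps <- features[features$type == "ARR17_repeat", , drop = FALSE]
  n <- nrow(loci)
  up <- logical(n); gg <- rep(NA_real_, n)
  adj <- logical(n); rg <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[genes$seq_id == loci$seq_id[i], , drop = FALSE]
    for (j in seq_len(nrow(g))) {
      gap <- interval_gap(loci$start[i], loci$end[i], g$start[j], g$end[j])
      if (is.na(gg[i]) || gap < gg[i]) gg[i] <- gap
      # strand-aware 5' test: the locus must be entirely on the 5' side
      is_5prime <- if (g$strand[j] == "+") loci$end[i] < g$start[j]
                   else loci$start[i] > g$end[j]
      if (is_5prime && gap >= upstream_window[1] && gap <= upstream_window[2])
        up[i] <- TRUE
    }
    r <- reps[reps$seq_id == loci$seq_id[i], , drop = FALSE]
    for (j in seq_len(nrow(r))) {
      gap <- interval_gap(loci$start[i], loci$end[i], r$start[j], r$end[j])
      if (is.na(rg[i]) || gap < rg[i]) rg[i] <- gap
      if (gap <= adjacent_gap) adj[i] <- TRUE
    }
  }
  loci$upstream_of_ARR17 <- up
  loci$gene_gap <- gg
  loci$adjacent_to_repeats <- adj
  loci$repeat_gap <- rg
  loci
}
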