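# Locating the sex-determining region (SDR) on assembly contigs and calling
# each SDR haplotype Y or X.
#
# In poplars with an XY system, the Y haplotype of the SDR carries partial
# repeats of the ARR17 gene (two of them arranged as an inverted repeat
# around a HEMA gene fragment); X haplotypes carry none. Marker sequences
# (the reference SDR, ARR17, ARR17 partial repeats, HEMA fragment, MSL,
# PSR, and the shared TCP/CLC/MET1/LRR genes) are aligned to the assembly
# and the resulting hit table drives the classification.

#' Packaged reference coordinates of the sex-locus landmarks
#'
#' Reference intervals of the ARR17 gene, the ARR17 partial-repeat locus,
#' the SDR, and the PSR (Populus-specific repeat) locus with its two parts
#' (the conserved transposase-bearing part over which read coverage stays
#' uniformly high, and the mosaic part interrupted by low-coverage windows),
#' on the male P. trichocarpa "Stettler 14" genome coordinate system.
#'
#' @return data.frame with columns `name`, `seq_id`, `start`, `end`,
#'   `strand`, `length` (1-based inclusive; `length = end - start + 1`).
#' @export
region_spec <- function() {
  df <- data.frame(
    name = c("ARR17_gene", "ARR17_repeat_locus", "SDR",
             "PSR_locus", "PSR_conserved_part", "PSR_mosaic_part"),
    seq_id = c("Chr19", "Chr18", "Chr18", "Chr18", "Chr18", "Chr18"),
    start = c(15907431L, 16290253L, 16200000L,
              16280032L, 16284417L, 16280032L),
    end = c(15910397L, 16308089L, 16320000L,
            16289301L, 16289301L, 16284418L),
    strand = "+",
    stringsAsFactors = FALSE)
  df$length <- df$end - df$start + 1L
  df
}

#' Chain fragmented marker hits into clusters
#'
#' Alignments of one marker sequence against a contig are typically split
#' into several local hits; hits on the same contig and strand whose
#' contig-coordinate gap is at most `chain_gap` are chained into one
#' cluster. The cluster interval spans min..max of the chained hits and the
#' covered query fraction is the merged query-side coverage divided by the
#' marker length.
#'
#' @param hits alignment data.frame with the marker as query (`qseqid`) and
#'   the contig as subject (`sseqid`); filter with [filter_alignments()]
#'   first.
#' @param marker_lengths named vector of marker sequence lengths.
#' @param chain_gap maximum gap (bp) between chained hits; default 20 kb
#'   tolerates the long variable intergenic stretches inside the SDR.
#' @return data.frame with one row per cluster: `marker`, `contig_id`,
#'   `start`, `end`, `strand`, `covered_query_fraction`, `mean_identity`,
#'   `n_hits`.
#' @export
cluster_marker_hits <- function(hits, marker_lengths, chain_gap = 20000) {
  assert_cols(hits, c("qseqid", "sseqid", "qstart", "qend",
                      "s_lo", "s_hi", "strand", "pident", "length"),
              "marker hits")
  unknown <- setdiff(unique(hits$qseqid), names(marker_lengths))
  if (length(unknown))
    stopf("marker(s) missing from marker_lengths: %s",
          paste(unknown, collapse = ", "))
  out <- list()
  groups <- split(seq_len(nrow(hits)),
                  list(hits$qseqid, hits$sseqid, hits$strand), drop = TRUE)
  for (idx in groups) {
    h <- hits[idx, , drop = FALSE]
    h <- h[order(h$s_lo, h$s_hi), , drop = FALSE]
    # chain: new cluster whenever the gap to the running end exceeds chain_gap
    cl <- integer(nrow(h))
    cur <- 1L
    run_end <- h$s_hi[1]
    cl[1] <- cur
    for (i in seq_len(nrow(h))[-1]) {
      gap <- h$s_lo[i] - run_end - 1L
      if (gap > chain_gap) {
        cur <- cur + 1L
        run_end <- h$s_hi[i]
      } else run_end <- max(run_end, h$s_hi[i])
      cl[i] <- cur
    }
    for (k in unique(cl)) {
      hk <- h[cl == k, , drop = FALSE]
      merged_q <- merge_intervals(hk$qstart, hk$qend)
      qcov <- sum(merged_q$end - merged_q$start + 1)
      out[[length(out) + 1]] <- data.frame(
        marker = hk$qseqid[1], contig_id = hk$sseqid[1],
        start = min(hk$s_lo), end = max(hk$s_hi),
        strand = hk$strand[1],
        covered_query_fraction = qcov / marker_lengths[[hk$qseqid[1]]],
        mean_identity = sum(hk$pident * hk$length) / sum(hk$length),
        n_hits = nrow(hk),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(marker = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      strand = character(),
                      covered_query_fraction = numeric(),
                      mean_identity = numeric(), n_hits = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$contig_id, res$marker, res$start), , drop = FALSE]
}

#' Locate the SDR on contigs
#'
#' Emits one SDR call per contig whose best `SDR` marker cluster covers at
#' least `min_query_fraction` of the reference SDR query. A contig carrying
#' two well-separated SDR clusters (a possible chimera) yields two calls,
#' flagged in `multiple_clusters`.
#'
#' @param clusters output of [cluster_marker_hits()].
#' @param min_query_fraction minimum covered fraction of the SDR query.
#' @return data.frame `contig_id`, `start`, `end`, `strand`,
#'   `covered_query_fraction`, `multiple_clusters`.
#' @export
locate_sdr <- function(clusters, min_query_fraction = 0.5) {
  sdr <- clusters[clusters$marker == "SDR" &
                    clusters$covered_query_fraction >= min_query_fraction, ,
                  drop = FALSE]
  if (nrow(sdr) == 0) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      covered_query_fraction = numeric(),
                      multiple_clusters = logical(),
                      stringsAsFactors = FALSE))
  }
  n_per_contig <- table(sdr$contig_id)
  data.frame(contig_id = sdr$contig_id, start = sdr$start, end = sdr$end,
             strand = sdr$strand,
             covered_query_fraction = sdr$covered_query_fraction,
             multiple_clusters = as.vector(n_per_contig[sdr$contig_id] > 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify SDR haplotypes as Y or X
#'
#' A located SDR is called **Y** when at least one `ARR17_repeat` cluster
#' overlaps the SDR interval extended by `flank` on both sides, and **X**
#' when no such cluster exists. Contigs without an SDR call are
#' `unclassified`.
#'
#' @param sdr_calls output of [locate_sdr()].
#' @param clusters marker clusters ([cluster_marker_hits()]); only rows with
#'   `marker == "ARR17_repeat"` are used as evidence.
#' @param flank extension (bp) of the SDR interval on each side when
#'   searching for repeat clusters.
#' @param contigs optional character vector of all contig ids; contigs
#'   without an SDR call are reported as `unclassified`.
#' @return data.frame `contig_id`, `start`, `end`, `strand`,
#'   `haplotype_class` in `{Y, X, unclassified}`, `n_repeat_clusters`.
#' @export
classify_haplotype <- function(sdr_calls, clusters, flank = 50000,
                               contigs = NULL) {
  reps <- clusters[clusters$marker == "ARR17_repeat", , drop = FALSE]
  res <- lapply(seq_len(nrow(sdr_calls)), function(i) {
    ci <- sdr_calls$contig_id[i]
    lo <- sdr_calls$start[i] - flank
    hi <- sdr_calls$end[i] + flank
    n <- sum(reps$contig_id == ci & reps$start <= hi & reps$end >= lo)
    data.frame(contig_id = ci, start = sdr_calls$start[i],
               end = sdr_calls$end[i], strand = sdr_calls$strand[i],
               haplotype_class = if (n >= 1) "Y" else "X",
               n_repeat_clusters = n, stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(contig_id = character(), start = integer(), end = integer(),
               strand = character(), haplotype_class = character(),
               n_repeat_clusters = integer(), stringsAsFactors = FALSE)
  extra <- setdiff(contigs, out$contig_id)
  if (length(extra)) {
    out <- rbind(out, data.frame(contig_id = extra, start = NA_integer_,
                                 end = NA_integer_, strand = NA_character_,
                                 haplotype_class = "unclassified",
                                 n_repeat_clusters = 0L,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Detect ARR17 inverted-repeat arms
#'
#' An inverted repeat is called for every pair of opposite-strand
#' `ARR17_repeat` clusters on one contig whose gap is at most `max_span`
#' and contains a `HEMA` cluster — the HEMA gene fragment between the arms
#' is the identifying signature.
#'
#' @param clusters marker clusters containing `ARR17_repeat` and `HEMA`
#'   rows.
#' @param max_span maximum gap (bp) between the two arms.
#' @return data.frame `contig_id`, `left_start`, `left_end`, `left_strand`,
#'   `right_start`, `right_end`, `right_strand`, `spacer_start`,
#'   `spacer_end`, `hema_present` (always `TRUE` for emitted calls).
#' @export
find_inverted_repeat <- function(clusters, max_span = 10000) {
  reps <- clusters[clusters$marker == "ARR17_repeat", , drop = FALSE]
  hema <- clusters[clusters$marker == "HEMA", , drop = FALSE]
  out <- list()
  for (ci in unique(reps$contig_id)) {
    r <- reps[reps$contig_id == ci, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    h <- hema[hema$contig_id == ci, , drop = FALSE]
    if (nrow(r) < 2) next
    for (i in seq_len(nrow(r) - 1)) for (j in (i + 1):nrow(r)) {
      if (r$strand[i] == r$strand[j]) next
      if (r$start[j] <= r$end[i]) next # overlapping arms: no spacer
      gap <- r$start[j] - r$end[i] - 1L
      if (gap > max_span || gap < 1) next
      sp_lo <- r$end[i] + 1L
      sp_hi <- r$start[j] - 1L
      hema_in <- any(h$start >= sp_lo & h$end <= sp_hi)
      if (!hema_in) next
      out[[length(out) + 1]] <- data.frame(
        contig_id = ci,
        left_start = r$start[i], left_end = r$end[i],
        left_strand = r$strand[i],
        right_start = r$start[j], right_end = r$end[j],
        right_strand = r$strand[j],
        spacer_start = sp_lo, spacer_end = sp_hi,
        hema_present = TRUE, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig_id = character(), left_start = integer(),
                      left_end = integer(), left_strand = character(),
                      right_start = integer(), right_end = integer(),
                      right_strand = character(), spacer_start = integer(),
                      spacer_end = integer(), hema_present = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Call MSL completeness per contig
#'
#' The MSL query (a male-specific lncRNA locus of some poplar sections) is
#' called `complete` when its best cluster covers at least
#' `complete_fraction` of the query, `partial` when covered but below that
#' threshold, and `absent` when no filtered hit exists.
#'
#' @param clusters marker clusters; rows with `marker == "MSL"` are used.
#' @param complete_fraction query-coverage threshold for a complete call.
#' @param contigs optional contig universe; contigs without MSL hits get an
#'   `absent` row.
#' @return data.frame `contig_id`, `status`, `covered_query_fraction`,
#'   `best_identity`.
#' @export
call_msl <- function(clusters, complete_fraction = 0.9, contigs = NULL) {
  msl <- clusters[clusters$marker == "MSL", , drop = FALSE]
  ids <- unique(c(msl$contig_id, contigs))
  res <- lapply(ids, function(ci) {
    m <- msl[msl$contig_id == ci, , drop = FALSE]
    if (nrow(m) == 0) {
      return(data.frame(contig_id = ci, status = "absent",
                        covered_query_fraction = 0,
                        best_identity = NA_real_, stringsAsFactors = FALSE))
    }
    best <- m[which.max(m$covered_query_fraction), , drop = FALSE]
    status <- if (best$covered_query_fraction >= complete_fraction)
      "complete" else "partial"
    data.frame(contig_id = ci, status = status,
               covered_query_fraction = best$covered_query_fraction,
               best_identity = best$mean_identity, stringsAsFactors = FALSE)
  })
  if (length(res) == 0) {
    return(data.frame(contig_id = character(), status = character(),
                      covered_query_fraction = numeric(),
                      best_identity = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}
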