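# SDR localisation and Y/X haplotype classification.

mk_hit <- function(marker, contig, c_start, c_end, strand = "+",
                   q_start = 1L, q_end = NULL, pident = 95) {
  len <- c_end - c_start + 1L
  q_end <- q_end %||% (q_start + len - 1L)
  data.frame(qseqid = marker, sseqid = contig, pident = pident,
             length = len, mismatch = 0L, gapopen = 0L,
             qstart = q_start, qend = q_end,
             sstart = if (strand == "+") c_start else c_end,
             send = if (strand == "+") c_end else c_start,
             evalue = 0, bitscore = 3 * len, gaps = 0L, strand = strand,
             s_lo = c_start, s_hi = c_end, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
MLEN <- c(SDR = 16000, ARR17_repeat = 600, HEMA = 400, MSL = 1200)

mk_cluster <- function(marker, contig, start, end, strand = "+",
                       frac = 1, ident = 95, n = 1L) {
  data.frame(marker = marker, contig_id = contig, start = start, end = end,
             strand = strand, covered_query_fraction = frac,
             mean_identity = ident, n_hits = n, stringsAsFactors = FALSE)
}

test_that("marker-hit chaining respects gap and strand, and is idempotent", {
  # 5 kb gap: one cluster; 25 kb gap: two; opposite strands never merge
  h <- rbind(mk_hit("SDR", "c1", 1000, 2000, q_start = 1),
             mk_hit("SDR", "c1", 7001, 8000, q_start = 1001))
  cl <- cluster_marker_hits(h, MLEN)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start, cl$end), c(1000L, 8000L))
  expect_equal(cl$n_hits, 2L)

  h2 <- rbind(mk_hit("SDR", "c1", 1000, 2000), mk_hit("SDR", "c1", 27001, 28000))
  expect_equal(nrow(cluster_marker_hits(h2, MLEN)), 2)

  h3 <- rbind(mk_hit("SDR", "c1", 1000, 2000, strand = "+"),
              mk_hit("SDR", "c1", 3000, 4000, strand = "-"))
  cl3 <- cluster_marker_hits(h3, MLEN)
  expect_equal(nrow(cl3), 2)
  expect_setequal(cl3$strand, c("+", "-"))

  # idempotence: feeding cluster intervals back as hits changes nothing
  back <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i)
    mk_hit(cl$marker[i], cl$contig_id[i], cl$start[i], cl$end[i],
           strand = cl$strand[i])))
  cl_again <- cluster_marker_hits(back, MLEN)
  expect_equal(cl_again[, c("marker", "contig_id", "start", "end", "strand")],
               cl[, c("marker", "contig_id", "start", "end", "strand")])

  # query-side coverage uses merged query intervals
  h4 <- rbind(mk_hit("SDR", "c1", 1, 8000, q_start = 1),
              mk_hit("SDR", "c1", 8001, 16000, q_start = 4001))
  expect_equal(cluster_marker_hits(h4, MLEN)$covered_query_fraction,
               12000 / 16000)
})

test_that("SDR calls need half the reference query covered", {
  cl <- rbind(mk_cluster("SDR", "c1", 100, 15000, frac = 0.8),
              mk_cluster("SDR", "c2", 100, 2000, frac = 0.1))
  calls <- locate_sdr(cl)
  expect_equal(calls$contig_id, "c1")
  expect_false(calls$multiple_clusters)
})

test_that("Y/X classification follows the ARR17-partial-repeat rule", {
  sdr <- locate_sdr(mk_cluster("SDR", "c1", 1000, 15000, frac = 0.9))
  reps <- rbind(mk_cluster("ARR17_repeat", "c1", 12000, 12600),
                mk_cluster("ARR17_repeat", "c1", 13500, 14100, strand = "-"))
  y <- classify_haplotype(sdr, reps)
  expect_equal(y$haplotype_class, "Y")
  expect_equal(y$n_repeat_clusters, 2L)

  x <- classify_haplotype(sdr, mk_cluster("HEMA", "c1", 12000, 12400))
  expect_equal(x$haplotype_class, "X")
  expect_equal(x$n_repeat_clusters, 0L)

  u <- classify_haplotype(sdr, reps, contigs = c("c1", "c9"))
  expect_equal(u$haplotype_class[u$contig_id == "c9"], "unclassified")

  # enlarging the flank can only add evidence, never converting Y to X
  rep_far <- mk_cluster("ARR17_repeat", "c1", 80000, 80600)
  classes <- vapply(c(1000, 20000, 50000, 100000), function(fl)
    classify_haplotype(sdr, rep_far, flank = fl)$haplotype_class,
    character(1))
  expect_false(is.unsorted(match(classes, c("X", "Y"))))
})

test_that("inverted repeats require opposite strands and HEMA between", {
  arms <- rbind(mk_cluster("ARR17_repeat", "c1", 1000, 1600, strand = "+"),
                mk_cluster("ARR17_repeat", "c1", 2500, 3100, strand = "-"))
  hema <- mk_cluster("HEMA", "c1", 1800, 2200)
  call <- find_inverted_repeat(rbind(arms, hema))
  expect_equal(nrow(call), 1)
  expect_equal(call$left_strand, "+")
  expect_equal(call$right_strand, "-")
  expect_true(call$hema_present)
  expect_true(call$spacer_start > call$left_end &&
                call$spacer_end < call$right_start)

  same <- arms; same$strand <- "+"
  expect_equal(nrow(find_inverted_repeat(rbind(same, hema))), 0)
  expect_equal(nrow(find_inverted_repeat(arms)), 0) # no HEMA between
  # arms further apart than max_span do not pair
  far <- rbind(mk_cluster("ARR17_repeat", "c1", 1000, 1600, strand = "+"),
               mk_cluster("ARR17_repeat", "c1", 42500, 43100, strand = "-"),
               mk_cluster("HEMA", "c1", 20000, 20400))
  expect_equal(nrow(find_inverted_repeat(far)), 0)
})

test_that("MSL completeness is called from query coverage", {
  cl <- rbind(mk_cluster("MSL", "c1", 100, 1200, frac = 0.95),
              mk_cluster("MSL", "c2", 100, 400, frac = 0.2))
  calls <- call_msl(cl, contigs = c("c1", "c2", "c3"))
  expect_equal(calls$status[calls$contig_id == "c1"], "complete")
  expect_equal(calls$status[calls$contig_id == "c2"], "partial")
  expect_equal(calls$status[calls$contig_id == "c3"], "absent")
})

test_that("synthetic Y/X panels are classified perfectly across seeds", {
  for (seed in 1:20) {
    panel <- gen_sdr_panel(n_y = 5, n_x = 5, seed = seed)
    hits <- filter_alignments(panel$hits)
    cl <- cluster_marker_hits(hits, setNames(panel$markers$length,
                                             panel$markers$id))
    calls <- classify_haplotype(locate_sdr(cl), cl,
                                contigs = unique(panel$hits$sseqid))
    expect_equal(unname(panel$labels[calls$contig_id]),
                 calls$haplotype_class,
                 info = paste("seed", seed))
    # every Y contig shows exactly one inverted-repeat pair
    ir <- find_inverted_repeat(cl)
    expect_setequal(ir$contig_id,
                    names(panel$labels)[panel$labels == "Y"])
    expect_equal(nrow(ir), sum(panel$labels == "Y"))
  }
})

test_that("synthetic SDR interval matches the planted span", {
  res <- gen_sdr_contig("Y", seed = 42, contig_id = "tigY")
  hits <- filter_alignments(res$hits)
  cl <- cluster_marker_hits(hits, setNames(res$markers$length,
                                           res$markers$id))
  call <- locate_sdr(cl)
  expect_equal(call$contig_id, "tigY")
  expect_lt(abs(call$start - min(res$truth$start)), 1000)
  expect_lt(abs(call$end - max(res$truth$end)), 1000)
  # inverted-pair truth: arms on opposite strands, HEMA between
  reps <- res$truth[res$truth$marker == "ARR17_repeat", ]
  hema <- res$truth[res$truth$marker == "HEMA", ]
  expect_gte(nrow(reps), 2)
  left <- reps[reps$end < hema$start, ]
  right <- reps[reps$start > hema$end, ]
  expect_true(any(left$strand != right$strand[1]))

  resx <- gen_sdr_contig("X", seed = 42)
  expect_false("ARR17_repeat" %in% resx$truth$marker)
})
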