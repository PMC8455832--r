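# Synthetic-data generators.
#
# Every generator plants known structure (allelic duplication, marker
# layout, group-structured VAF states, high-fold loci, ORFs) and returns
# the planted truth alongside the data, so each analysis stage can be
# validated by parameter recovery. All randomness flows through one seeded
# RNG per generator call; the same seed gives byte-identical outputs.

#' Parameters for the diploid-assembly simulator
#'
#' Defaults emulate a long-read assembly with abundantly separated
#' haplotypes: 45% of the (haploid) sequence present in two haplotype
#' copies, with inter-allele divergence of 130 substitutions and 31 gapped
#' columns per kb.
#'
#' @param genome_size haploid genome size (bp) before duplication.
#' @param n_contigs number of primary contigs.
#' @param dup_fraction fraction of the haploid sequence present as two
#'   haplotypes, in `[0, 1]`.
#' @param mismatch_rate substitutions per kb between allelic copies.
#' @param indel_rate gapped columns per kb between allelic copies.
#' @param indel_len_mean mean indel length (bp; geometric lengths).
#' @param seed RNG seed.
#' @return A list of class `diploid_sim_params`.
#' @export
diploid_sim_params <- function(genome_size = 1e6, n_contigs = 20,
                               dup_fraction = 0.45, mismatch_rate = 130,
                               indel_rate = 31, indel_len_mean = 3,
                               seed = 1) {
  stopifnot(dup_fraction >= 0, dup_fraction <= 1, mismatch_rate >= 0,
            indel_rate >= 0, indel_len_mean >= 1, is_count(n_contigs))
  structure(list(genome_size = genome_size, n_contigs = n_contigs,
                 dup_fraction = dup_fraction, mismatch_rate = mismatch_rate,
                 indel_rate = indel_rate, indel_len_mean = indel_len_mean,
                 seed = seed),
            class = "diploid_sim_params")
}

# Mutate one haplotype copy: substitutions and geometric-length indels at
# the given per-kb rates. Returns the mutated sequence and realized edit
# counts.
mutate_copy <- function(seq, mismatch_rate, indel_rate, indel_len_mean) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  bases <- c("A", "C", "G", "T")
  n_sub <- min(L, rpois(1, L * mismatch_rate / 1000))
  if (n_sub > 0) {
    pos <- sample.int(L, n_sub)
    repl <- sample(bases, n_sub, replace = TRUE)
    clash <- repl == chars[pos]
    while (any(clash)) {
      repl[clash] <- sample(bases, sum(clash), replace = TRUE)
      clash <- repl == chars[pos]
    }
    chars[pos] <- repl
  }
  n_ev <- if (indel_rate > 0) rpois(1, L * indel_rate / 1000 / indel_len_mean)
          else 0L
  del_bp <- 0L; ins_bp <- 0L
  if (n_ev > 0) {
    anchors <- sort(sample.int(L - 1L, min(n_ev, L - 1L)), decreasing = TRUE)
    lens <- 1L + rgeom(length(anchors), 1 / indel_len_mean)
    is_del <- runif(length(anchors)) < 0.5
    pieces <- chars
    for (k in seq_along(anchors)) {
      p <- anchors[k]
      if (is_del[k]) {
        hi <- min(p + lens[k] - 1L, length(pieces))
        del_bp <- del_bp + (hi - p + 1L)
        pieces <- pieces[-(p:hi)]
      } else {
        ins_bp <- ins_bp + lens[k]
        pieces <- append(pieces, sample(bases, lens[k], replace = TRUE),
                         after = p)
      }
    }
    chars <- pieces
  }
  list(seq = paste(chars, collapse = ""), n_sub = n_sub,
       n_events = n_ev, gap_cols = del_bp + ins_bp, ins_bp = ins_bp)
}

#' Simulate a diploid assembly with separated haplotypes
#'
#' Generates `n_contigs` primary contigs totalling `genome_size` bp, then
#' re-emits a planted fraction of the sequence as second-haplotype contigs
#' carrying substitutions and indels at the planted per-kb rates.
#'
#' @param params a [diploid_sim_params()] object.
#' @return A list with `records` (FASTA data.frame, see [read_fasta()]) and
#'   `truth`: `contigs` (id, length, haplotype copy flag), `pairs` (one row
#'   per allelic pair with planted interval, mismatch and gap counts,
#'   alignment length and identity) and `params`.
#' @export
gen_diploid_assembly <- function(params = diploid_sim_params()) {
  stopifnot(inherits(params, "diploid_sim_params"))
  with_seed(params$seed, {
    G <- params$genome_size
    n <- params$n_contigs
    if (G < n * 2000)
      stopf("genome_size %g too small for %d contigs (need >= 2 kb each)",
            G, n)
    w <- runif(n, 0.7, 1.3)
    len <- floor(G * w / sum(w))
    len[n] <- G - sum(len[-n])
    ids <- sprintf("ctg%03d", seq_len(n))
    seqs <- vapply(len, random_dna, character(1))
    budget <- round(G * params$dup_fraction)
    pair_rows <- list(); hap_ids <- character(); hap_seqs <- character()
    for (i in seq_len(n)) {
      if (budget < 1000) break
      take <- min(len[i], budget)
      if (take < 1000) break
      sub <- substr(seqs[i], 1, take)
      mut <- mutate_copy(sub, params$mismatch_rate, params$indel_rate,
                         params$indel_len_mean)
      hid <- paste0(ids[i], "_h2")
      hap_ids <- c(hap_ids, hid)
      hap_seqs <- c(hap_seqs, mut$seq)
      aln_len <- take + mut$ins_bp
      pair_rows[[length(pair_rows) + 1]] <- data.frame(
        qseqid = ids[i], qstart = 1L, qend = as.integer(take),
        sseqid = hid, sstart = 1L, send = nchar(mut$seq),
        mismatches = mut$n_sub, gap_opens = mut$n_events,
        gap_cols = mut$gap_cols, aln_len = as.integer(aln_len),
        pident = 100 * (aln_len - mut$n_sub - mut$gap_cols) / aln_len,
        stringsAsFactors = FALSE)
      budget <- budget - take
    }
    records <- data.frame(
      id = c(ids, hap_ids), description = "",
      seq = c(seqs, hap_seqs),
      length = nchar(c(seqs, hap_seqs)), stringsAsFactors = FALSE)
    pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
      data.frame(qseqid = character(), qstart = integer(), qend = integer(),
                 sseqid = character(), sstart = integer(), send = integer(),
                 mismatches = integer(), gap_opens = integer(),
                 gap_cols = integer(), aln_len = integer(),
                 pident = numeric(), stringsAsFactors = FALSE)
    truth <- list(contigs = data.frame(id = records$id,
                                       length = records$length,
                                       is_hap2 = records$id %in% hap_ids,
                                       stringsAsFactors = FALSE),
                  pairs = pairs, params = params)
    list(records = records, truth = truth)
  })
}

#' Truth-computed multiplicity fractions for a simulated assembly
#'
#' Computes, from planted intervals alone, the genome-wide fractions of
#' emitted bases at each self-coverage multiplicity — the reference values
#' the analysis pipeline should recover.
#'
#' @param truth the `truth` element of [gen_diploid_assembly()].
#' @return Named numeric vector `f0, f1, f2, f3, f4, f5plus`.
#' @export
expected_multiplicity <- function(truth) {
  total <- sum(truth$contigs$length)
  dup_primary <- sum(truth$pairs$qend - truth$pairs$qstart + 1)
  dup_hap <- sum(truth$contigs$length[truth$contigs$is_hap2])
  f2 <- (dup_primary + dup_hap) / total
  c(f0 = 0, f1 = 1 - f2, f2 = f2, f3 = 0, f4 = 0, f5plus = 0)
}

#' Generate the self-alignment hit table implied by planted truth
#'
#' Emits (a) the trivial full-length 100%-identity diagonal self-hit for
#' every contig and (b) both reciprocal directions of each planted allelic
#' pair, with identity, mismatch and gap counts consistent with the planted
#' edits and bitscore proportional to alignment length. Generating the
#' table from truth (rather than by running an aligner) makes downstream
#' tests exercise interval arithmetic, not alignment heuristics.
#'
#' @param truth the `truth` element of [gen_diploid_assembly()].
#' @return Alignment data.frame (13-column dialect fields).
#' @export
gen_self_alignment_table <- function(truth) {
  ctg <- truth$contigs
  diag <- make_alignment(qseqid = ctg$id, sseqid = ctg$id, pident = 100,
                         length = ctg$length, mismatch = 0, gapopen = 0,
                         qstart = 1, qend = ctg$length, sstart = 1,
                         send = ctg$length, gaps = 0)
  p <- truth$pairs
  if (nrow(p) == 0) return(diag)
  fwd <- make_alignment(qseqid = p$qseqid, sseqid = p$sseqid,
                        pident = p$pident, length = p$aln_len,
                        mismatch = p$mismatches, gapopen = p$gap_opens,
                        qstart = p$qstart, qend = p$qend,
                        sstart = p$sstart, send = p$send, gaps = p$gap_cols)
  rev <- make_alignment(qseqid = p$sseqid, sseqid = p$qseqid,
                        pident = p$pident, length = p$aln_len,
                        mismatch = p$mismatches, gapopen = p$gap_opens,
                        qstart = p$sstart, qend = p$send,
                        sstart = p$qstart, send = p$qend, gaps = p$gap_cols)
  rbind(diag, fwd, rev)
}

# Desk-scale marker reference lengths (bp) used by the SDR simulator.
sdr_marker_lengths <- function() {
  c(SDR = 16000, ARR17 = 1000, ARR17_repeat = 600, HEMA = 400, MSL = 1200,
    TCP = 1500, CLC = 1500, MET1 = 1500, LRR = 1500, PSR = 2000)
}

# One marker-block hit: marker as query, contig as subject; bitscore 3x
# length so every block longer than ~350 bp survives default filtering.
marker_hit <- function(marker, contig, c_start, c_end, strand,
                       q_start = 1L, q_end = NULL, pident = NULL) {
  len <- c_end - c_start + 1L
  q_end <- q_end %||% (q_start + len - 1L)
  pident <- pident %||% runif(1, 88, 99)
  mm <- round(len * (100 - pident) / 100 * 0.7)
  gp <- round(len * (100 - pident) / 100 * 0.3)
  s1 <- if (strand == "+") c_start else c_end
  s2 <- if (strand == "+") c_end else c_start
  make_alignment(qseqid = marker, sseqid = contig, pident = pident,
                 length = len, mismatch = mm, gapopen = max(1L, gp %/% 3L),
                 qstart = q_start, qend = q_end, sstart = s1, send = s2,
                 bitscore = 3 * len, gaps = gp)
}

#' Simulate one SDR-bearing contig with marker hits
#'
#' Embeds an ordered LRR–MET1–CLC–TCP marker block (the genes shared by Y
#' and X SDR haplotypes) in random sequence. A `Y` contig additionally
#' carries ARR17 partial-repeat copies — two of them as an inverted pair
#' flanking a HEMA-fragment block — plus a PSR copy and a partial MSL
#' block; an `X` contig carries none of these. Marker hits are emitted
#' from the planted layout.
#'
#' @param haplotype `"Y"` or `"X"`.
#' @param seed RNG seed (`NULL` to use the current RNG state, e.g. inside
#'   [gen_sdr_panel()]).
#' @param contig_id contig name.
#' @param contig_length total contig length (bp).
#' @return A list with `record` (one-row FASTA data.frame), `markers`
#'   (FASTA data.frame of marker references), `hits` (alignment
#'   data.frame) and `truth` (data.frame `marker`, `start`, `end`,
#'   `strand`, plus attribute-free `haplotype` column).
#' @export
gen_sdr_contig <- function(haplotype = c("Y", "X"), seed = NULL,
                           contig_id = NULL, contig_length = 30000) {
  haplotype <- match.arg(haplotype)
  contig_id <- contig_id %||% paste0("ctg", haplotype, "001")
  with_seed(seed, {
    ml <- sdr_marker_lengths()
    blocks <- list() # name, len, strand
    add <- function(name, len, strand = "+")
      blocks[[length(blocks) + 1]] <<- list(name = name, len = len,
                                            strand = strand)
    gapb <- function() add("", sample(300:800, 1))
    add("LRR", ml[["LRR"]]); gapb()
    add("MET1", ml[["MET1"]]); gapb()
    add("CLC", ml[["CLC"]]); gapb()
    add("TCP", ml[["TCP"]]); gapb()
    if (haplotype == "Y") {
      add("ARR17_repeat", ml[["ARR17_repeat"]], "+")
      add("", sample(200:400, 1))
      add("PSR", ml[["PSR"]], "+")
      add("", sample(300:600, 1))
      # inverted pair: two arms on opposite strands flanking a HEMA block
      add("ARR17_repeat", ml[["ARR17_repeat"]], "+")
      add("", sample(80:150, 1))
      add("HEMA", ml[["HEMA"]], "+")
      add("", sample(80:150, 1))
      add("ARR17_repeat", ml[["ARR17_repeat"]], "-")
      add("", sample(300:600, 1))
      add("MSL_partial", 600, "+")
    }
    span <- sum(vapply(blocks, function(b) b$len, numeric(1)))
    if (span + 4000 > contig_length)
      stopf("contig_length %d too small for the planted SDR span (%d bp)",
            contig_length, span)
    left_pad <- sample(2000:(contig_length - span - 2000), 1)
    cursor <- left_pad + 1L
    truth <- list(); seq_parts <- list(random_dna(left_pad))
    for (b in blocks) {
      if (b$name == "") {
        seq_parts[[length(seq_parts) + 1]] <- random_dna(b$len)
      } else {
        marker <- sub("_partial$", "", b$name)
        block_seq <- random_dna(b$len)
        seq_parts[[length(seq_parts) + 1]] <- block_seq
        truth[[length(truth) + 1]] <- data.frame(
          marker = marker, start = cursor,
          end = cursor + b$len - 1L, strand = b$strand,
          partial = grepl("_partial$", b$name), stringsAsFactors = FALSE)
      }
      cursor <- cursor + b$len
    }
    seq_parts[[length(seq_parts) + 1]] <- random_dna(contig_length - cursor + 1L)
    seq <- paste(unlist(seq_parts), collapse = "")
    truth <- do.call(rbind, truth)
    truth$haplotype <- haplotype
    # marker hits from truth
    hits <- list()
    for (i in seq_len(nrow(truth))) {
      q_end <- if (truth$partial[i]) truth$end[i] - truth$start[i] + 1L
               else NULL
      hits[[i]] <- marker_hit(truth$marker[i], contig_id,
                              truth$start[i], truth$end[i],
                              truth$strand[i], q_end = q_end)
    }
    # reference-SDR hits: three chained chunks covering most of the SDR
    # query, mapped across the shared marker span
    sdr_lo <- min(truth$start); sdr_hi <- max(truth$end)
    qlen <- ml[["SDR"]]
    qcuts <- round(qlen * c(0, 0.33, 0.66, 1))
    scuts <- round(sdr_lo + (sdr_hi - sdr_lo) * c(0, 0.33, 0.66, 1))
    for (j in 1:3) {
      qs <- qcuts[j] + ifelse(j == 1, 1L, 120L)
      qe <- qcuts[j + 1]
      ss <- scuts[j] + ifelse(j == 1, 0L, 120L)
      se <- scuts[j + 1]
      hits[[length(hits) + 1]] <- marker_hit("SDR", contig_id, ss, se, "+",
                                             q_start = qs, q_end = qe,
                                             pident = runif(1, 85, 95))
    }
    hits <- do.call(rbind, hits)
    markers <- data.frame(id = names(ml), description = "",
                          seq = vapply(unname(ml), random_dna, character(1)),
                          length = unname(ml), stringsAsFactors = FALSE)
    record <- data.frame(id = contig_id, description = "", seq = seq,
                         length = nchar(seq), stringsAsFactors = FALSE)
    list(record = record, markers = markers, hits = hits, truth = truth)
  })
}

#' Simulate a panel of Y and X SDR contigs
#'
#' @param n_y,n_x number of Y and X contigs.
#' @param seed RNG seed.
#' @param contig_length per-contig length (bp).
#' @return A list with `records` (FASTA data.frame of all contigs),
#'   `markers`, `hits` (combined alignment data.frame), `truth` (combined
#'   feature truth) and `labels` (named character vector contig -> Y/X).
#' @export
gen_sdr_panel <- function(n_y = 50, n_x = 50, seed = 1,
                          contig_length = 30000) {
  with_seed(seed, {
    haps <- c(rep("Y", n_y), rep("X", n_x))
    ids <- sprintf("ctg%s%03d", haps, c(seq_len(n_y), seq_len(n_x)))
    out <- lapply(seq_along(ids), function(i)
      gen_sdr_contig(haps[i], seed = NULL, contig_id = ids[i],
                     contig_length = contig_length))
    records <- do.call(rbind, lapply(out, `[[`, "record"))
    hits <- do.call(rbind, lapply(out, `[[`, "hits"))
    truth <- do.call(rbind, lapply(seq_along(out), function(i) {
      t <- out[[i]]$truth; t$contig_id <- ids[i]; t
    }))
    labels <- stats::setNames(haps, ids)
    list(records = records, markers = out[[1]]$markers, hits = hits,
         truth = truth, labels = labels)
  })
}

#' Parameters for the VAF-panel simulator
#'
#' Emulates a ploidy-4 joint-calling panel: per-group VAF profiles take
#' states in `{0, 0.25, 0.5, 0.75, 1}`, per-sample depths are Poisson with
#' occasional sub-5x dropout, and allele observations are binomial draws
#' around the group state.
#'
#' @param n_groups number of sample groups (e.g. species).
#' @param samples_per_group samples per group.
#' @param n_sites number of variant sites.
#' @param group_divergence expected absolute difference between the VAF
#'   states of two groups at a site (0 = identical profiles; 0.4 = fully
#'   independent profiles).
#' @param mean_depth Poisson mean read depth.
#' @param dropout_prob probability that a sample's depth at a site is
#'   redrawn uniformly from `{0,...,4}` (below the 5-read mask).
#' @param seed RNG seed.
#' @return A list of class `vaf_sim_params`.
#' @export
vaf_sim_params <- function(n_groups = 3, samples_per_group = 23,
                           n_sites = 300, group_divergence = 0.25,
                           mean_depth = 30, dropout_prob = 0.1, seed = 1) {
  stopifnot(is_count(n_groups), is_count(samples_per_group),
            is_count(n_sites), group_divergence >= 0,
            group_divergence <= 0.4 + 1e-12,
            dropout_prob >= 0, dropout_prob <= 1, mean_depth > 0)
  structure(list(n_groups = n_groups, samples_per_group = samples_per_group,
                 n_sites = n_sites, group_divergence = group_divergence,
                 mean_depth = mean_depth, dropout_prob = dropout_prob,
                 seed = seed),
            class = "vaf_sim_params")
}

#' Simulate a group-structured multi-sample VCF of VAF profiles
#'
#' Group profiles are built from a shared profile by redrawing a planted
#' fraction of sites independently per group (the fraction is chosen so the
#' expected per-site state difference between two groups equals
#' `group_divergence`). Per sample and site, depth is Poisson (with sub-5x
#' dropout) and alternate observations are binomial around the group state;
#' zero-depth entries become missing genotypes.
#'
#' @param params a [vaf_sim_params()] object.
#' @param path output VCF path (default: a tempfile).
#' @param binomial_noise set `FALSE` to make AO exactly `DP * state`
#'   (rounded), removing within-group noise.
#' @return A list with `path`, `samples`, `labels` (named integer group per
#'   sample), `profiles` (site x group state matrix) and `sites`.
#' @export
gen_vaf_vcf <- function(params = vaf_sim_params(), path = tempfile(fileext = ".vcf"),
                        binomial_noise = TRUE) {
  stopifnot(inherits(params, "vaf_sim_params"))
  with_seed(params$seed, {
    states <- c(0, 0.25, 0.5, 0.75, 1)
    ns <- params$n_sites
    ng <- params$n_groups
    # E|X - Y| for two independent uniform draws over the 5 states is 0.4
    p_div <- min(1, params$group_divergence / 0.4)
    shared <- sample(states, ns, replace = TRUE)
    divergent <- runif(ns) < p_div
    profiles <- matrix(shared, nrow = ns, ncol = ng)
    profiles[divergent, ] <- matrix(sample(states, sum(divergent) * ng,
                                           replace = TRUE),
                                    ncol = ng)
    colnames(profiles) <- paste0("group", seq_len(ng))
    pos <- sort(sample(16200000:16320000, ns))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, ns, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    sites <- data.frame(chrom = "Chr18", pos = pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
    n_samp <- ng * params$samples_per_group
    labels <- rep(seq_len(ng), each = params$samples_per_group)
    samples <- sprintf("s%02d_g%d", seq_len(n_samp), labels)
    names(labels) <- samples
    DP <- matrix(rpois(ns * n_samp, params$mean_depth), ns, n_samp)
    drop <- matrix(runif(ns * n_samp) < params$dropout_prob, ns, n_samp)
    DP[drop] <- sample(0:4, sum(drop), replace = TRUE)
    state <- profiles[, labels, drop = FALSE]
    if (!binomial_noise) {
      # quarter states divide depths that are multiples of 4 exactly, so
      # the emitted VAFs equal the planted states with no rounding jitter
      DP <- 4L * ceiling(DP / 4)
    }
    AO <- if (binomial_noise) {
      matrix(rbinom(ns * n_samp, as.vector(DP), as.vector(state)), ns, n_samp)
    } else round(DP * state)
    RO <- DP - AO
    missing <- DP == 0
    DPc <- DP; DPc[missing] <- NA
    AOc <- matrix(as.character(AO), ns, n_samp); AOc[missing] <- NA
    ROc <- RO; ROc[missing] <- NA
    colnames(DPc) <- colnames(ROc) <- colnames(AOc) <- samples
    write_sample_vcf(sites, samples, DPc, ROc, AOc, path)
    list(path = path, samples = samples, labels = labels,
         profiles = profiles, sites = sites)
  })
}

#' Simulate a read-depth track with planted high-fold loci
#'
#' Depth is `background` outside the planted loci and `background * fold`
#' inside; Gaussian noise with sd `noise_sd` is added everywhere and the
#' result clipped at zero.
#'
#' @param length track length (bp).
#' @param background baseline depth.
#' @param loci data.frame with `start`, `end`, `fold`; must lie within the
#'   track and must not overlap.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @param seq_id track name.
#' @return A list with `track` (a [depth_track()]) and `truth` (`loci`).
#' @export
gen_depth_track <- function(length, background = 30,
                            loci = data.frame(start = integer(),
                                              end = integer(),
                                              fold = numeric()),
                            noise_sd = 0, seed = 1, seq_id = "sim") {
  assert_cols(loci, c("start", "end", "fold"), "loci")
  if (nrow(loci)) {
    if (any(loci$start < 1) || any(loci$end > length) ||
        any(loci$end < loci$start))
      stopf("planted locus outside [1, %d]", length)
    o <- order(loci$start)
    if (any(loci$start[o][-1] <= loci$end[o][-nrow(loci)]))
      stopf("planted loci overlap")
  }
  with_seed(seed, {
    depth <- rep(background, length)
    for (i in seq_len(nrow(loci)))
      depth[loci$start[i]:loci$end[i]] <- background * loci$fold[i]
    if (noise_sd > 0) depth <- depth + rnorm(length, 0, noise_sd)
    depth <- round(pmax(depth, 0))
    list(track = depth_track(seq_id, depth), truth = loci)
  })
}

# A 12-mer containing a stop codon in every frame on both strands and no
# ATG/CAT; interleaving it between random spacers bounds the length of any
# unplanned ORF.
STOP_BLOCK <- "TTAATTAGTTAA"

all_frame_filler <- function(n) {
  unit <- nchar(STOP_BLOCK) + 90L
  parts <- character(0)
  left <- n
  while (left > 0) {
    take <- min(90L, max(0L, left - nchar(STOP_BLOCK)))
    piece <- paste0(random_dna(take),
                    substr(STOP_BLOCK, 1, min(nchar(STOP_BLOCK),
                                              left - take)))
    parts <- c(parts, piece)
    left <- left - nchar(piece)
  }
  paste(parts, collapse = "")
}

#' Simulate a locus carrying a known set of ORFs
#'
#' Plants `n_orfs` open reading frames (alternating strands) separated by
#' filler in which stop codons recur in all six frames, so no unplanned ORF
#' of `min_aa` or more can arise in the filler; the construction is
#' validated (and re-drawn if necessary) so that exactly the planted ORFs
#' reach `min_aa`.
#'
#' @param n_orfs number of ORFs to plant.
#' @param aa_range integer range the protein lengths are drawn from.
#' @param min_aa the detection threshold the construction is validated
#'   against.
#' @param spacer filler length (bp) between consecutive ORFs.
#' @param seed RNG seed.
#' @param id sequence id.
#' @return A list with `record` (one-row FASTA data.frame) and `truth`
#'   (data.frame `start`, `end`, `strand`, `aa_length`).
#' @export
gen_orf_locus <- function(n_orfs = 5, aa_range = c(100, 160), min_aa = 100,
                          spacer = 300, seed = 1, id = "orf_locus") {
  stopifnot(is_count(n_orfs), aa_range[1] >= min_aa)
  with_seed(seed, {
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1, paste,
                    collapse = "")
    sense <- setdiff(codons, STOP_CODONS)
    for (attempt in 1:50) {
      aa <- sample(seq(aa_range[1], aa_range[2]), n_orfs, replace = TRUE)
      strands <- rep(c("+", "-"), length.out = n_orfs)
      # jitter filler lengths so planted ORFs fall in varying frames
      fill_len <- spacer + sample(0:2, n_orfs + 1, replace = TRUE)
      parts <- list(all_frame_filler(fill_len[1]))
      cursor <- fill_len[1]
      truth <- list()
      for (k in seq_len(n_orfs)) {
        orf <- paste0("ATG",
                      paste(sample(sense, aa[k] - 1, replace = TRUE),
                            collapse = ""),
                      sample(STOP_CODONS, 1))
        if (strands[k] == "-") orf <- rev_comp(orf)
        truth[[k]] <- data.frame(start = cursor + 1L,
                                 end = cursor + nchar(orf),
                                 strand = strands[k], aa_length = aa[k])
        parts[[length(parts) + 1]] <- orf
        parts[[length(parts) + 1]] <- all_frame_filler(fill_len[k + 1])
        cursor <- cursor + nchar(orf) + fill_len[k + 1]
      }
      seq <- paste(unlist(parts), collapse = "")
      truth <- do.call(rbind, truth)
      found <- find_orfs(seq, min_aa = min_aa, id = id)
      ok <- nrow(found) == n_orfs &&
        all(found$start == truth$start[order(truth$start)]) &&
        all(found$end == truth$end[order(truth$start)])
      if (ok) {
        return(list(record = data.frame(id = id, description = "",
                                        seq = seq, length = nchar(seq),
                                        stringsAsFactors = FALSE),
                    truth = truth))
      }
    }
    stopf("failed to construct a clean ORF locus in 50 attempts")
  })
}

#' Check truth-derived 100%-identity hits against sequences
#'
#' A naive exact-match verifier for small simulated fixtures: every hit
#' with 100% identity and no edits must correspond to identical substrings
#' (reverse-complemented for minus-strand hits). Not a general aligner.
#'
#' @param records alignment data.frame.
#' @param fasta FASTA data.frame holding all query and subject sequences.
#' @param max_len skip hits longer than this (default 10 kb).
#' @return `TRUE` invisibly; errors on the first mismatch.
#' @export
verify_exact_hits <- function(records, fasta, max_len = 10000) {
  seqs <- stats::setNames(fasta$seq, fasta$id)
  exact <- records[records$pident == 100 & records$mismatch == 0 &
                     (is.na(records$gaps) | records$gaps == 0) &
                     records$length <= max_len, , drop = FALSE]
  for (i in seq_len(nrow(exact))) {
    q <- substr(seqs[[exact$qseqid[i]]], exact$qstart[i], exact$qend[i])
    s <- substr(seqs[[exact$sseqid[i]]], exact$s_lo[i], exact$s_hi[i])
    if (exact$strand[i] == "-") s <- rev_comp(s)
    if (q != s)
      stopf("hit %d: query %s[%d,%d] does not match subject %s",
            i, exact$qseqid[i], exact$qstart[i], exact$qend[i],
            exact$sseqid[i])
  }
  invisible(TRUE)
}
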