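# Independent brute-force oracles used to verify the package's algorithms.
# Each oracle takes a deliberately naive route (per-base counting, substring
# enumeration, exhaustive search over merges) so that agreement with the
# implementation is informative.

# Per-base multiplicity counting: increment a counter vector base by base.
oracle_multiplicity <- function(records, seq_lengths) {
  sapply(names(seq_lengths), function(id) {
    v <- integer(seq_lengths[[id]])
    r <- records[records$qseqid == id, , drop = FALSE]
    for (k in seq_len(nrow(r))) {
      v[r$qstart[k]:r$qend[k]] <- v[r$qstart[k]:r$qend[k]] + 1L
    }
    m <- pmin(v, 5L)
    vapply(0:5, function(x) mean(m == x), numeric(1))
  })
}

# Exhaustive Ward agglomeration from raw coordinates: at each step evaluate
# the between-centroid merge cost 2*|A||B|/(|A|+|B|) * ||cA - cB||^2 for
# every cluster pair and merge the minimum. Returns merge heights and the
# partition after each merge.
oracle_ward <- function(X) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_cost <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        A <- clusters[[i]]; B <- clusters[[j]]
        cA <- colMeans(X[A, , drop = FALSE])
        cB <- colMeans(X[B, , drop = FALSE])
        cost <- 2 * length(A) * length(B) / (length(A) + length(B)) *
          sum((cA - cB)^2)
        if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
      }
    }
    heights <- c(heights, sqrt(best_cost))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    lab <- integer(n)
    for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
    partitions[[length(partitions) + 1]] <- lab
  }
  list(heights = heights, partitions = partitions)
}

# Two partitions agree up to label permutation iff their co-membership
# matrices match.
same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

# ORF enumeration by forward scanning from every ATG occurrence, grouped by
# (frame, stop) keeping the most upstream ATG.
oracle_orfs <- function(seq, min_aa = 100) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  revcomp <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  scan <- function(s) {
    L <- nchar(s)
    found <- list()
    for (i in seq_len(max(0, L - 2))) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i + 3
      while (j + 2 <= L) {
        if (substr(s, j, j + 2) %in% stops) {
          key <- paste((i - 1) %% 3, j + 2)
          if (is.null(found[[key]]) || found[[key]][1] > i)
            found[[key]] <- c(i, j + 2, (i - 1) %% 3, (j - i) / 3)
          break
        }
        j <- j + 3
      }
    }
    if (length(found) == 0) return(NULL)
    m <- do.call(rbind, found)
    m[m[, 4] >= min_aa, , drop = FALSE]
  }
  L <- nchar(seq)
  fwd <- scan(seq)
  rev <- scan(revcomp(seq))
  rows <- list()
  if (!is.null(fwd) && nrow(fwd)) {
    for (k in seq_len(nrow(fwd)))
      rows[[length(rows) + 1]] <- data.frame(
        strand = "+", frame = fwd[k, 3], start = fwd[k, 1], end = fwd[k, 2],
        aa_length = fwd[k, 4])
  }
  if (!is.null(rev) && nrow(rev)) {
    for (k in seq_len(nrow(rev)))
      rows[[length(rows) + 1]] <- data.frame(
        strand = "-", frame = rev[k, 3], start = L - rev[k, 2] + 1,
        end = L - rev[k, 1] + 1, aa_length = rev[k, 4])
  }
  if (length(rows) == 0) {
    return(data.frame(strand = character(), frame = numeric(),
                      start = numeric(), end = numeric(),
                      aa_length = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# Plain double-loop Euclidean distance with pairwise deletion.
oracle_pairwise_distance <- function(values, mask) {
  n <- ncol(values)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (r in seq_len(nrow(values))) {
      if (mask[r, i] && mask[r, j]) s <- s + (values[r, i] - values[r, j])^2
    }
    D[i, j] <- sqrt(s)
  }
  D
}

# Alignment records with both strands and write-stable numeric precision,
# for file round-trip checks.
make_test_alignments <- function(n) {
  qs <- sample(1:5000, n)
  qe <- qs + sample(100:2000, n)
  slo <- sample(1:5000, n)
  shi <- slo + (qe - qs)
  minus <- runif(n) < 0.4
  df <- data.frame(
    qseqid = sample(LETTERS[1:5], n, replace = TRUE),
    sseqid = sample(LETTERS[1:5], n, replace = TRUE),
    pident = round(runif(n, 70, 100), 2),
    length = qe - qs + 1L,
    mismatch = rpois(n, 20), gapopen = rpois(n, 3),
    qstart = qs, qend = qe,
    sstart = ifelse(minus, shi, slo), send = ifelse(minus, slo, shi),
    evalue = 0, bitscore = round(runif(n, 500, 4000), 1),
    stringsAsFactors = FALSE)
  df$gaps <- df$gapopen + rpois(n, 4)
  df$strand <- ifelse(minus, "-", "+")
  df$s_lo <- slo
  df$s_hi <- shi
  df
}

# Random alignment-record table over a set of sequences.
random_alignment_records <- function(seq_lengths, n_hits) {
  ids <- names(seq_lengths)
  qid <- sample(ids, n_hits, replace = TRUE)
  qs <- qe <- integer(n_hits)
  for (k in seq_len(n_hits)) {
    L <- seq_lengths[[qid[k]]]
    a <- sort(sample.int(L, 2))
    qs[k] <- a[1]; qe[k] <- a[2]
  }
  data.frame(qseqid = qid, sseqid = sample(ids, n_hits, replace = TRUE),
             pident = runif(n_hits, 60, 100),
             length = qe - qs + 1L,
             mismatch = rpois(n_hits, 5), gapopen = rpois(n_hits, 2),
             qstart = qs, qend = qe, sstart = qs, send = qe,
             evalue = rep(0, n_hits), bitscore = runif(n_hits, 100, 5000),
             gaps = rpois(n_hits, 3),
             strand = rep("+", n_hits), s_lo = qs, s_hi = qe,
             stringsAsFactors = FALSE)
}
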