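# Per-base read-depth tracks, BED intervals and newick trees.

#' Construct a depth track
#'
#' A depth track is a per-base read-depth array for one sequence, 1-based
#' (element `i` is the depth at position `i`).
#'
#' @param seq_id sequence name.
#' @param depth numeric vector of non-negative depths.
#' @return An object of class `depth_track` (list with `seq_id`, `depth`,
#'   `length`).
#' @export
depth_track <- function(seq_id, depth) {
  stopifnot(is.character(seq_id), length(seq_id) == 1)
  if (any(depth < 0)) stopf("negative depth in track %s", seq_id)
  structure(list(seq_id = seq_id, depth = as.numeric(depth),
                 length = length(depth)),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track: %s, %d bp, median depth %.1f\n",
              x$seq_id, x$length, stats::median(x$depth)))
  invisible(x)
}

#' Read a per-base depth track
#'
#' Accepts either 4-column bedgraph (`chrom start end depth`, 0-based
#' half-open) or 3-column depth TSV (`chrom pos depth`, 1-based, as printed
#' by `samtools depth`). Both are converted to a 1-based per-base array
#' covering positions 1 to the last covered position; positions absent from
#' the file get depth 0.
#'
#' @param path input path.
#' @return A [depth_track()].
#' @export
read_depth_track <- function(path) {
  if (!file.exists(path)) stopf("depth track not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (!ncol(df) %in% c(3, 4))
    stopf("depth track %s: expected 3 (depth TSV) or 4 (bedgraph) columns, found %d",
          path, ncol(df))
  ids <- unique(df[[1]])
  if (length(ids) != 1)
    stopf("depth track %s covers multiple sequences (%s); one per file expected",
          path, paste(ids, collapse = ", "))
  if (ncol(df) == 4) {
    start0 <- df[[2]]; end0 <- df[[3]]; val <- df[[4]]
    if (any(val < 0)) stopf("negative depth in %s", path)
    if (any(end0 <= start0)) stopf("empty/inverted bedgraph interval in %s", path)
    o <- order(start0)
    start0 <- start0[o]; end0 <- end0[o]; val <- val[o]
    if (any(start0[-1] < end0[-length(end0)]))
      stopf("overlapping bedgraph intervals in %s", path)
    depth <- numeric(max(end0))
    for (i in seq_along(start0)) depth[(start0[i] + 1):end0[i]] <- val[i]
  } else {
    pos <- df[[2]]; val <- df[[3]]
    if (any(val < 0)) stopf("negative depth in %s", path)
    if (any(pos < 1)) stopf("position < 1 in depth TSV %s", path)
    if (anyDuplicated(pos)) stopf("duplicated position in depth TSV %s", path)
    depth <- numeric(max(pos))
    depth[pos] <- val
  }
  depth_track(ids, depth)
}

#' Write a depth track as bedgraph
#'
#' Run-length encodes the per-base array; inverse of [read_depth_track()].
#'
#' @param track a [depth_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  stopifnot(inherits(track, "depth_track"))
  r <- rle(track$depth)
  end0 <- cumsum(r$lengths)
  start0 <- c(0, end0[-length(end0)])
  out <- data.frame(track$seq_id, start0, end0, r$values)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention. Optional `name`, `score` and `strand` columns are
#' written when present.
#'
#' @param intervals data.frame with columns `seq_id`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  assert_cols(intervals, c("seq_id", "start", "end"), "intervals")
  if (any(intervals$start < 1) || any(intervals$end < intervals$start))
    stopf("invalid interval (need 1 <= start <= end)")
  out <- data.frame(intervals$seq_id, intervals$start - 1L, intervals$end)
  extra <- intersect(c("name", "score", "strand"), names(intervals))
  for (i in seq_along(extra)) {
    # BED columns are positional: fill the preceding ones if skipped
    if (extra[i] == "score" && !"name" %in% extra) out$name <- "."
    if (extra[i] == "strand" && !"score" %in% extra &&
        ncol(out) < 5) out$score <- 0
    out[[extra[i]]] <- intervals[[extra[i]]]
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' @param path BED path.
#' @return data.frame with `seq_id`, `start`, `end` (1-based inclusive) and
#'   any of `name`, `score`, `strand` present in the file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  if (file.size(path) == 0)
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(seq_id = df[[1]], start = df[[2]] + 1L, end = df[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- df[[4]]
  if (ncol(df) >= 5) out$score <- df[[5]]
  if (ncol(df) >= 6) out$strand <- df[[6]]
  out
}

#' Export a hierarchical clustering as a newick string
#'
#' Branch lengths are merge-height differences, so leaves sit at depth equal
#' to the height of their first merge (the usual dendrogram geometry); a
#' two-leaf tree merged at height 3 becomes `(a:3,b:3);`.
#'
#' @param tree an [stats::hclust] object (as returned by [ward_linkage()]).
#' @return A single newick string.
#' @export
export_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  labels <- tree$labels %||% as.character(seq_len(nrow(tree$merge) + 1))
  fmt <- function(x) format(x, digits = 8, trim = TRUE, scientific = FALSE)
  node <- function(i) {
    # i < 0: leaf -i ; i > 0: internal node from merge row i
    if (i < 0) list(str = labels[-i], h = 0)
    else {
      a <- node(tree$merge[i, 1])
      b <- node(tree$merge[i, 2])
      h <- tree$height[i]
      list(str = sprintf("(%s:%s,%s:%s)", a$str, fmt(h - a$h),
                         b$str, fmt(h - b$h)),
           h = h)
    }
  }
  if (nrow(tree$merge) == 0) return(sprintf("%s;", labels[1]))
  paste0(node(nrow(tree$merge))$str, ";")
}

#' Write a tree in newick format
#'
#' @param tree an `hclust` object or a ready newick string.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  s <- if (is.character(tree)) tree else export_newick(tree)
  writeLines(s, path)
  invisible(path)
}
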