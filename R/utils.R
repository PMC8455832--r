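# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

# Random DNA of length n as a single string.
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rev_comp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Merge 1-based inclusive intervals; merge only genuinely overlapping ones
# when min_overlap = 1, also merge abutting ones when min_overlap = 0.
merge_intervals <- function(start, end, min_overlap = 0L) {
  if (length(start) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  ir <- IRanges::IRanges(start = start, end = end)
  red <- IRanges::reduce(ir, min.gapwidth = if (min_overlap >= 1L) 0L else 1L)
  data.frame(start = IRanges::start(red), end = IRanges::end(red))
}

# Gap (bp) between two 1-based inclusive intervals; 0 when they overlap/touch.
interval_gap <- function(s1, e1, s2, e2) {
  if (e1 < s2) return(s2 - e1 - 1L)
  if (e2 < s1) return(s1 - e2 - 1L)
  0L
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 &&
  x == as.integer(x)

#' Sequencing fold coverage
#'
#' Total sequenced bases divided by genome size, the usual "x-fold coverage"
#' figure quoted for a sequencing run.
#'
#' @param total_bases total sequenced yield in bases.
#' @param genome_size genome size in bases.
#' @return Fold coverage (numeric scalar).
#' @examples
#' fold_coverage(31e9, 500e6) # 62
#' @export
fold_coverage <- function(total_bases, genome_size) {
  stopifnot(is.numeric(total_bases), is.numeric(genome_size), genome_size > 0)
  total_bases / genome_size
}
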