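# Multi-sample VCF input with per-sample DP/RO/AO fields, as produced by
# haplotype-based callers run at elevated ploidy on pooled BAMs.

#' Parse a multi-sample VCF with DP/RO/AO per-sample fields
#'
#' Retains only sites overlapping `regions` (all sites when `regions` is
#' `NULL`). Multi-allelic sites are kept intact: `alt` holds the
#' comma-separated ALT string and the `AO` matrix holds one comma-separated
#' count per alt allele. Samples with a missing genotype entry (`.`) have
#' `NA` in all three matrices.
#'
#' @param path path to an (uncompressed) VCF v4.x file.
#' @param regions optional data.frame with columns `seq_id`, `start`, `end`
#'   (1-based inclusive).
#' @return A list with elements `samples` (character vector), `sites`
#'   (data.frame `chrom`, `pos`, `ref`, `alt`), and site-by-sample matrices
#'   `DP`, `RO` (numeric) and `AO` (character, comma-separated per alt).
#' @export
parse_sample_vcf <- function(path, regions = NULL) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  header_ok <- any(startsWith(readLines(path, n = 500), "#CHROM"))
  if (!header_ok) stopf("malformed VCF header: no #CHROM line in %s", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stopf("failed to parse VCF %s: %s",
                                          path, conditionMessage(e)))
  samples <- setdiff(colnames(v@gt), "FORMAT")
  n_sites <- nrow(v@fix)
  if (is.null(n_sites) || n_sites == 0) {
    empty <- matrix(numeric(), 0, length(samples),
                    dimnames = list(NULL, samples))
    return(list(samples = samples,
                sites = data.frame(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   stringsAsFactors = FALSE),
                DP = empty, RO = empty,
                AO = matrix(character(), 0, length(samples),
                            dimnames = list(NULL, samples))))
  }
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  for (key in c("DP", "RO", "AO")) {
    if (!key %in% fmt_keys)
      stopf("VCF FORMAT is missing the %s key (found: %s)",
            key, paste(fmt_keys, collapse = ":"))
  }
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) # single-site VCFs drop to a named vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  if (any(sites$pos < 1)) stopf("VCF position < 1")
  DP <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  RO <- vcfR::extract.gt(v, element = "RO", as.numeric = TRUE)
  AO <- vcfR::extract.gt(v, element = "AO")
  dim_fix <- function(m, mode) {
    m <- matrix(m, nrow = n_sites, ncol = length(samples),
                dimnames = list(NULL, samples))
    m
  }
  DP <- dim_fix(DP); RO <- dim_fix(RO); AO <- dim_fix(AO)
  keep <- rep(TRUE, n_sites)
  if (!is.null(regions)) {
    assert_cols(regions, c("seq_id", "start", "end"), "regions")
    keep <- vapply(seq_len(n_sites), function(i) {
      any(regions$seq_id == sites$chrom[i] &
            regions$start <= sites$pos[i] & regions$end >= sites$pos[i])
    }, logical(1))
  }
  # AO must carry one count per alt allele for non-missing samples
  n_alt <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  n_ao <- matrix(lengths(strsplit(ifelse(is.na(AO), "", AO), ",",
                                  fixed = TRUE)),
                 nrow = n_sites)
  bad <- which(!is.na(AO) & n_ao != n_alt, arr.ind = TRUE)
  if (nrow(bad))
    stopf("site %s:%d sample %s: AO has %d value(s) for %d alt allele(s)",
          sites$chrom[bad[1, 1]], sites$pos[bad[1, 1]],
          samples[bad[1, 2]], n_ao[bad[1, 1], bad[1, 2]], n_alt[bad[1, 1]])
  list(samples = samples,
       sites = sites[keep, , drop = FALSE],
       DP = DP[keep, , drop = FALSE],
       RO = RO[keep, , drop = FALSE],
       AO = AO[keep, , drop = FALSE])
}

# Minimal VCF writer used by the simulator (FORMAT DP:RO:AO, no genotypes).
write_sample_vcf <- function(sites, samples, DP, RO, AO, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sdrkit-simulator",
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=RO,Number=1,Type=Integer,Description="Reference allele observation count">',
           '##FORMAT=<ID=AO,Number=A,Type=Integer,Description="Alternate allele observation count">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    gt <- vapply(seq_along(samples), function(j) {
      if (is.na(DP[i, j])) "." else
        sprintf("%d:%d:%s", DP[i, j], RO[i, j], AO[i, j])
    }, character(1))
    paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            ".", ".", ".", "DP:RO:AO", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
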