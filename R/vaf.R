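# Sample clustering on variant-allele-fraction (VAF) profiles.
#
# For a panel of resequenced samples jointly called over a region of
# interest, the VAF at a site (alternate observations / depth) summarises
# the local haplotype dosage; with ploidy-4 joint calling the expected
# states are quarters {0, 0.25, 0.5, 0.75, 1}. Cross-sample Euclidean
# distances over shared well-covered sites, Ward.D2 clustering and
# classical MDS then group samples by relatedness over the region.

#' VAF extraction parameters
#'
#' @param min_depth sites covered by fewer than `min_depth` reads for a
#'   sample are masked for that sample (default 5).
#' @param regions optional data.frame (`seq_id`, `start`, `end`) restricting
#'   the analysed sites.
#' @return A list of class `vaf_params`.
#' @export
vaf_params <- function(min_depth = 5, regions = NULL) {
  stopifnot(min_depth >= 1)
  structure(list(min_depth = min_depth, regions = regions),
            class = "vaf_params")
}

#' Build a masked VAF matrix from parsed VCF data
#'
#' One row per (site, alt allele) — multi-allelic sites expand into several
#' rows. The value is `AO / DP`; entries with depth below `min_depth` or a
#' missing genotype are masked.
#'
#' @param vcf result of [parse_sample_vcf()].
#' @param params a [vaf_params()] object.
#' @return A list of class `vaf_matrix`: `samples`, `sites` (data.frame
#'   `chrom`, `pos`, `alt`), `values` (rows = site-alt, cols = samples),
#'   `mask` (logical, `TRUE` = usable), `min_depth`.
#' @export
build_vaf_matrix <- function(vcf, params = vaf_params()) {
  stopifnot(inherits(params, "vaf_params"))
  sites <- vcf$sites
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(params$regions)) {
    assert_cols(params$regions, c("seq_id", "start", "end"), "regions")
    keep <- vapply(seq_len(nrow(sites)), function(i) {
      any(params$regions$seq_id == sites$chrom[i] &
            params$regions$start <= sites$pos[i] &
            params$regions$end >= sites$pos[i])
    }, logical(1))
  }
  idx <- which(keep)
  rows <- list(); vals <- list(); masks <- list()
  for (i in idx) {
    alts <- strsplit(sites$alt[i], ",", fixed = TRUE)[[1]]
    ao_all <- vcf$AO[i, ]
    dp <- vcf$DP[i, ]
    bad <- which(!is.na(dp) & dp == 0 & !is.na(ao_all) & ao_all != "" &
                   vapply(strsplit(ifelse(is.na(ao_all), "0", ao_all), ",",
                                   fixed = TRUE),
                          function(x) any(as.numeric(x) > 0), logical(1)))
    if (length(bad))
      stopf("site %s:%d sample %s: DP = 0 but AO > 0",
            sites$chrom[i], sites$pos[i], vcf$samples[bad[1]])
    ao_split <- strsplit(ifelse(is.na(ao_all), NA_character_, ao_all), ",",
                         fixed = TRUE)
    for (a in seq_along(alts)) {
      ao <- vapply(ao_split, function(x)
        if (length(x) >= a) suppressWarnings(as.numeric(x[a])) else NA_real_,
        numeric(1))
      usable <- !is.na(dp) & dp >= params$min_depth & !is.na(ao)
      v <- ifelse(usable, ao / dp, NA_real_)
      rows[[length(rows) + 1]] <- data.frame(chrom = sites$chrom[i],
                                             pos = sites$pos[i],
                                             alt = alts[a],
                                             stringsAsFactors = FALSE)
      vals[[length(vals) + 1]] <- v
      masks[[length(masks) + 1]] <- usable
    }
  }
  n <- length(vals)
  values <- if (n) do.call(rbind, vals) else
    matrix(numeric(), 0, length(vcf$samples))
  mask <- if (n) do.call(rbind, masks) else
    matrix(logical(), 0, length(vcf$samples))
  colnames(values) <- colnames(mask) <- vcf$samples
  structure(list(samples = vcf$samples,
                 sites = if (n) do.call(rbind, rows) else
                   data.frame(chrom = character(), pos = integer(),
                              alt = character(), stringsAsFactors = FALSE),
                 values = values, mask = mask,
                 min_depth = params$min_depth),
            class = "vaf_matrix")
}

#' @export
print.vaf_matrix <- function(x, ...) {
  cat(sprintf("vaf_matrix: %d site-alt rows x %d samples (%.1f%% masked, min_depth %d)\n",
              nrow(x$values), length(x$samples),
              100 * mean(!x$mask), x$min_depth))
  invisible(x)
}

#' Cross-sample Euclidean distances with pairwise deletion
#'
#' `D[i, j] = sqrt(sum((v_i - v_j)^2))` over the sites unmasked in **both**
#' samples (pairwise deletion). Distances are not normalised by the number
#' of shared sites by default; `rescale = TRUE` multiplies each pairwise
#' distance by `sqrt(n_sites / n_shared)` for unequal-coverage panels.
#'
#' @param vm a [build_vaf_matrix()] result.
#' @param on_empty what to do when a sample pair shares no unmasked site:
#'   `"error"` (default) or `"na"`.
#' @param rescale rescale distances by shared-site count (default `FALSE`).
#' @return A list of class `vaf_dist`: `D` (symmetric matrix, zero
#'   diagonal), `shared` (shared-site counts), `samples`.
#' @export
pairwise_distance <- function(vm, on_empty = c("error", "na"),
                              rescale = FALSE) {
  stopifnot(inherits(vm, "vaf_matrix"))
  on_empty <- match.arg(on_empty)
  n <- length(vm$samples)
  if (n < 2) stopf("need at least 2 samples")
  D <- matrix(0, n, n, dimnames = list(vm$samples, vm$samples))
  shared <- matrix(nrow(vm$values), n, n,
                   dimnames = list(vm$samples, vm$samples))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- vm$mask[, i] & vm$mask[, j]
    ns <- sum(both)
    shared[i, j] <- shared[j, i] <- ns
    if (ns == 0) {
      if (on_empty == "error")
        stopf("samples %s and %s share no unmasked site",
              vm$samples[i], vm$samples[j])
      D[i, j] <- D[j, i] <- NA_real_
      next
    }
    d <- sqrt(sum((vm$values[both, i] - vm$values[both, j])^2))
    if (rescale) d <- d * sqrt(nrow(vm$values) / ns)
    D[i, j] <- D[j, i] <- d
  }
  diag(shared) <- colSums(vm$mask)
  structure(list(D = D, shared = shared, samples = vm$samples),
            class = "vaf_dist")
}

as_dist_matrix <- function(d) {
  if (inherits(d, "vaf_dist")) d <- d$D
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stopf("expected a square distance matrix")
  if (any(is.na(d))) stopf("distance matrix contains NA")
  if (any(d < 0)) stopf("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8) stopf("distance matrix is not symmetric")
  d
}

#' Ward minimum-variance clustering on squared distances (ward.D2)
#'
#' Agglomerates on the squared distance matrix with the Ward
#' coefficients of the Lance–Williams update; reported merge heights are on
#' the original distance scale (square root of the minimal squared-distance
#' objective at each merge), so they are nondecreasing.
#'
#' @param d a [pairwise_distance()] result, `dist` object or symmetric
#'   matrix.
#' @return An [stats::hclust] object (`method = "ward.D2"`).
#' @export
ward_linkage <- function(d) {
  m <- as_dist_matrix(d)
  labels <- rownames(m) %||% as.character(seq_len(nrow(m)))
  dd <- stats::as.dist(m)
  attr(dd, "Labels") <- labels
  stats::hclust(dd, method = "ward.D2")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres the squared distance matrix and eigendecomposes it;
#' coordinates are eigenvectors scaled by the square roots of the positive
#' eigenvalues. Negative eigenvalues (possible for masked, non-Euclidean
#' inputs) are dropped with a warning; if fewer than `k` positive
#' eigenvalues exist the coordinates are zero-padded.
#'
#' @param d distance input as in [ward_linkage()].
#' @param k number of output dimensions (default 2).
#' @return A list of class `mds_embedding`: `points` (n x k), `eig`
#'   (eigenvalues, descending), `positive_mass` (fraction of
#'   positive-eigenvalue mass captured by the `k` dimensions).
#' @export
mds_embed <- function(d, k = 2) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  if (n < 2) stopf("need at least 2 points for MDS")
  k <- min(k, n - 1)
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = k,
                                          eig = TRUE))
  eig <- fit$eig
  if (any(eig < -1e-8 * max(abs(eig))))
    warnf("distance matrix is non-Euclidean: %d negative eigenvalue(s) dropped",
          sum(eig < -1e-8 * max(abs(eig))))
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  if (ncol(pts) < k) {
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  # columns belonging to eigenvalues that are zero up to round-off carry no
  # geometry; truncate them to exact zeros
  eig_desc <- sort(eig, decreasing = TRUE)
  tol <- max(abs(eig)) * 1e-12
  for (j in seq_len(ncol(pts))) {
    if (j > length(eig_desc) || eig_desc[j] <= tol) pts[, j] <- 0
  }
  rownames(pts) <- rownames(m)
  pos <- eig[eig > 0]
  captured <- sum(head(sort(pos, decreasing = TRUE), k)) / sum(pos)
  structure(list(points = pts, eig = sort(eig, decreasing = TRUE),
                 positive_mass = captured),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("mds_embedding: %d points in %d dimension(s), %.1f%% of positive eigenvalue mass\n",
              nrow(x$points), ncol(x$points), 100 * x$positive_mass))
  invisible(x)
}

#' @export
plot.mds_embedding <- function(x, ..., labels = NULL) {
  graphics::plot(x$points[, 1], x$points[, 2],
                 xlab = "MDS 1", ylab = "MDS 2", ...)
  if (!is.null(labels))
    graphics::text(x$points[, 1], x$points[, 2], labels, pos = 3, cex = 0.7)
  invisible(x)
}

#' Cut a linkage tree into k clusters
#'
#' @param tree an `hclust` object (see [ward_linkage()]).
#' @param k number of clusters, `1 <= k <= n`.
#' @return Named integer vector of cluster labels.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- nrow(tree$merge) + 1
  if (!is_count(k) || k > n) stopf("k must be an integer in [1, %d]", n)
  stats::cutree(tree, k = k)
}
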