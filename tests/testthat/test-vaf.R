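# VAF matrix construction, masked Euclidean distances, Ward.D2 linkage and
# classical MDS.

mk_vm <- function(values, mask = NULL) {
  # build a vaf_matrix-shaped object directly from a value matrix
  mask <- mask %||% !is.na(values)
  samples <- colnames(values) %||% paste0("s", seq_len(ncol(values)))
  colnames(values) <- colnames(mask) <- samples
  structure(list(samples = samples,
                 sites = data.frame(chrom = "c", pos = seq_len(nrow(values)),
                                    alt = "A"),
                 values = values, mask = mask, min_depth = 5),
            class = "vaf_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

vcf_fixture <- function(lines) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="d">',
               '##FORMAT=<ID=RO,Number=1,Type=Integer,Description="r">',
               '##FORMAT=<ID=AO,Number=A,Type=Integer,Description="a">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               lines), f)
  f
}

test_that("VAF matrix masks low depth and expands multi-allelic sites", {
  f <- vcf_fixture(c(
    "chr\t10\t.\tA\tG\t9\t.\t.\tDP:RO:AO\t4:2:2\t10:10:0",
    "chr\t20\t.\tC\tG,T\t9\t.\t.\tDP:RO:AO\t10:5:3,2\t.",
    "chr\t30\t.\tG\tA\t9\t.\t.\tDP:RO:AO\t20:10:10\t5:1:4"))
  vm <- build_vaf_matrix(parse_sample_vcf(f))
  # one row per (site, alt): 1 + 2 + 1
  expect_equal(nrow(vm$values), 4)
  # DP = 4 is below the 5-read floor -> masked
  expect_false(vm$mask[1, "s1"])
  expect_equal(vm$values[1, "s2"], c(s2 = 0))
  expect_true(vm$mask[1, "s2"])
  # AO = "3,2" at DP 10 -> rows 0.3 and 0.2
  expect_equal(unname(vm$values[2:3, "s1"]), c(0.3, 0.2))
  expect_false(any(vm$mask[2:3, "s2"])) # missing genotype
  expect_equal(unname(vm$values[4, ]), c(0.5, 0.8))

  # region restriction inside build_vaf_matrix
  vm2 <- build_vaf_matrix(parse_sample_vcf(f),
                          vaf_params(regions = data.frame(seq_id = "chr",
                                                          start = 25,
                                                          end = 35)))
  expect_equal(vm2$sites$pos, 30L)

  # DP = 0 with positive AO is inconsistent
  f2 <- vcf_fixture("chr\t10\t.\tA\tG\t9\t.\t.\tDP:RO:AO\t0:0:3\t10:10:0")
  expect_error(build_vaf_matrix(parse_sample_vcf(f2)), "DP = 0 but AO > 0")
})

test_that("pairwise distances use pairwise deletion over shared sites", {
  v <- cbind(a = c(0, 0.5, 1), b = c(1, 0.5, 1))
  d <- pairwise_distance(mk_vm(v))
  expect_equal(d$D["a", "b"], 1)
  expect_equal(diag(d$D), c(a = 0, b = 0))

  # identical profiles
  expect_equal(pairwise_distance(mk_vm(cbind(a = c(.2, .4), b = c(.2, .4))))$D["a", "b"],
               0)

  # a site masked in either sample is excluded from the pair
  v <- cbind(a = c(0, 0.8), b = c(1, NA))
  d <- pairwise_distance(mk_vm(v))
  expect_equal(d$D["a", "b"], 1)
  expect_equal(d$shared["a", "b"], 1)

  # no shared sites: error by default, NA under the policy flag
  v <- cbind(a = c(0.1, NA), b = c(NA, 0.3))
  expect_error(pairwise_distance(mk_vm(v)), "share no unmasked site")
  expect_true(is.na(pairwise_distance(mk_vm(v), on_empty = "na")$D[1, 2]))

  # random masked matrices match the double-loop oracle
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    m <- sample(10:40, 1)
    values <- matrix(round(runif(n * m), 2), m, n)
    mask <- matrix(runif(n * m) > 0.2, m, n)
    values[!mask] <- NA
    vm <- mk_vm(values, mask)
    got <- pairwise_distance(vm, on_empty = "na")$D
    ora <- oracle_pairwise_distance(ifelse(mask, values, 0), mask)
    expect_equal(unname(got), ora, tolerance = 1e-12)
    # symmetry and nonnegativity under masking
    expect_equal(got, t(got))
    expect_true(all(got[!is.na(got)] >= 0))
  }
})

test_that("unmasked Euclidean distances satisfy the triangle inequality", {
  set.seed(8)
  v <- matrix(runif(60), 15, 4)
  D <- pairwise_distance(mk_vm(v))$D
  n <- ncol(v)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
})

test_that("ward linkage reproduces the exhaustive minimum-merge oracle", {
  # 2 points at distance 3 merge at height 3
  d <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  h <- ward_linkage(d)
  expect_equal(h$height, 3)

  # two tight clusters far apart separate at k = 2
  set.seed(4)
  X <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 10, 0.1), 5, 2))
  lab <- cut_tree(ward_linkage(as.matrix(dist(X))), 2)
  expect_equal(length(unique(lab[1:5])), 1)
  expect_equal(length(unique(lab[6:10])), 1)
  expect_true(lab[1] != lab[6])

  # n <= 7 random Euclidean configurations: every merge is the pair with
  # the minimal Ward objective increase, verified exhaustively from
  # coordinates
  set.seed(9)
  for (rep in 1:12) {
    n <- sample(4:7, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    h <- ward_linkage(as.matrix(dist(X)))
    ora <- oracle_ward(X)
    expect_equal(h$height, ora$heights, tolerance = 1e-9)
    for (step in seq_len(n - 1)) {
      got <- unname(cutree(h, k = n - step))
      expect_true(same_partition(got, ora$partitions[[step]]),
                  info = paste("rep", rep, "step", step))
    }
  }

  expect_error(ward_linkage(matrix(c(0, 1, 2, 0), 2, 2)), "not symmetric")
  expect_error(ward_linkage(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

test_that("ward merge heights are nondecreasing", {
  set.seed(31)
  for (rep in 1:10) {
    values <- matrix(runif(200), 20, 10)
    mask <- matrix(runif(200) > 0.15, 20, 10)
    values[!mask] <- NA
    h <- ward_linkage(pairwise_distance(mk_vm(values, mask), on_empty = "na"))
    expect_false(is.unsorted(h$height))
  }
})

test_that("classical MDS recovers geometry", {
  # collinear points embed on one axis
  x <- c(0, 1, 2, 5)
  D <- as.matrix(dist(x))
  emb <- mds_embed(D, k = 2)
  expect_lt(max(abs(emb$points[, 2])), 1e-8)
  expect_equal(as.matrix(dist(emb$points)), D, ignore_attr = TRUE,
               tolerance = 1e-9)

  # equilateral triangle with unit sides
  D3 <- matrix(1, 3, 3); diag(D3) <- 0
  emb3 <- mds_embed(D3, k = 2)
  pd <- as.matrix(dist(emb3$points))
  expect_equal(pd[upper.tri(pd)], rep(1, 3), tolerance = 1e-9)

  # planted full-rank 2-D configuration is reconstructed to 1e-8
  set.seed(2)
  X <- matrix(rnorm(24), 12, 2)
  D <- as.matrix(dist(X))
  emb <- mds_embed(D, k = 2)
  expect_equal(as.matrix(dist(emb$points)), D, ignore_attr = TRUE,
               tolerance = 1e-8)
  skip_if_not_installed("vegan")
  pr <- vegan::procrustes(X, emb$points, symmetric = FALSE)
  expect_lt(sqrt(mean(pr$X - pr$Yrot)^2), 1e-8)

  expect_error(mds_embed(matrix(0, 1, 1)), "at least 2")
})

test_that("cut_tree covers the degenerate cluster counts", {
  set.seed(6)
  h <- ward_linkage(as.matrix(dist(matrix(rnorm(10), 5, 2))))
  expect_equal(sort(unique(cut_tree(h, 5))), 1:5)  # singletons
  expect_equal(unique(cut_tree(h, 1)), 1)          # one cluster
  expect_error(cut_tree(h, 6), "k must be")
  expect_error(cut_tree(h, 0), "k must be")
})

test_that("group-structured VAF panels are recovered end to end", {
  skip_if_not_installed("mclust")
  for (seed in 1:3) {
    sim <- gen_vaf_vcf(vaf_sim_params(
      n_groups = 3, samples_per_group = 5, n_sites = 200,
      group_divergence = 0.25, mean_depth = 100, dropout_prob = 0.1,
      seed = seed))
    vm <- build_vaf_matrix(parse_sample_vcf(sim$path))
    expect_lt(mean(!vm$mask), 0.2)
    tree <- ward_linkage(pairwise_distance(vm))
    lab <- cut_tree(tree, 3)
    expect_equal(mclust::adjustedRandIndex(lab, sim$labels[names(lab)]), 1,
                 info = paste("seed", seed))
    unlink(sim$path)
  }
})
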