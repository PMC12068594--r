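test_that("tpm matches hand-computed rates and its invariants", {
  m <- matrix(c(10, 10), ncol = 1, dimnames = list(c("g1", "g2"), "s1"))
  t1 <- tpm(m, c(1000, 2000))
  expect_equal(unname(t1[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  expect_equal(unname(tpm(matrix(5, 1, 1), 500)[1, 1]), 1e6)

  set.seed(2)
  counts <- matrix(rpois(300, 20), 50, 6)
  lens <- sample(200:5000, 50)
  tt <- tpm(counts, lens)
  expect_equal(unname(colSums(tt)), rep(1e6, 6), tolerance = 1e-6)
  # depth invariance
  counts2 <- counts; counts2[, 3] <- counts2[, 3] * 2
  expect_equal(tpm(counts2, lens)[, 3], tt[, 3], tolerance = 1e-9)

  z <- counts; z[, 2] <- 0; colnames(z) <- paste0("s", 1:6)
  expect_error(tpm(z, lens), "s2")
})

test_that("upper-quartile normalization equalizes upper quartiles", {
  set.seed(3)
  a <- rnbinom(500, mu = 50, size = 5)
  m <- cbind(A = a, B = 2 * a)
  norm <- upper_quartile_normalize(m)
  expect_equal(norm[, "A"], norm[, "B"], ignore_attr = TRUE)

  # post-condition on random NB matrices: per-sample UQs equal to 1e-9
  x <- matrix(rnbinom(500 * 6, mu = 30, size = 2), 500, 6)
  n <- upper_quartile_normalize(x)
  uqs <- apply(n, 2, function(v) quantile(v[v > 0], 0.75))
  expect_lt(max(uqs) - min(uqs), 1e-9)

  # idempotence: upper quartiles already equal, so nothing changes
  n2 <- upper_quartile_normalize(n)
  expect_equal(n2, n, tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(upper_quartile_normalize(matrix(c(1, 0, 0, 0, 1, 1, 1, 1), 4, 2)),
               "nonzero")
})

test_that("expressed-gene filter is strict and monotone", {
  m <- matrix(c(1.5, 0.9, 1.0), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  expect_identical(filter_expressed(m), "a")
  expect_length(filter_expressed(matrix(0, 5, 3)), 0)
  # adding an all-zero library can only shrink the kept set
  m2 <- cbind(m, 0)
  expect_true(all(filter_expressed(m2) %in% filter_expressed(m)))
})

test_that("deg_filter equals brute force and honours strict thresholds", {
  fixed <- data.frame(gene_id = c("a", "b", "c", "d"),
                      log2fc = c(1.2, 1.0, -2.0, 1.5),
                      padj = c(0.01, 0.01, 0.04, 0.05))
  expect_identical(deg_filter(fixed), c("a", "c"))
  expect_length(deg_filter(fixed[0, ]), 0)

  set.seed(8)
  tab <- data.frame(gene_id = sprintf("g%05d", 1:10000),
                    log2fc = rnorm(10000, 0, 1.2),
                    padj = runif(10000))
  expect_identical(deg_filter(tab), brute_deg_filter(tab))
})

test_that("stand-in DE test behaves at the null and under permutation", {
  set.seed(12)
  base <- matrix(rnbinom(400 * 3, mu = 100, size = 10), 400, 3)
  counts <- cbind(base, base)  # group 2 literally identical to group 1
  rownames(counts) <- paste0("g", 1:400)
  res <- de_test_standin(counts, rep(c("x", "y"), each = 3))
  expect_equal(res$log2fc, rep(0, 400))
  expect_true(all(res$padj > 0.9))

  expect_error(de_test_standin(counts[, 1:3], c("x", "x", "y")), "replicates")
  expect_error(de_test_standin(counts, rep("x", 6)), "two groups")

  # labels carrying no signal (global null): near-zero rejections
  sim <- generate_counts(1000, c(a = 3, b = 3), de_fraction = 0, seed = 13)
  res_p <- de_test_standin(sim$counts, rep(c("a", "b"), 3))
  expect_lte(mean(res_p$padj < 0.05), 0.07)
})

test_that("stand-in DE test recovers planted fold changes", {
  sim <- generate_counts(1500, c(a = 3, b = 3), dispersion = 0.05,
                         de_fraction = 0.1, true_lfc_magnitude = 2, seed = 14)
  tab <- de_test_standin(sim$counts, sim$groups, chromosome = sim$chromosome)
  truth <- sim$truth$true_de_genes
  called <- deg_filter(tab)
  expect_gte(mean(truth$gene_id %in% called), 0.8)
  # estimated log2fc tracks the planted sign
  est <- tab$log2fc[match(truth$gene_id, tab$gene_id)]
  expect_gt(cor(est, truth$true_log2fc), 0.9)
  expect_identical(tab$chromosome, sim$chromosome)
})

test_that("gene-set intersections are exact and deterministic", {
  out <- intersect_gene_sets(list(one = c("a", "b", "c"), two = c("b", "c", "d")))
  expect_equal(out$pairwise$n, 2)
  expect_identical(out$common, c("b", "c"))

  disj <- intersect_gene_sets(list(tfs = c("PAX6", "PITX1"), degs = c("DCT", "TYR")))
  expect_equal(disj$pairwise$n, 0)
  expect_length(disj$common, 0)

  same <- intersect_gene_sets(list(a = c("z", "y"), b = c("y", "z")))
  expect_identical(same$common, c("y", "z"))
  expect_error(intersect_gene_sets(list(c("a"))), "named")
})

test_that("clustering transform is the documented shifted log", {
  m <- matrix(c(0, 1, 3, 7), 2, 2)
  tr <- transform_for_clustering(m, normalize = FALSE)
  expect_equal(tr[1, 1], 0)
  expect_equal(tr, log2(m + 1), ignore_attr = TRUE)
  expect_match(attr(tr, "transform"), "stand-in")
  # monotone per sample
  expect_true(all(diff(tr[order(m[, 1]), 1]) >= 0))
})

test_that("ward clustering separates blobs and matches Lance-Williams", {
  set.seed(19)
  blob <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
                matrix(rnorm(40, 5, 0.3), 20, 2))
  cl <- ward_cluster(blob, k = 2)
  lab <- rep(1:2, each = 20)
  agree <- max(mean(cl$assignment == lab), mean(cl$assignment == 3 - lab))
  expect_equal(agree, 1)

  # k = n gives singletons; duplicate rows co-cluster below that
  small <- matrix(rnorm(12), 6, 2)
  expect_equal(sort(unique(ward_cluster(small, k = 6)$assignment)), 1:6)
  dup <- rbind(small, small[1, ])
  cl_d <- ward_cluster(dup, k = 3)
  expect_equal(cl_d$assignment[7], cl_d$assignment[1])

  # merge heights agree with direct Lance-Williams recursion on 8 points
  pts <- matrix(rnorm(16), 8, 2)
  expect_equal(ward_cluster(pts, k = 1)$hclust$height,
               brute_ward_d2_heights(pts), tolerance = 1e-9)
  # and are monotone non-decreasing
  expect_true(all(diff(ward_cluster(pts, k = 1)$hclust$height) >= 0))

  expect_error(ward_cluster(small, k = 10), "k must be")
})
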