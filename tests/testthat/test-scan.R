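aagt_pwm <- function(pseudocount = 0.01) {
  pwm(matrix(c(10, 0, 0, 0,
               10, 0, 0, 0,
               0, 0, 10, 0,
               0, 0, 0, 10), nrow = 4), tf_id = "AAGT", pseudocount = pseudocount)
}

test_that("scan finds the contract hits on both strands", {
  p <- aagt_pwm()
  h <- scan_promoter("CCAAGTCC", p, alpha_raw = 0.01)
  expect_equal(nrow(h), 1)
  expect_equal(h$offset, 2)
  expect_equal(h$strand, "+")

  # ACTT at offset 2 is the reverse complement of AAGT
  h2 <- scan_promoter("CCACTTCC", p, alpha_raw = 0.01)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$offset, 2)
  expect_equal(h2$strand, "-")

  expect_equal(nrow(scan_promoter(strrep("N", 50), p, alpha_raw = 1)), 0)

  expect_warning(h3 <- scan_promoter("ACG", p, alpha_raw = 1), "longer than")
  expect_equal(nrow(h3), 0)
})

test_that("scan equals the naive per-offset oracle", {
  set.seed(123)
  for (i in 1:20) {
    L <- sample(3:10, 1)
    x <- random_pwm(L)
    seq <- random_dna(sample(50:200, 1))
    alpha <- 10^-sample(1:3, 1)
    got <- scan_promoter(seq, x, alpha_raw = alpha)
    want <- naive_scan(seq, x, alpha)
    got <- got[order(got$offset, got$strand), c("offset", "strand", "score", "pvalue")]
    want <- want[order(want$offset, want$strand), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("reverse-complement symmetry of the hit set", {
  set.seed(5)
  for (i in 1:10) {
    x <- random_pwm(6)
    seq <- random_dna(120)
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
    h_f <- scan_promoter(seq, x, alpha_raw = 0.05)
    h_r <- scan_promoter(rc, x, alpha_raw = 0.05)
    # a '+' hit at offset o maps to a '-' hit at n - L - o on the reverse
    n <- nchar(seq); L <- ncol(x$matrix)
    mirrored <- data.frame(offset = n - L - h_f$offset,
                           strand = ifelse(h_f$strand == "+", "-", "+"),
                           score = h_f$score)
    o1 <- mirrored[order(mirrored$offset, mirrored$strand), ]
    o2 <- h_r[order(h_r$offset, h_r$strand), c("offset", "strand", "score")]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o1, o2, tolerance = 1e-12)
  }
})

test_that("bh_fdr matches the step-up definition and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(1), 1)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:10) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    adj <- bh_fdr(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("scan_promoters controls FDR over the whole window family", {
  g <- generate_genome(1, 30000, seed = 17)
  m <- generate_gene_models(g, n_genes = 4, seed = 17)
  pwms <- demo_pwms(2, seed = 17)
  gid <- unique(m$gene_id)
  copies <- data.frame(gene_id = gid[1:2], tf_id = "TF1", n = c(3, 2))
  pl <- plant_motifs(g, m, pwms, copies, seed = 17)
  proms <- extract_promoters(pl$genome, m)
  hits <- scan_promoters(proms, pwms, background = "uniform")
  expect_true(all(hits$padj >= hits$pvalue))
  bm <- binding_strength(hits, tfs = names(pwms), genes = gid)
  expect_gte(bm["TF1", gid[1]], 3)
  expect_gte(bm["TF1", gid[2]], 2)

  # planted offsets are all recovered as FDR-passing hits
  th <- pl$truth$planted_hits
  sig <- hits[hits$padj < 0.05, ]
  for (i in seq_len(nrow(th))) {
    expect_true(any(sig$tf_id == th$tf_id[i] &
                      sig$transcript_id == th$transcript_id[i] &
                      sig$offset == th$offset[i] & sig$strand == "+"))
  }
})

test_that("binding strength thresholds, masks and monotonicity", {
  hits <- data.frame(
    tf_id = c("tfA", "tfA", "tfA", "tfB"),
    gene_id = c("g1", "g1", "g2", "g1"),
    transcript_id = "t", offset = c(1, 5, 2, 9), strand = "+",
    score = 1, pvalue = c(0.001, 0.04, 0.002, 0.2),
    padj = c(0.01, 0.2, 0.01, 0.6))
  bm <- binding_strength(hits, tfs = c("tfA", "tfB"), genes = c("g1", "g2", "g3"))
  expect_equal(bm["tfA", "g1"], 1)   # 0.01 passes, 0.2 does not
  expect_equal(bm["tfA", "g2"], 1)
  expect_equal(bm["tfB", "g1"], 0)
  expect_equal(bm["tfA", "g3"], 0)

  ann <- c(g1 = TRUE, g2 = TRUE, g3 = FALSE)
  bm_m <- binding_strength(hits, tfs = c("tfA", "tfB"), genes = names(ann),
                           annotated = ann)
  expect_true(all(is.na(bm_m[, "g3"])))
  expect_false(anyNA(bm_m[, c("g1", "g2")]))

  # counts are non-increasing as fdr_alpha decreases
  a_grid <- c(0.5, 0.1, 0.05, 0.005)
  counts <- sapply(a_grid, function(a) {
    sum(binding_strength(hits, fdr_alpha = a), na.rm = TRUE)
  })
  expect_true(all(diff(counts) <= 0))

  expect_error(binding_strength(hits[, setdiff(names(hits), "padj")]), "padj")
})

test_that("isoform hits at the same genomic coordinate are deduplicated", {
  # two isoforms of one gene with overlapping promoter windows
  hits <- data.frame(
    tf_id = "tfA", gene_id = "g1",
    transcript_id = c("t1", "t2", "t2"),
    offset = c(10, 0, 50), strand = "+", score = 5,
    pvalue = 1e-6, padj = 1e-4,
    contig = "ctg", genome_start = c(110, 110, 160), genome_strand = "+")
  bm <- binding_strength(hits, tfs = "tfA", genes = "g1", dedup = TRUE)
  expect_equal(bm["tfA", "g1"], 2)  # shared coordinate counted once
  bm2 <- binding_strength(hits, tfs = "tfA", genes = "g1", dedup = FALSE)
  expect_equal(bm2["tfA", "g1"], 3)
})

test_that("hit genomic coordinates point back to the motif instance", {
  g <- generate_genome(1, 20000, seed = 23)
  m <- generate_gene_models(g, n_genes = 2, strand_mix = 0, seed = 23)  # '-' genes
  pwms <- demo_pwms(1, seed = 23)
  copies <- data.frame(gene_id = unique(m$gene_id)[1], tf_id = "TF1", n = 2)
  pl <- plant_motifs(g, m, pwms, copies, seed = 23)
  proms <- extract_promoters(pl$genome, m)
  hits <- scan_promoters(proms, pwms, background = "uniform")
  sig <- hits[hits$padj < 0.05 & hits$strand == "+", ]
  cons <- pwm_consensus(pwms$TF1)
  for (i in seq_len(nrow(sig))) {
    gseq <- substr(pl$genome[[sig$contig[i]]], sig$genome_start[i] + 1,
                   sig$genome_start[i] + nchar(cons))
    # sense-strand hit on a '-' promoter sits on the genomic '-' strand
    expect_identical(regconverge:::revcomp_chr(gseq), cons)
  }
})
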