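make_models <- function(...) gene_models(data.frame(...))

test_that("promoter windows match the hand-computed fixtures", {
  genome <- c(ctg = random_dna(5000))
  # plus strand, start = 3001: window [1000, 4000), length 3000
  m <- make_models(gene_id = "g1", transcript_id = "t1", contig = "ctg",
                   start = 3001, end = 3600, strand = "+")
  pr <- extract_promoters(genome, m)
  expect_equal(pr$window_start, 1000)
  expect_equal(pr$window_end, 4000)
  expect_false(pr$truncated)
  expect_equal(nchar(pr$sequence), 3000)
  expect_identical(pr$sequence, substr(genome[["ctg"]], 1001, 4000))
  # the TSS base is the first base of the downstream segment
  expect_identical(substr(pr$sequence, 2001, 2001), substr(genome[["ctg"]], 3001, 3001))

  # minus strand, end = 2000: same window, reverse complemented
  m2 <- make_models(gene_id = "g2", transcript_id = "t2", contig = "ctg",
                    start = 1500, end = 2000, strand = "-")
  pr2 <- extract_promoters(genome, m2)
  expect_equal(pr2$window_start, 1000)
  expect_equal(pr2$window_end, 4000)
  expect_equal(nchar(pr2$sequence), 3000)
  rc <- strsplit(chartr("ACGT", "TGCA", substr(genome[["ctg"]], 1001, 4000)), "")[[1]]
  expect_identical(pr2$sequence, paste(rev(rc), collapse = ""))

  # truncation at the contig start
  m3 <- make_models(gene_id = "g3", transcript_id = "t3", contig = "ctg",
                    start = 501, end = 900, strand = "+")
  pr3 <- extract_promoters(genome, m3)
  expect_equal(pr3$window_start, 0)
  expect_equal(pr3$window_end, 1500)
  expect_true(pr3$truncated)
})

test_that("extraction is strand-symmetric under genome reverse complement", {
  set.seed(42)
  for (rep in 1:25) {
    len <- sample(300:800, 1)
    genome <- c(ctg = random_dna(len))
    rc_genome <- c(ctg = paste(rev(strsplit(chartr("ACGT", "TGCA", genome[["ctg"]]),
                                            "")[[1]]), collapse = ""))
    start <- sample(100:(len - 100), 1)
    end <- min(len, start + 50)
    m_f <- make_models(gene_id = "g", transcript_id = "t", contig = "ctg",
                       start = start, end = end, strand = "+")
    # mirrored gene on the reverse-complemented genome
    m_r <- make_models(gene_id = "g", transcript_id = "t", contig = "ctg",
                       start = len - end + 1, end = len - start + 1, strand = "-")
    up <- sample(20:120, 1); down <- sample(10:60, 1)
    p_f <- extract_promoters(genome, m_f, up, down)
    p_r <- extract_promoters(rc_genome, m_r, up, down)
    expect_identical(p_f$sequence, p_r$sequence)
    expect_identical(p_f$truncated, p_r$truncated)
    # mirrored coordinates: [s, e) maps to [len - e, len - s)
    expect_equal(p_r$window_start, len - p_f$window_end)
    expect_equal(p_r$window_end, len - p_f$window_start)
  }
})

test_that("extraction is pure and ambiguity codes become N", {
  genome <- c(ctg = paste0(random_dna(200), "RYKM", random_dna(200)))
  m <- make_models(gene_id = "g", transcript_id = "t", contig = "ctg",
                   start = 150, end = 250, strand = "+")
  p1 <- extract_promoters(genome, m, 100, 160)
  p2 <- extract_promoters(genome, m, 100, 160)
  expect_identical(p1, p2)
  expect_true(grepl("NNNN", p1$sequence))
  expect_true(all(strsplit(p1$sequence, "")[[1]] %in% c("A", "C", "G", "T", "N")))

  expect_error(extract_promoters(genome,
    make_models(gene_id = "g", transcript_id = "t", contig = "nope",
                start = 10, end = 20, strand = "+")), "contig")
})

test_that("gene-level collapse keeps the 5'-most TSS", {
  genome <- c(ctg = random_dna(4000))
  m <- make_models(gene_id = c("g", "g"), transcript_id = c("t1", "t2"),
                   contig = "ctg", start = c(2000, 2200), end = c(2600, 2800),
                   strand = "+")
  pr <- extract_promoters(genome, m, 500, 100, collapse = "gene")
  expect_equal(nrow(pr), 1)
  expect_equal(pr$transcript_id, "t1")
  m_neg <- make_models(gene_id = c("g", "g"), transcript_id = c("t1", "t2"),
                       contig = "ctg", start = c(1400, 1600), end = c(2000, 2200),
                       strand = "-")
  pr_neg <- extract_promoters(genome, m_neg, 500, 100, collapse = "gene")
  expect_equal(pr_neg$transcript_id, "t2")
})

test_that("GFF3 round trip and parse errors behave", {
  g <- generate_genome(2, c(40000, 40000), seed = 21)
  m <- generate_gene_models(g, n_genes = 6, isoforms_per_gene = 2, seed = 21)
  gff <- tempfile(fileext = ".gff3")
  write_gff3(m, gff)
  parsed <- parse_annotation(gff)
  parsed <- parsed[order(parsed$transcript_id), ]
  m_sorted <- m[order(m$transcript_id), ]
  expect_equal(parsed$gene_id, m_sorted$gene_id)
  expect_equal(parsed$start, m_sorted$start)
  expect_equal(parsed$end, m_sorted$end)
  expect_equal(parsed$strand, m_sorted$strand)

  # gene with three isoforms yields three models sharing gene_id
  m3 <- generate_gene_models(g, n_genes = 2, isoforms_per_gene = 3, seed = 3)
  gff3 <- tempfile(fileext = ".gff3")
  write_gff3(m3, gff3)
  p3 <- parse_annotation(gff3)
  expect_equal(sum(p3$gene_id == p3$gene_id[1]), 3)

  # orphan transcript
  bad <- c("##gff-version 3",
           "ctg\t.\tgene\t100\t200\t.\t+\t.\tID=geneA",
           "ctg\t.\tmRNA\t100\t200\t.\t+\t.\tID=tx1;Parent=geneMISSING")
  f <- tempfile(fileext = ".gff3"); writeLines(bad, f)
  expect_error(parse_annotation(f), "tx1")

  # malformed coordinates
  bad2 <- c("##gff-version 3",
            "ctg\t.\tgene\t300\t200\t.\t+\t.\tID=geneA")
  f2 <- tempfile(fileext = ".gff3"); writeLines(bad2, f2)
  expect_error(parse_annotation(f2), "start > end")

  # gene without transcripts still yields one model
  lone <- c("##gff-version 3",
            "ctg\t.\tgene\t100\t200\t.\t-\t.\tID=geneB")
  f3 <- tempfile(fileext = ".gff3"); writeLines(lone, f3)
  p <- parse_annotation(f3)
  expect_equal(nrow(p), 1)
  expect_equal(p$transcript_id, "geneB")
})

test_that("assembly filter applies both thresholds strictly", {
  expect_true(assembly_filter(6e5, 1e4)$pass)
  expect_false(assembly_filter(5e5, 1e4)$pass)     # N50 boundary
  expect_false(assembly_filter(6e5, 3e4)$pass)     # scaffold-count boundary
  expect_match(assembly_filter(4e5, 4e4)$reasons[1], "N50")
  expect_length(assembly_filter(4e5, 4e4)$reasons, 2)
  expect_error(assembly_filter(0, 10), "positive")
})

test_that("gene model validation catches bad input", {
  expect_error(make_models(gene_id = "g", transcript_id = "t", contig = "c",
                           start = 10, end = 5, strand = "+"), "start")
  expect_error(make_models(gene_id = "g", transcript_id = "t", contig = "c",
                           start = 1, end = 5, strand = "x"), "strand")
  expect_error(make_models(gene_id = c("g", "g"), transcript_id = c("t", "t"),
                           contig = "c", start = 1, end = 5, strand = "+"),
               "duplicated")
})
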