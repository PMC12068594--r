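## Expression-side processing: TPM, upper-quartile normalization, expressed
## and DEG filters, set intersections, clustering transform, Ward.D2.

#' Transcripts-per-million normalization
#'
#' Per sample: rate_g = count_g / length_kb_g, TPM_g = 1e6 * rate_g / sum(rates).
#' Every column of the result sums to 1e6.
#'
#' @param counts Gene x sample matrix of non-negative counts.
#' @param lengths Gene lengths in bp (> 0), recycled over rows.
#' @return TPM matrix with the same dimnames.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  check_that(all(counts >= 0), "counts must be non-negative")
  check_that(length(lengths) == nrow(counts) && all(lengths > 0),
             "lengths must be positive, one per gene")
  rate <- counts / (lengths / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stop(sprintf("TPM undefined for all-zero sample(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Upper-quartile normalization
#'
#' Rescales each sample so its 75th percentile over genes nonzero in that
#' sample equals the geometric mean of all samples' upper quartiles. The
#' geometric-mean target keeps the output on the scale of the input and is
#' symmetric in the samples.
#'
#' @param x Gene x sample matrix (TPM or counts).
#' @param min_nonzero Minimum nonzero genes required per sample (default 4).
#' @return Normalized matrix; attribute `uq_factors` holds the per-sample
#'   scale factors applied.
#' @export
upper_quartile_normalize <- function(x, min_nonzero = 4) {
  x <- as.matrix(x)
  check_that(all(x >= 0), "matrix must be non-negative")
  uq <- apply(x, 2, function(v) {
    nz <- v[v > 0]
    if (length(nz) < min_nonzero) {
      stop(sprintf("sample has fewer than %d nonzero genes", min_nonzero), call. = FALSE)
    }
    stats::quantile(nz, 0.75, names = FALSE)
  })
  target <- exp(mean(log(uq)))
  fac <- target / uq
  out <- sweep(x, 2, fac, "*")
  attr(out, "uq_factors") <- fac
  out
}

#' Expressed-gene filter
#'
#' Genes whose mean TPM across libraries is strictly greater than
#' `min_mean_tpm` (default 1) are retained.
#'
#' @param x TPM matrix (genes x samples).
#' @param min_mean_tpm Threshold, strict.
#' @return Character vector of retained gene ids (rownames), or row indices
#'   if the matrix is unnamed.
#' @export
filter_expressed <- function(x, min_mean_tpm = 1) {
  x <- as.matrix(x)
  keep <- rowMeans(x) > min_mean_tpm
  if (is.null(rownames(x))) which(keep) else rownames(x)[keep]
}

#' Stand-in differential-expression test
#'
#' A deliberately simple, clearly labeled substitute for the external
#' negative-binomial Wald analysis used upstream of this package: counts are
#' upper-quartile normalized, log2(x + 1) transformed, and tested per gene
#' with limma's moderated t statistic; p-values are BH adjusted. The reported
#' `log2fc` is the log2 ratio of group means of normalized counts (offset
#' 0.5). Supply an externally computed DEG table instead whenever one is
#' available.
#'
#' @param counts Gene x sample count matrix.
#' @param groups Factor/vector of length `ncol(counts)` with exactly two
#'   levels; the fold change is level 2 over level 1.
#' @param chromosome Optional per-gene chromosome labels carried through.
#' @param normalize Upper-quartile normalize first (default TRUE).
#' @return data.frame (`deg_table`): `gene_id`, `log2fc`, `pvalue`, `padj`,
#'   and `chromosome` if given.
#' @export
de_test_standin <- function(counts, groups, chromosome = NULL, normalize = TRUE) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  check_that(nlevels(groups) == 2, "exactly two groups are required")
  check_that(all(table(groups) >= 2),
             "each group needs >= 2 replicates; use external DE statistics otherwise")
  check_that(length(groups) == ncol(counts), "one group label per sample")
  norm <- if (normalize) upper_quartile_normalize(counts) else counts
  logm <- log2(norm + 1)
  design <- stats::model.matrix(~groups)
  fit <- limma::eBayes(limma::lmFit(logm, design), trend = TRUE)
  p <- fit$p.value[, 2]
  m1 <- rowMeans(norm[, groups == levels(groups)[1], drop = FALSE])
  m2 <- rowMeans(norm[, groups == levels(groups)[2], drop = FALSE])
  lfc <- log2(m2 + 0.5) - log2(m1 + 0.5)
  gene_id <- rownames(counts)
  if (is.null(gene_id)) gene_id <- paste0("gene_", seq_len(nrow(counts)))
  out <- data.frame(gene_id = gene_id, log2fc = unname(lfc),
                    pvalue = unname(p), padj = bh_fdr(unname(p)),
                    stringsAsFactors = FALSE)
  if (!is.null(chromosome)) out$chromosome <- chromosome
  attr(out, "method") <- "stand-in: limma moderated t on log2(UQ-normalized + 1)"
  out
}

#' Differential-expression threshold filter
#'
#' Keeps genes with `log2fc > lfc_cut` or `log2fc < -lfc_cut`, and
#' `padj < alpha`. All comparisons are strict, so boundary rows are dropped.
#'
#' @param table DEG table with columns `gene_id`, `log2fc`, `padj`.
#' @param lfc_cut Fold-change cutoff on the log2 scale (default 1).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Character vector of DEG gene ids.
#' @export
deg_filter <- function(table, lfc_cut = 1, alpha = 0.05) {
  check_that(all(c("gene_id", "log2fc", "padj") %in% names(table)),
             "DEG table needs columns gene_id, log2fc, padj")
  keep <- (table$log2fc > lfc_cut | table$log2fc < -lfc_cut) & table$padj < alpha
  keep[is.na(keep)] <- FALSE
  table$gene_id[keep]
}

#' Intersections of named gene sets
#'
#' @param sets Named list of character vectors.
#' @return list with `sizes`, `pairwise` (data.frame of all unordered pairs
#'   with intersection sizes and members) and `common` (intersection of all
#'   sets). Gene vectors are sorted for deterministic output.
#' @export
intersect_gene_sets <- function(sets) {
  check_that(is.list(sets) && length(sets) >= 1 && !is.null(names(sets)) &&
               all(nzchar(names(sets))), "`sets` must be a named list")
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  nm <- names(sets)
  pairs <- if (length(sets) >= 2) t(utils::combn(nm, 2)) else matrix(character(0), ncol = 2)
  pw <- data.frame(
    set_a = pairs[, 1], set_b = pairs[, 2],
    n = apply(pairs, 1, function(p) length(intersect(sets[[p[1]]], sets[[p[2]]]))),
    stringsAsFactors = FALSE
  )
  pw$members <- apply(pairs, 1, function(p) paste(intersect(sets[[p[1]]], sets[[p[2]]]),
                                                  collapse = ","))
  list(sizes = vapply(sets, length, integer(1)),
       pairwise = pw,
       common = Reduce(intersect, sets))
}

#' Shifted-log transform for clustering
#'
#' Documented stand-in for a regularized-log transform: log2(normalized
#' count + 1). The returned matrix carries attribute `transform` naming the
#' substitution.
#'
#' @param counts Gene x sample count matrix.
#' @param normalize Upper-quartile normalize first (default TRUE).
#' @return Transformed matrix.
#' @export
transform_for_clustering <- function(counts, normalize = TRUE) {
  counts <- as.matrix(counts)
  check_that(all(counts >= 0), "counts must be non-negative")
  norm <- if (normalize) upper_quartile_normalize(counts) else counts
  out <- log2(norm + 1)
  attr(out, "transform") <- "log2(x + 1) shifted log; stand-in for a regularized-log transform"
  out
}

#' Ward.D2 hierarchical clustering
#'
#' Agglomerative clustering with the Ward.D2 criterion on Euclidean
#' distances, cut at `k` clusters.
#'
#' @param x Numeric matrix; rows (`axis = "rows"`) or columns
#'   (`axis = "cols"`) are clustered.
#' @param k Number of clusters (1 <= k <= n).
#' @param axis Which margin to cluster.
#' @return list of class `ward_clustering`: `assignment` (named integer
#'   vector), `hclust` (the dendrogram), `method` = "ward.D2".
#' @export
ward_cluster <- function(x, k, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  m <- as.matrix(x)
  if (axis == "cols") m <- t(m)
  n <- nrow(m)
  check_that(k >= 1 && k <= n, sprintf("k must be in [1, %d]", n))
  hc <- stats::hclust(stats::dist(m), method = "ward.D2")
  structure(list(assignment = stats::cutree(hc, k = k), hclust = hc,
                 method = "ward.D2", k = k),
            class = "ward_clustering")
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("<ward_clustering> %s, k = %d, n = %d\n", x$method, x$k,
              length(x$assignment)))
  print(table(x$assignment))
  invisible(x)
}
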