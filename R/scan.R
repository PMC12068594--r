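## Promoter scanning, FDR control over scanned windows, and the TF x gene
## binding-strength matrix.

## Integer scores of every window of the (discretized) log-odds matrix `li`
## along integer-coded sequence `codes`. Windows containing N (NA code) or a
## -Inf-scoring base get -Inf.
slide_scores <- function(codes, li) {
  L <- ncol(li)
  n_off <- length(codes) - L + 1L
  if (n_off < 1L) return(numeric(0))
  sc <- numeric(n_off)
  for (j in seq_len(L)) {
    sc <- sc + li[, j][codes[j:(j + n_off - 1L)]]
  }
  sc[is.na(sc)] <- -Inf
  sc
}

#' Scan one promoter with one PWM
#'
#' Scores every offset of the promoter on both strands with the PWM's
#' log-odds matrix (discretized at 1e-4 bits), assigns each window an exact
#' background p-value, and reports windows with `pvalue <= alpha_raw`. A
#' minus-strand hit at offset `o` means the reverse complement of the motif
#' matches the promoter sequence starting at 0-based offset `o`. Positions
#' containing `N` never match.
#'
#' @param promoter A single-row slice of a `promoter_set`, or a plain
#'   character DNA string.
#' @param x A `pwm`.
#' @param alpha_raw Raw p-value threshold for reporting (default 0.05).
#' @param background `"uniform"`, `"promoter"` (composition of this
#'   sequence), or a numeric 4-vector.
#' @return data.frame with columns `tf_id`, `gene_id`, `transcript_id`,
#'   `offset`, `strand`, `score` (bits), `pvalue`. If the motif is longer
#'   than the window an empty result is returned with a warning.
#' @export
scan_promoter <- function(promoter, x, alpha_raw = 0.05, background = "uniform") {
  sp <- scan_windows(promoter, x, background)
  keep <- sp$pvalue <= alpha_raw & is.finite(sp$score)  # N windows never hit
  sp[keep, , drop = FALSE]
}

## Score all windows of one promoter; returns the full table (no threshold).
scan_windows <- function(promoter, x, background = "uniform") {
  stopifnot(inherits(x, "pwm"))
  if (is.character(promoter) && is.null(dim(promoter))) {
    seqs <- promoter
    gene_id <- NA_character_; transcript_id <- NA_character_
  } else {
    stopifnot(nrow(promoter) == 1L)
    seqs <- promoter$sequence
    gene_id <- promoter$gene_id; transcript_id <- promoter$transcript_id
  }
  bg <- resolve_background(background, seqs, x)
  codes <- encode_dna(seqs)
  L <- ncol(x$matrix)
  empty <- data.frame(tf_id = character(0), gene_id = character(0),
                      transcript_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      pvalue = numeric(0), stringsAsFactors = FALSE)
  if (length(codes) < L) {
    warning(sprintf("motif '%s' (length %d) longer than window (%d nt); no hits",
                    x$tf_id, L, length(codes)))
    return(empty)
  }
  li_f <- discretize_lo(pwm_log_odds(x, bg))
  li_r <- revcomp_matrix(li_f)
  s_f <- slide_scores(codes, li_f)
  s_r <- slide_scores(codes, li_r)
  p_f <- tail_pvalue(score_tail_dist(li_f, bg), s_f)
  p_r <- tail_pvalue(score_tail_dist(li_r, bg), s_r)
  n_off <- length(s_f)
  out <- data.frame(
    tf_id = x$tf_id, gene_id = gene_id, transcript_id = transcript_id,
    offset = rep(0:(n_off - 1L), 2L),
    strand = rep(c("+", "-"), each = n_off),
    score = c(s_f, s_r) * SCORE_DELTA,
    pvalue = c(p_f, p_r), stringsAsFactors = FALSE
  )
  out$score[!is.finite(out$score)] <- -Inf
  out
}

resolve_background <- function(background, seqs, x) {
  if (is.numeric(background)) {
    check_that(length(background) == 4 && all(background > 0),
               "numeric background must be a strictly positive 4-vector")
    return(background / sum(background))
  }
  switch(match.arg(background, c("uniform", "promoter")),
         uniform = rep(0.25, 4),
         promoter = {
           v <- unlist(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE))
           tab <- table(factor(v, levels = DNA_BASES))
           cnt <- as.numeric(tab) + 1  # add-one so the background stays positive
           cnt / sum(cnt)
         })
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Vector of adjusted p-values (monotone step-up, capped at 1).
#' @export
bh_fdr <- function(pvalues) {
  check_that(is.numeric(pvalues) && !anyNA(pvalues) &&
               all(pvalues >= 0) && all(pvalues <= 1),
             "p-values must be numbers in [0, 1]")
  n <- length(pvalues)
  if (n == 0L) return(numeric(0))
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * pvalues[o]))[ro]
}

#' Scan a promoter set with a set of PWMs, with per-TF FDR control
#'
#' For each PWM, every window of every promoter on both strands forms the
#' multiple-testing family; Benjamini-Hochberg adjusted p-values are computed
#' over that family and hits with `pvalue <= alpha_raw` are returned with
#' their `padj`. Genomic coordinates of each hit are reported so that hits
#' shared by overlapping isoform promoters can be deduplicated downstream.
#'
#' @param promoters A `promoter_set` (see [extract_promoters()]).
#' @param pwms A `pwm` or list of `pwm` objects.
#' @param alpha_raw Raw p-value cutoff for rows kept in the output (the BH
#'   family always includes all windows). Default 0.05.
#' @param background `"promoter"` (default: pooled composition of the scanned
#'   promoter set), `"uniform"`, or a numeric 4-vector.
#' @return data.frame of hits: `tf_id`, `gene_id`, `transcript_id`, `offset`,
#'   `strand`, `score`, `pvalue`, `padj`, `contig`, `genome_start` (0-based),
#'   `genome_strand`.
#' @export
scan_promoters <- function(promoters, pwms, alpha_raw = 0.05,
                           background = "promoter") {
  stopifnot(inherits(promoters, "data.frame"))
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- resolve_background(background, promoters$sequence, NULL)
  per_tf <- lapply(pwms, function(x) {
    rows <- lapply(seq_len(nrow(promoters)), function(i) {
      w <- scan_windows(promoters[i, ], x, background = bg)
      if (nrow(w) == 0) return(w)
      w$contig <- promoters$contig[i]
      L <- ncol(x$matrix)
      if (promoters$strand[i] == "+") {
        w$genome_start <- promoters$window_start[i] + w$offset
        w$genome_strand <- w$strand
      } else {
        win_len <- promoters$window_end[i] - promoters$window_start[i]
        w$genome_start <- promoters$window_start[i] + win_len - w$offset - L
        w$genome_strand <- ifelse(w$strand == "+", "-", "+")
      }
      w
    })
    all_w <- do.call(rbind, rows)
    if (is.null(all_w) || nrow(all_w) == 0) return(all_w)
    all_w$padj <- bh_fdr(all_w$pvalue)
    all_w[all_w$pvalue <= alpha_raw & is.finite(all_w$score), , drop = FALSE]
  })
  out <- do.call(rbind, per_tf)
  if (is.null(out)) {
    out <- data.frame(tf_id = character(0), gene_id = character(0),
                      transcript_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      pvalue = numeric(0), contig = character(0),
                      genome_start = integer(0), genome_strand = character(0),
                      padj = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Count FDR-passing hits into a binding-strength matrix
#'
#' Binding strength of a TF for a gene is the number of its motif hits with
#' `padj < fdr_alpha` in the gene's promoter window(s). Hits found at the
#' same genomic coordinate in overlapping isoform promoters are counted once
#' (`dedup = TRUE`). Genes listed in `genes` but flagged unannotated are
#' masked (`NA`), not zero.
#'
#' @param hits Hit table from [scan_promoters()] (must carry `padj`).
#' @param tfs,genes Row and column universes of the matrix. Defaults to the
#'   TFs/genes present in `hits`.
#' @param fdr_alpha FDR threshold, strict (default 0.05).
#' @param annotated Optional named logical vector over `genes`; `FALSE`
#'   masks the gene's column as `NA`.
#' @param dedup Deduplicate hits by genomic coordinate across isoforms.
#' @return Integer matrix (TF x gene) with attribute `annotated`.
#' @export
binding_strength <- function(hits, tfs = NULL, genes = NULL, fdr_alpha = 0.05,
                             annotated = NULL, dedup = TRUE) {
  check_that(!is.null(hits$padj), "hits must carry a padj column (see scan_promoters)")
  if (is.null(tfs)) tfs <- sort(unique(hits$tf_id))
  if (is.null(genes)) genes <- sort(unique(hits$gene_id))
  keep <- hits[hits$padj < fdr_alpha, , drop = FALSE]
  if (dedup && nrow(keep) > 0 && !is.null(keep$genome_start)) {
    key <- paste(keep$tf_id, keep$gene_id, keep$contig, keep$genome_start,
                 keep$genome_strand, sep = "\r")
    keep <- keep[!duplicated(key), , drop = FALSE]
  }
  m <- matrix(0L, nrow = length(tfs), ncol = length(genes),
              dimnames = list(tfs, genes))
  if (nrow(keep) > 0) {
    tab <- table(factor(keep$tf_id, levels = tfs), factor(keep$gene_id, levels = genes))
    m[] <- as.integer(tab)
  }
  if (is.null(annotated)) annotated <- stats::setNames(rep(TRUE, length(genes)), genes)
  check_that(all(genes %in% names(annotated)), "annotated mask must cover all genes")
  ann <- as.logical(annotated[genes])
  m[, !ann] <- NA_integer_
  attr(m, "annotated") <- stats::setNames(ann, genes)
  m
}
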