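## Gene models, promoter-window extraction and the assembly-quality filter.

#' Construct and validate a table of gene models
#'
#' A gene model is one transcript of one gene: the unit whose promoter window
#' is extracted. Coordinates are GFF3-style, 1-based inclusive.
#'
#' @param df data.frame with columns `gene_id`, `transcript_id`, `contig`,
#'   `start`, `end`, `strand` and optionally `chromosome`.
#' @return A validated data.frame of class `gene_models`.
#' @export
gene_models <- function(df) {
  req <- c("gene_id", "transcript_id", "contig", "start", "end", "strand")
  check_that(all(req %in% names(df)),
             paste("gene model table must have columns:", paste(req, collapse = ", ")))
  if (is.null(df$chromosome)) df$chromosome <- sub("^chr", "", df$contig)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  check_that(all(df$strand %in% c("+", "-")), "strand must be '+' or '-'")
  check_that(all(df$start >= 1) && all(df$start <= df$end),
             "coordinates must satisfy 1 <= start <= end")
  dup <- df$transcript_id[duplicated(df$transcript_id)]
  check_that(length(dup) == 0,
             paste("duplicated transcript ids:", paste(unique(dup), collapse = ", ")))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Parse a GFF3 annotation into gene models
#'
#' Reads `gene` and `mRNA`/`transcript` features and returns one gene model
#' per transcript. Genes without any transcript contribute a single model
#' built from the gene feature itself. Transcripts whose `Parent` does not
#' resolve to a gene raise a parse error that lists the offending ids, as do
#' records with `start > end`.
#'
#' @param path Path to a GFF3 file.
#' @param chrom_map Optional named character vector mapping contig names to
#'   chromosome labels (e.g. `c(contig_1 = "Z")`). By default a leading
#'   `"chr"` prefix is stripped from the contig name.
#' @return A `gene_models` data.frame.
#' @export
parse_annotation <- function(path, chrom_map = NULL) {
  lines <- readLines(path)
  body <- grep("^[^#]", lines, value = FALSE)
  if (length(body)) {
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    bad <- body[vapply(fields, function(f) {
      length(f) >= 5 && suppressWarnings(as.numeric(f[4]) > as.numeric(f[5]))
    }, logical(1))]
    check_that(length(bad) == 0,
               paste("malformed coordinates (start > end) on line(s):",
                     paste(bad, collapse = ", ")))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  txs <- gr[type %in% c("mRNA", "transcript")]
  gene_ids <- as.character(genes$ID)
  parent <- vapply(as.list(txs$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  orphan <- as.character(txs$ID)[is.na(parent) | !parent %in% gene_ids]
  check_that(length(orphan) == 0,
             paste("transcripts with missing/unknown Parent gene:",
                   paste(orphan, collapse = ", ")))
  to_chrom <- function(contig) {
    if (!is.null(chrom_map) && contig %in% names(chrom_map)) unname(chrom_map[[contig]])
    else sub("^chr", "", contig)
  }
  rows <- list()
  if (length(txs)) {
    rows[[1]] <- data.frame(
      gene_id = parent,
      transcript_id = as.character(txs$ID),
      contig = as.character(GenomicRanges::seqnames(txs)),
      start = GenomicRanges::start(txs),
      end = GenomicRanges::end(txs),
      strand = as.character(GenomicRanges::strand(txs)),
      stringsAsFactors = FALSE
    )
  }
  lonely <- setdiff(gene_ids, parent)
  if (length(lonely)) {
    g <- genes[match(lonely, gene_ids)]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = lonely,
      transcript_id = lonely,
      contig = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g),
      end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, rows)
  check_that(!is.null(df) && nrow(df) > 0, "annotation contains no gene or transcript features")
  df$chromosome <- vapply(df$contig, to_chrom, character(1))
  gene_models(df)
}

#' Extract promoter windows around transcription start sites
#'
#' For each gene model the window spans `upstream` bases 5' of the TSS and
#' `downstream` bases 3' of it (the TSS base is the first base of the
#' downstream segment), on the transcript's sense strand. Internally windows
#' are 0-based half-open genomic intervals; on the minus strand the returned
#' sequence is reverse-complemented so it always reads 5' to 3' relative to
#' the transcript. Windows running off a contig end are clipped and flagged
#' `truncated`. IUPAC ambiguity codes are normalized to `N`.
#'
#' @param genome Named character vector or `DNAStringSet` of contig sequences.
#' @param models A `gene_models` data.frame (see [gene_models()]).
#' @param upstream,downstream Window half-widths in bp (defaults 2000/1000).
#' @param collapse `"isoform"` (default) keeps one window per transcript;
#'   `"gene"` keeps a single window anchored at the 5'-most TSS per gene.
#' @return data.frame of class `promoter_set` with columns `gene_id`,
#'   `transcript_id`, `contig`, `window_start`, `window_end` (0-based
#'   half-open), `strand`, `truncated`, `sequence`.
#' @export
extract_promoters <- function(genome, models, upstream = 2000, downstream = 1000,
                              collapse = c("isoform", "gene")) {
  collapse <- match.arg(collapse)
  genome <- as_genome_chr(genome)
  check_that(upstream >= 0 && downstream >= 1, "window must include the TSS (downstream >= 1)")
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  missing_contig <- setdiff(unique(models$contig), names(genome))
  check_that(length(missing_contig) == 0,
             paste("contig(s) not present in genome:", paste(missing_contig, collapse = ", ")))

  ## TSS (0-based) is the 5'-most transcribed coordinate on the strand
  tss0 <- ifelse(models$strand == "+", models$start - 1L, models$end - 1L)

  if (collapse == "gene") {
    keep <- unlist(lapply(split(seq_len(nrow(models)), models$gene_id), function(i) {
      s <- models$strand[i][1]
      if (s == "+") i[which.min(tss0[i])] else i[which.max(tss0[i])]
    }), use.names = FALSE)
    models <- models[sort(keep), , drop = FALSE]
    tss0 <- tss0[sort(keep)]
  }

  n <- nrow(models)
  ws <- integer(n); we <- integer(n); seqs <- character(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    len <- nchar(genome[[models$contig[i]]])
    if (models$strand[i] == "+") {
      raw_s <- tss0[i] - upstream
      raw_e <- tss0[i] + downstream
    } else {
      raw_s <- tss0[i] - downstream + 1L
      raw_e <- tss0[i] + upstream + 1L
    }
    s <- max(0L, raw_s); e <- min(len, raw_e)
    check_that(e > s, sprintf("window for transcript '%s' falls outside contig '%s'",
                              models$transcript_id[i], models$contig[i]))
    sq <- substr(genome[[models$contig[i]]], s + 1L, e)
    if (models$strand[i] == "-") sq <- revcomp_chr(sq)
    ws[i] <- s; we[i] <- e
    seqs[i] <- normalize_ambiguity(sq)
    trunc[i] <- (s != raw_s) || (e != raw_e)
  }
  out <- data.frame(
    gene_id = models$gene_id, transcript_id = models$transcript_id,
    contig = models$contig, window_start = ws, window_end = we,
    strand = models$strand, truncated = trunc, sequence = seqs,
    stringsAsFactors = FALSE
  )
  attr(out, "upstream") <- upstream
  attr(out, "downstream") <- downstream
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Assembly-quality filter for cross-species comparison
#'
#' A genome assembly qualifies when its scaffold N50 exceeds 500 kb and it
#' has fewer than 30,000 scaffolds (both strict).
#'
#' @param scaffold_n50 Scaffold N50 in bp.
#' @param n_scaffolds Number of scaffolds.
#' @param min_n50,max_scaffolds Thresholds (defaults 5e5 and 3e4).
#' @return list with `pass` (logical) and `reasons` (character, empty if pass).
#' @export
assembly_filter <- function(scaffold_n50, n_scaffolds,
                            min_n50 = 5e5, max_scaffolds = 3e4) {
  check_that(scaffold_n50 > 0 && n_scaffolds > 0, "assembly stats must be positive")
  reasons <- character(0)
  if (!(scaffold_n50 > min_n50)) {
    reasons <- c(reasons, sprintf("scaffold N50 %g not greater than %g", scaffold_n50, min_n50))
  }
  if (!(n_scaffolds < max_scaffolds)) {
    reasons <- c(reasons, sprintf("%g scaffolds not fewer than %g", n_scaffolds, max_scaffolds))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Write promoter windows as FASTA
#'
#' Headers follow `gene|transcript|contig:start-end(strand)`.
#' @param promoters A `promoter_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  hdr <- sprintf("%s|%s|%s:%d-%d(%s)", promoters$gene_id, promoters$transcript_id,
                 promoters$contig, promoters$window_start, promoters$window_end,
                 promoters$strand)
  ss <- Biostrings::DNAStringSet(promoters$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
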