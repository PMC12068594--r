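## Plain-text readers/writers for the package's standard artifacts.

#' Write a genome as FASTA
#' @param genome Named character vector or DNAStringSet.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome_chr(genome)
  ss <- Biostrings::DNAStringSet(unname(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ## keep only the first word of each header
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write gene models as GFF3 (gene + mRNA records with Parent links)
#' @param models A `gene_models` data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  genes <- models[!duplicated(models$gene_id), , drop = FALSE]
  gspan <- do.call(rbind, lapply(split(models, models$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], contig = d$contig[1],
               start = min(d$start), end = max(d$end), strand = d$strand[1],
               stringsAsFactors = FALSE)
  }))
  gspan <- gspan[match(genes$gene_id, gspan$gene_id), ]
  gene_gr <- GenomicRanges::GRanges(
    gspan$contig, IRanges::IRanges(gspan$start, gspan$end), gspan$strand,
    type = "gene", ID = gspan$gene_id,
    Parent = IRanges::CharacterList(vector("list", nrow(gspan))))
  tx_gr <- GenomicRanges::GRanges(
    models$contig, IRanges::IRanges(models$start, models$end), models$strand,
    type = "mRNA", ID = models$transcript_id,
    Parent = as(models$gene_id, "CharacterList"))
  rtracklayer::export(c(gene_gr, tx_gr), path, format = "gff3")
  invisible(path)
}

#' Write a gene x sample count/TPM table as TSV
#'
#' Columns: `gene_id`, `length`, `chromosome`, then one column per sample.
#' @param counts Matrix with rownames.
#' @param lengths Gene lengths in bp.
#' @param chromosome Per-gene chromosome labels.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, lengths, chromosome, path) {
  df <- data.frame(gene_id = rownames(counts), length = lengths,
                   chromosome = chromosome, counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_counts_tsv()]
#' @param path TSV file.
#' @return list: `counts`, `lengths`, `chromosome`.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("gene_id", "length", "chromosome")),
                    drop = FALSE])
  rownames(m) <- df$gene_id
  list(counts = m, lengths = df$length, chromosome = df$chromosome)
}

#' Write a binding-strength matrix with its annotation mask sidecar
#' @param m Matrix from [binding_strength()].
#' @param path Output TSV; the mask goes to `paste0(path, ".mask")`.
#' @return `path`, invisibly.
#' @export
write_binding_matrix <- function(m, path) {
  df <- data.frame(tf_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- attr(m, "annotated")
  if (is.null(ann)) ann <- stats::setNames(!apply(is.na(m), 2, all), colnames(m))
  utils::write.table(data.frame(gene_id = names(ann), annotated = ann),
                     paste0(path, ".mask"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a binding-strength matrix and its mask
#' @param path TSV written by [write_binding_matrix()].
#' @return Matrix with `annotated` attribute (masked columns NA).
#' @export
read_binding_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  maskf <- paste0(path, ".mask")
  if (file.exists(maskf)) {
    md <- utils::read.delim(maskf, stringsAsFactors = FALSE)
    ann <- stats::setNames(as.logical(md$annotated), md$gene_id)
    m[, colnames(m)[!ann[colnames(m)]]] <- NA
    attr(m, "annotated") <- ann[colnames(m)]
  }
  m
}

#' Write promoter windows as BED6
#' @param promoters A `promoter_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_promoter_bed <- function(promoters, path) {
  df <- data.frame(promoters$contig, promoters$window_start, promoters$window_end,
                   paste(promoters$gene_id, promoters$transcript_id, sep = "|"),
                   0L, promoters$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
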