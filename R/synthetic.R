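## Synthetic genomes, annotations, motif plants, counts and species sets
## with recorded ground truth, so every downstream stage has a closed-loop
## test without external downloads.

#' Generate a random genome
#'
#' Contigs are i.i.d. nucleotide sequences with expected GC content
#' `gc_fraction`. Runs are byte-identical for the same seed.
#'
#' @param n_contigs Number of contigs.
#' @param contig_lengths Integer vector of lengths (recycled to `n_contigs`).
#' @param gc_fraction Expected GC proportion, in (0, 1). Default 0.41,
#'   a typical avian genome-wide GC content.
#' @param seed RNG seed.
#' @param contig_names Optional contig names (default `contig_1`, ...).
#' @return Named character vector of sequences.
#' @export
generate_genome <- function(n_contigs, contig_lengths, gc_fraction = 0.41,
                            seed = 1, contig_names = NULL) {
  check_that(n_contigs >= 1, "need at least one contig")
  contig_lengths <- rep_len(as.integer(contig_lengths), n_contigs)
  check_that(all(contig_lengths >= 1), "contig lengths must be >= 1")
  check_that(is_prob(gc_fraction) && gc_fraction > 0 && gc_fraction < 1,
             "gc_fraction must be strictly between 0 and 1")
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
             (1 - gc_fraction) / 2)
  if (is.null(contig_names)) contig_names <- paste0("contig_", seq_len(n_contigs))
  with_seed(seed, {
    stats::setNames(vapply(contig_lengths, function(len) {
      paste(sample(DNA_BASES, len, replace = TRUE, prob = probs), collapse = "")
    }, character(1)), contig_names)
  })
}

#' Generate non-pathological gene models on a genome
#'
#' Genes are packed into equal slots per contig so that every promoter
#' window (2 kb upstream / 1 kb downstream of the TSS) fits inside its
#' contig. Each gene gets `isoforms_per_gene` transcripts whose TSSs may be
#' offset from one another within the slot. Coordinates are 1-based
#' inclusive, GFF3-style.
#'
#' @param genome Named character vector (see [generate_genome()]).
#' @param n_genes Total number of genes.
#' @param isoforms_per_gene Transcripts per gene (default 1).
#' @param strand_mix Proportion of genes on the '+' strand (default 0.5).
#' @param seed RNG seed.
#' @param upstream,downstream Promoter margins reserved around each TSS.
#' @param tss_jitter Maximum TSS offset between isoforms of a gene (default 200).
#' @return A `gene_models` data.frame.
#' @export
generate_gene_models <- function(genome, n_genes, isoforms_per_gene = 1,
                                 strand_mix = 0.5, seed = 1,
                                 upstream = 2000, downstream = 1000,
                                 tss_jitter = 200) {
  genome <- as_genome_chr(genome)
  check_that(n_genes >= 1 && isoforms_per_gene >= 1, "counts must be >= 1")
  check_that(is_prob(strand_mix), "strand_mix must be a proportion")
  lens <- nchar(genome)
  ## distribute genes over contigs proportionally to length
  alloc <- floor(n_genes * lens / sum(lens))
  while (sum(alloc) < n_genes) alloc[which.max(lens - alloc)] <- alloc[which.max(lens - alloc)] + 1L
  gene_len <- 600L
  ## symmetric margin: whatever the strand, the promoter window and gene
  ## body must fit on both sides of the TSS inside the slot
  margin <- max(upstream, downstream + 1L, gene_len)
  need <- 2L * margin + tss_jitter + 2L
  for (ci in seq_along(genome)) {
    if (alloc[ci] > 0 && lens[ci] %/% alloc[ci] < need) {
      stop(sprintf("infeasible packing: contig '%s' (%d bp) cannot hold %d gene slot(s) of %d bp",
                   names(genome)[ci], lens[ci], alloc[ci], need), call. = FALSE)
    }
  }
  with_seed(seed, {
    rows <- list()
    g <- 0L
    for (ci in seq_along(genome)) {
      if (alloc[ci] == 0) next
      slot <- lens[ci] %/% alloc[ci]
      for (si in seq_len(alloc[ci])) {
        g <- g + 1L
        gid <- sprintf("gene_%03d", g)
        strand <- if (stats::runif(1) < strand_mix) "+" else "-"
        slot_start <- (si - 1L) * slot  # 0-based slot origin
        ## anchor the base TSS so window + gene body + isoform jitter fit
        base_tss <- slot_start + margin +
          sample.int(max(1L, slot - need + 1L), 1L) - 1L
        for (k in seq_len(isoforms_per_gene)) {
          jit <- if (isoforms_per_gene == 1L) 0L else
            as.integer(round((k - 1L) * tss_jitter / (isoforms_per_gene - 1L)))
          if (strand == "+") {
            start <- base_tss + jit + 1L   # 1-based; TSS0 = base_tss + jit
            end <- start + gene_len - 1L
          } else {
            end <- base_tss + tss_jitter - jit + 1L  # TSS0 = base_tss + tss_jitter - jit
            start <- end - gene_len + 1L
          }
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = gid, transcript_id = sprintf("%s.t%d", gid, k),
            contig = names(genome)[ci], start = start, end = end,
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
    gene_models(do.call(rbind, rows))
  })
}

#' Plant motif consensus copies into promoter windows
#'
#' Writes the consensus sequence of each PWM at randomly chosen,
#' non-overlapping offsets inside the promoter window of the gene's first
#' transcript, on the transcript's sense strand, and records every
#' insertion. Planting a consensus guarantees the maximal PWM score, so
#' closed-loop recovery tests are sharp.
#'
#' @param genome Named character vector.
#' @param models `gene_models` for the genome.
#' @param pwms Named list of `pwm` objects.
#' @param copies data.frame with columns `gene_id`, `tf_id`, `n`.
#' @param seed RNG seed.
#' @param upstream,downstream Promoter window geometry (defaults 2000/1000).
#' @return list: `genome` (modified sequences) and `truth` (a
#'   `synthetic_truth` whose `planted_hits` lists gene, transcript, TF,
#'   0-based offset in the promoter window, and strand).
#' @export
plant_motifs <- function(genome, models, pwms, copies, seed = 1,
                         upstream = 2000, downstream = 1000) {
  genome <- as_genome_chr(genome)
  check_that(all(c("gene_id", "tf_id", "n") %in% names(copies)),
             "copies needs columns gene_id, tf_id, n")
  check_that(all(copies$n >= 0), "copy numbers must be >= 0")
  check_that(all(copies$gene_id %in% models$gene_id), "unknown gene in copies")
  check_that(all(copies$tf_id %in% names(pwms)), "unknown TF in copies")
  proms <- extract_promoters(genome, models, upstream, downstream)
  ## one promoter per gene: its first transcript
  first_tx <- proms[!duplicated(proms$gene_id), , drop = FALSE]
  rownames(first_tx) <- first_tx$gene_id
  planted <- list()
  occupied <- stats::setNames(vector("list", nrow(first_tx)), first_tx$gene_id)
  with_seed(seed, {
    for (r in seq_len(nrow(copies))) {
      n <- copies$n[r]
      if (n == 0) next
      gid <- copies$gene_id[r]
      tf <- copies$tf_id[r]
      cons <- pwm_consensus(pwms[[tf]])
      L <- nchar(cons)
      pr <- first_tx[gid, ]
      win_len <- pr$window_end - pr$window_start
      for (k in seq_len(n)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          off <- sample.int(win_len - L + 1L, 1L) - 1L  # 0-based in window
          clash <- any(vapply(occupied[[gid]], function(iv) {
            off < iv[2] && (off + L) > iv[1]
          }, logical(1)))
          if (!clash) {
            occupied[[gid]] <- c(occupied[[gid]], list(c(off, off + L)))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop(sprintf("window overflow: cannot place %d copies of '%s' in promoter of '%s'",
                       n, tf, gid), call. = FALSE)
        }
        ## map promoter offset to genomic coordinates and write the consensus
        if (pr$strand == "+") {
          gstart <- pr$window_start + off           # 0-based genomic
          ins <- cons
        } else {
          gstart <- pr$window_end - off - L
          ins <- revcomp_chr(cons)
        }
        seqc <- genome[[pr$contig]]
        substr(seqc, gstart + 1L, gstart + L) <- ins
        genome[[pr$contig]] <- seqc
        planted[[length(planted) + 1L]] <- data.frame(
          gene_id = gid, transcript_id = pr$transcript_id, tf_id = tf,
          offset = off, strand = "+", stringsAsFactors = FALSE)
      }
    }
  })
  hits <- if (length(planted)) do.call(rbind, planted) else
    data.frame(gene_id = character(0), transcript_id = character(0),
               tf_id = character(0), offset = integer(0), strand = character(0))
  truth <- synthetic_truth(planted_hits = hits, seed = seed)
  list(genome = genome, truth = truth)
}

#' Ground-truth container for synthetic data
#'
#' @param planted_hits data.frame of planted motif insertions.
#' @param true_de_genes data.frame of truly DE genes with signed log2 fold changes.
#' @param chromosome_assignment Named character vector gene -> chromosome.
#' @param convergent_pair Character vector of length 2, or NULL.
#' @param seed The generator seed.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(planted_hits = NULL, true_de_genes = NULL,
                            chromosome_assignment = NULL,
                            convergent_pair = NULL, seed = NA) {
  structure(list(planted_hits = planted_hits, true_de_genes = true_de_genes,
                 chromosome_assignment = chromosome_assignment,
                 convergent_pair = convergent_pair, seed = seed),
            class = "synthetic_truth")
}

#' Generate negative-binomial RNA-seq counts with planted fold changes
#'
#' Counts follow NB(mu, dispersion) with variance mu + dispersion * mu^2.
#' Per-gene baseline means are log-normal around `base_mean` (sdlog
#' `mean_sdlog`, mean-preserving). A `de_fraction` of genes get their
#' group-2 mean scaled by `2^(+/- true_lfc_magnitude)` with random sign.
#' Chromosome labels are drawn per gene from `chrom_labels` with
#' `chrom_props` weights.
#'
#' @param n_genes Number of genes.
#' @param groups Named integer vector of replicates per group, e.g.
#'   `c(control = 3, case = 3)`. Exactly two groups.
#' @param base_mean Baseline mean count (default 100).
#' @param dispersion NB dispersion alpha > 0 (default 0.1).
#' @param de_fraction Fraction of genes with a true fold change (default 0.1).
#' @param true_lfc_magnitude Absolute planted log2 fold change (default 2).
#' @param chrom_labels Chromosome labels to sample from (default 1..28, Z, W).
#' @param chrom_props Sampling weights for `chrom_labels` (default uniform).
#' @param mean_sdlog Log-normal spread of per-gene baseline means (default 0.5;
#'   0 gives constant means).
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length model
#'   (defaults give a median near 2 kb).
#' @param seed RNG seed.
#' @return list: `counts` (genes x samples), `lengths` (bp), `groups`
#'   (factor), `chromosome`, `truth` (`synthetic_truth` with
#'   `true_de_genes`).
#' @export
generate_counts <- function(n_genes, groups = c(control = 3, case = 3),
                            base_mean = 100, dispersion = 0.1,
                            de_fraction = 0.1, true_lfc_magnitude = 2,
                            chrom_labels = c(as.character(1:28), "Z", "W"),
                            chrom_props = NULL, mean_sdlog = 0.5,
                            gene_length_meanlog = log(2000),
                            gene_length_sdlog = 0.4, seed = 1) {
  check_that(dispersion > 0, "dispersion must be > 0")
  check_that(base_mean > 0, "base_mean must be > 0")
  check_that(is_prob(de_fraction), "de_fraction must be a proportion")
  check_that(length(groups) == 2 && all(groups >= 1), "exactly two groups with >= 1 replicate")
  if (is.null(names(groups))) names(groups) <- c("group1", "group2")
  if (is.null(chrom_props)) chrom_props <- rep(1, length(chrom_labels))
  with_seed(seed, {
    gene_id <- sprintf("gene_%05d", seq_len(n_genes))
    mu0 <- if (mean_sdlog > 0) {
      stats::rlnorm(n_genes, meanlog = log(base_mean) - mean_sdlog^2 / 2,
                    sdlog = mean_sdlog)
    } else rep(base_mean, n_genes)
    n_de <- floor(de_fraction * n_genes)
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    sign <- rep(0, n_genes)
    sign[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE)
    lfc <- sign * true_lfc_magnitude
    mu <- cbind(mu0, mu0 * 2^lfc)  # per-group means
    labels <- rep(names(groups), groups)
    grp_of_sample <- rep(1:2, groups)
    size <- 1 / dispersion
    counts <- matrix(0L, n_genes, sum(groups),
                     dimnames = list(gene_id,
                                     paste0(labels, "_", unlist(lapply(groups, seq_len)))))
    for (s in seq_len(sum(groups))) {
      counts[, s] <- stats::rnbinom(n_genes, size = size, mu = mu[, grp_of_sample[s]])
    }
    lengths <- round(stats::rlnorm(n_genes, gene_length_meanlog, gene_length_sdlog))
    chromosome <- sample(chrom_labels, n_genes, replace = TRUE,
                         prob = chrom_props / sum(chrom_props))
    truth <- synthetic_truth(
      true_de_genes = data.frame(gene_id = gene_id[de_idx],
                                 true_log2fc = lfc[de_idx],
                                 stringsAsFactors = FALSE),
      chromosome_assignment = stats::setNames(chromosome, gene_id),
      seed = seed)
    list(counts = counts, lengths = lengths,
         groups = factor(labels, levels = names(groups)),
         chromosome = chromosome, truth = truth)
  })
}

#' Generate per-species binding matrices along a phylogeny
#'
#' A root TF x gene profile is drawn once, then evolves along the tree by
#' Brownian perturbation: each branch adds independent N(0, profile_noise^2
#' * branch_length) to every cell. An optional convergent pair of non-sister
#' leaves is pulled toward its shared mean profile by `convergence_strength`
#' (0 = no pull, 1 = both leaves end up identical), emulating convergent
#' regulatory evolution.
#'
#' @param tree Phylogeny (`phylo`, Newick string or file).
#' @param profile_noise Brownian standard deviation per unit branch length
#'   (default 3, about half the spread of the root profile).
#' @param convergent_pair Character vector of two non-sister leaf names, or
#'   NULL.
#' @param convergence_strength Pull strength in [0, 1] (default 0).
#' @param n_tfs,n_genes Matrix dimensions (defaults 3 TFs x 10 color genes,
#'   the scale of a regional-TF vs melanogenesis-gene comparison).
#' @param root_mean,root_sd Normal model of the root profile cells
#'   (defaults 10 and 5; values are truncated at 0).
#' @param p_unannotated Per-(species, gene) probability that a gene is
#'   missing from that species' annotation and its column masked NA
#'   (default 0).
#' @param seed RNG seed.
#' @return list: `profiles` (named list of TF x gene matrices), `tree`,
#'   `truth` (`synthetic_truth` with the convergent pair).
#' @export
generate_species_set <- function(tree, profile_noise = 3,
                                 convergent_pair = NULL,
                                 convergence_strength = 0,
                                 n_tfs = 3, n_genes = 10,
                                 root_mean = 10, root_sd = 5,
                                 p_unannotated = 0, seed = 1) {
  tree <- as_phylo(tree)
  check_that(!any(duplicated(tree$tip.label)), "tree leaves must be uniquely named")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using unit branch lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  check_that(is_prob(convergence_strength), "convergence_strength must be in [0, 1]")
  if (!is.null(convergent_pair)) {
    check_that(length(convergent_pair) == 2 &&
                 all(convergent_pair %in% tree$tip.label),
               "convergent pair must name two tree leaves")
    sis <- sister_pairs(tree)
    is_sis <- any(vapply(sis, function(p) setequal(p, convergent_pair), logical(1)))
    check_that(!is_sis, "convergent pair must be non-sister leaves")
  }
  tfs <- paste0("TF", seq_len(n_tfs))
  genes <- sprintf("color_gene_%02d", seq_len(n_genes))
  ncell <- n_tfs * n_genes
  ntip <- length(tree$tip.label)
  with_seed(seed, {
    root <- pmax(0, stats::rnorm(ncell, root_mean, root_sd))
    ## node values by preorder traversal of the edge matrix
    nnode <- ntip + tree$Nnode
    vals <- matrix(NA_real_, nnode, ncell)
    root_node <- ntip + 1L
    vals[root_node, ] <- root
    eo <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]; child <- eo$edge[e, 2]
      bl <- eo$edge.length[e]
      vals[child, ] <- vals[par, ] + stats::rnorm(ncell, 0, profile_noise * sqrt(bl))
    }
    leaves <- lapply(seq_len(ntip), function(i) vals[i, ])
    names(leaves) <- tree$tip.label
    if (!is.null(convergent_pair) && convergence_strength > 0) {
      a <- convergent_pair[1]; b <- convergent_pair[2]
      m <- (leaves[[a]] + leaves[[b]]) / 2
      leaves[[a]] <- (1 - convergence_strength) * leaves[[a]] + convergence_strength * m
      leaves[[b]] <- (1 - convergence_strength) * leaves[[b]] + convergence_strength * m
    }
    profiles <- lapply(leaves, function(v) {
      m <- matrix(pmax(0, v), n_tfs, n_genes, dimnames = list(tfs, genes))
      if (p_unannotated > 0) {
        mask <- stats::runif(n_genes) < p_unannotated
        m[, mask] <- NA_real_
      }
      m
    })
    truth <- synthetic_truth(convergent_pair = convergent_pair, seed = seed)
    list(profiles = profiles, tree = tree, truth = truth)
  })
}
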