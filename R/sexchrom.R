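## Sex-chromosome enrichment of DEGs and dosage-effect classification.

#' Per-chromosome DEG ratios
#'
#' For every chromosome with at least one expressed gene, reports the number
#' of expressed genes, the number of DEGs, their ratio, and the class:
#' `sex` for Z and W, `autosome` for numeric labels. Genes on unplaced
#' scaffolds (any other label, or missing) are excluded and reported in the
#' `excluded` attribute.
#'
#' @param degs Character vector of DEG gene ids.
#' @param universe data.frame of expressed genes with columns `gene_id` and
#'   `chromosome`.
#' @return data.frame of class `chrom_ratios`: `chromosome`, `n_genes`,
#'   `n_degs`, `ratio`, `class`.
#' @export
chromosome_ratios <- function(degs, universe) {
  check_that(all(c("gene_id", "chromosome") %in% names(universe)),
             "universe needs columns gene_id and chromosome")
  missing <- setdiff(degs, universe$gene_id)
  check_that(length(missing) == 0,
             paste("DEGs absent from the expressed-gene universe:",
                   paste(missing, collapse = ", ")))
  chrom <- as.character(universe$chromosome)
  placed <- !is.na(chrom) & (grepl("^[0-9]+[A-Za-z]?$", chrom) | chrom %in% c("Z", "W"))
  excluded <- universe$gene_id[!placed]
  u <- universe[placed, , drop = FALSE]
  chrom <- chrom[placed]
  lev <- unique(chrom)
  ## numeric chromosomes first in natural order, then Z, W
  num <- suppressWarnings(as.numeric(sub("[A-Za-z]$", "", lev)))
  lev <- lev[order(is.na(num), num, lev)]
  n_genes <- as.integer(table(factor(chrom, levels = lev)))
  is_deg <- u$gene_id %in% degs
  n_degs <- as.integer(table(factor(chrom[is_deg], levels = lev)))
  out <- data.frame(
    chromosome = lev, n_genes = n_genes, n_degs = n_degs,
    ratio = n_degs / n_genes,
    class = ifelse(lev %in% c("Z", "W"), "sex", "autosome"),
    stringsAsFactors = FALSE
  )
  attr(out, "excluded") <- excluded
  class(out) <- c("chrom_ratios", "data.frame")
  out
}

#' Label-permutation test for sex-chromosome DEG enrichment
#'
#' Tests whether per-chromosome DEG ratios are higher on sex chromosomes
#' than on autosomes. The statistic is mean(sex ratios) - mean(autosome
#' ratios); the null distribution permutes the sex/autosome labels across
#' chromosomes. The two-class comparison makes a label-permutation test on
#' the group-mean difference equivalent to the permutation linear-model
#' formulation. p = (1 + #{perm >= observed}) / (1 + n_perm) (one-sided,
#' add-one smoothed).
#'
#' @param ratios A `chrom_ratios` data.frame (or any data.frame with `ratio`
#'   and `class` columns).
#' @param n_perm Number of label permutations (default 10000; < 100 warns).
#' @param seed RNG seed.
#' @param alternative `"greater"` (sex > autosome, default) or `"two.sided"`.
#' @return list of class `perm_test`: `statistic`, `p_value`, `n_perm`,
#'   `seed`, `alternative`.
#' @export
permutation_enrichment_test <- function(ratios, n_perm = 10000, seed = 1,
                                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_that(all(c("ratio", "class") %in% names(ratios)),
             "ratios needs columns ratio and class")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value")
  r <- ratios$ratio
  is_sex <- ratios$class == "sex"
  k <- sum(is_sex); n <- length(r)
  check_that(k >= 1 && (n - k) >= 1,
             "degenerate input: need at least one sex chromosome and one autosome")
  obs <- mean(r[is_sex]) - mean(r[!is_sex])
  tot <- sum(r)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, k)
      s <- sum(r[idx])
      s / k - (tot - s) / (n - k)
    }, numeric(1))
  })
  ## tolerance so exact ties are counted despite floating-point noise
  tol <- 1e-12 * max(1, abs(obs))
  cnt <- if (alternative == "greater") sum(perm >= obs - tol) else
    sum(abs(perm) >= abs(obs) - tol)
  structure(list(statistic = obs, p_value = (1 + cnt) / (1 + n_perm),
                 n_perm = n_perm, seed = seed, alternative = alternative),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Label-permutation test (%s): statistic = %.4g, p = %.4g (%d permutations)\n",
              x$alternative, x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Dosage-effect classification of Z-linked male-biased DEGs
#'
#' On the avian Z chromosome (males ZZ, females ZW) a pure copy-number
#' (dosage) effect predicts roughly two-fold male-biased expression. DEGs
#' with `1 < |log2fc| <= 1.5` are classed `dosage`; `|log2fc| > 1.5` is
#' `exceeds_dosage`; genes with `|log2fc| > 2` (over four-fold) additionally
#' get the `strong_male_biased` flag.
#'
#' @param z_degs DEG table restricted to Z-linked male-biased DEGs, with
#'   columns `gene_id`, `log2fc`, and optionally `chromosome` (must be "Z").
#' @param dosage_band Numeric length-2: the (open, closed] band treated as a
#'   dosage effect. Default `c(1, 1.5)`.
#' @param strong_cut `strong_male_biased` threshold, strict (default 2).
#' @return data.frame: `gene_id`, `abs_log2fc`, `class`, `strong_male_biased`.
#' @export
classify_dosage <- function(z_degs, dosage_band = c(1, 1.5), strong_cut = 2) {
  check_that(all(c("gene_id", "log2fc") %in% names(z_degs)),
             "z_degs needs columns gene_id and log2fc")
  if (!is.null(z_degs$chromosome)) {
    bad <- z_degs$gene_id[z_degs$chromosome != "Z"]
    check_that(length(bad) == 0,
               paste("non-Z genes in dosage classification:", paste(bad, collapse = ", ")))
  }
  a <- abs(z_degs$log2fc)
  check_that(all(a > dosage_band[1]),
             sprintf("all genes must be DEGs with |log2fc| > %g", dosage_band[1]))
  cls <- ifelse(a <= dosage_band[2], "dosage", "exceeds_dosage")
  data.frame(gene_id = z_degs$gene_id, abs_log2fc = a, class = cls,
             strong_male_biased = a > strong_cut, stringsAsFactors = FALSE)
}
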