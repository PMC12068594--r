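## Cross-species comparison of binding-strength matrices on a phylogeny.

#' Align two binding-strength matrices into paired vectors
#'
#' Rows (TFs) are matched by name; only TFs shared by both matrices are
#' used (none shared is an error). Cells are kept when the gene is present
#' and annotated (non-NA) in BOTH species; everything else is dropped and
#' counted. Flattening order is TF-major, gene-minor over the sorted shared
#' TF and gene union, and is recorded in the result.
#'
#' @param reference,other Numeric TF x gene matrices (NA = unannotated), as
#'   produced by [binding_strength()] or [generate_species_set()].
#' @return list: `x`, `y` (paired numeric vectors), `cells` (data.frame of
#'   tf/gene per kept cell), `n_dropped`, `dropped` (data.frame of dropped
#'   cells with a reason).
#' @export
align_profiles <- function(reference, other) {
  tfs <- intersect(rownames(reference), rownames(other))
  check_that(length(tfs) > 0, "no shared TFs between the two matrices")
  tfs <- sort(tfs)
  genes <- sort(union(colnames(reference), colnames(other)))
  grid <- expand.grid(gene = genes, tf = tfs, stringsAsFactors = FALSE)[, c("tf", "gene")]
  val <- function(m, tf, gene) {
    if (!gene %in% colnames(m)) return(NA_real_)
    as.numeric(m[tf, gene])
  }
  x <- mapply(val, grid$tf, grid$gene, MoreArgs = list(m = reference))
  y <- mapply(val, grid$tf, grid$gene, MoreArgs = list(m = other))
  keep <- !is.na(x) & !is.na(y)
  dropped <- grid[!keep, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$reason <- ifelse(is.na(x[!keep]) & is.na(y[!keep]), "unannotated in both",
                             ifelse(is.na(x[!keep]), "unannotated in reference",
                                    "unannotated in other"))
  } else dropped$reason <- character(0)
  list(x = unname(x[keep]), y = unname(y[keep]),
       cells = grid[keep, , drop = FALSE],
       n_dropped = sum(!keep), dropped = dropped,
       order = "tf-major, gene-minor")
}

pcc_or_na <- function(x, y, min_cells = 3) {
  if (length(x) < min_cells) {
    return(list(pcc = NA_real_, n = length(x), note = sprintf("fewer than %d common cells", min_cells)))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(pcc = NA_real_, n = length(x), note = "constant vector"))
  }
  list(pcc = stats::cor(x, y), n = length(x), note = "")
}

#' Pearson correlation of each species' binding profile to a reference
#'
#' @param profiles Named list of TF x gene matrices (one per species).
#' @param reference_species Name of the reference species in `profiles`.
#' @param min_cells Minimum aligned cells for a defined PCC (default 3).
#' @return data.frame: `species`, `pcc`, `n_common_cells`, `note`. Undefined
#'   correlations are NA with the reason in `note`, never imputed.
#' @export
pcc_vs_reference <- function(profiles, reference_species, min_cells = 3) {
  check_that(reference_species %in% names(profiles),
             sprintf("reference species '%s' not in profiles", reference_species))
  ref <- profiles[[reference_species]]
  rows <- lapply(names(profiles), function(sp) {
    if (sp == reference_species) {
      n <- sum(!is.na(ref))
      return(data.frame(species = sp, pcc = 1, n_common_cells = n, note = "reference",
                        stringsAsFactors = FALSE))
    }
    al <- align_profiles(ref, profiles[[sp]])
    r <- pcc_or_na(al$x, al$y, min_cells)
    data.frame(species = sp, pcc = r$pcc, n_common_cells = r$n, note = r$note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' All-pairs Pearson correlations between species profiles
#'
#' @inheritParams pcc_vs_reference
#' @return Symmetric matrix of PCCs (diagonal 1, NA where undefined).
#' @export
pairwise_pcc <- function(profiles, min_cells = 3) {
  nm <- names(profiles)
  m <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  diag(m) <- 1
  if (length(nm) >= 2) {
    for (i in seq_len(length(nm) - 1)) {
      for (j in (i + 1):length(nm)) {
        al <- align_profiles(profiles[[nm[i]]], profiles[[nm[j]]])
        m[i, j] <- m[j, i] <- pcc_or_na(al$x, al$y, min_cells)$pcc
      }
    }
  }
  m
}

#' Patristic distances between the leaves of a phylogeny
#'
#' Branch-length distances via [ape::cophenetic.phylo()]. Trees without
#' branch lengths fall back to a topological distance (every edge length 1)
#' with a warning.
#'
#' @param tree An `ape::phylo` object or path/string of Newick.
#' @return Symmetric distance matrix over leaf names.
#' @export
patristic_distances <- function(tree) {
  tree <- as_phylo(tree)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using topological (unit-edge) distances")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  stats::cophenetic(tree)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("`tree` must be a phylo object, a Newick string, or a file path", call. = FALSE)
}

## Leaf pairs that are sisters (share an immediate parent node).
sister_pairs <- function(tree) {
  tree <- as_phylo(tree)
  tip_edges <- tree$edge[tree$edge[, 2] <= length(tree$tip.label), , drop = FALSE]
  by_parent <- split(tip_edges[, 2], tip_edges[, 1])
  pairs <- list()
  for (tips in by_parent) {
    if (length(tips) >= 2) {
      cmb <- utils::combn(sort(tree$tip.label[tips]), 2)
      for (k in seq_len(ncol(cmb))) pairs[[length(pairs) + 1L]] <- cmb[, k]
    }
  }
  pairs
}

## Theil-Sen line fit (median of pairwise slopes; median-based intercept).
theil_sen <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in seq_len(n - 1)) {
    dx <- x[(i + 1):n] - x[i]
    dy <- y[(i + 1):n] - y[i]
    ok <- dx != 0
    slopes <- c(slopes, dy[ok] / dx[ok])
  }
  b <- if (length(slopes)) stats::median(slopes) else 0
  a <- stats::median(y - b * x)
  list(intercept = a, slope = b)
}

#' Convergence report over a phylogeny
#'
#' Summarizes how similar each species' TF-by-gene binding profile is to a
#' reference species, in the light of phylogenetic distance and a binary
#' color phenotype. The report contains:
#'
#' * a per-species table of PCC to the reference, patristic distance to the
#'   reference, and phenotype;
#' * the Spearman rank correlation between PCC and patristic distance
#'   (negative under neutral Brownian divergence);
#' * `convergent_pairs`: non-sister species pairs whose mutual PCC is an
#'   outlier above the PCC-vs-distance trend (Theil-Sen fit over all pairs,
#'   residuals standardized by median/MAD; flagged when the robust z-score
#'   exceeds `flag_z`) — candidate convergently similar regulatory profiles;
#' * `signature`: TRUE when some phenotype-matched species lies farther from
#'   the reference yet has LOWER PCC than a phenotype-mismatched closer
#'   species — the pattern expected when a shared phenotype evolved through
#'   different regulatory routes (convergence rather than parallelism).
#'
#' @param profiles Named list of TF x gene matrices per species.
#' @param tree Phylogeny covering all species.
#' @param reference_species Reference species name.
#' @param phenotypes Named character vector (`"bright"`/`"dull"`) per species.
#' @param flag_z Robust z threshold for the convergent-pair flag (default 3.5).
#' @param min_cells Minimum aligned cells for a defined PCC.
#' @return list of class `convergence_report`.
#' @export
convergence_report <- function(profiles, tree, reference_species, phenotypes,
                               flag_z = 3.5, min_cells = 3) {
  tree <- as_phylo(tree)
  sp <- names(profiles)
  missing_tree <- setdiff(sp, tree$tip.label)
  check_that(length(missing_tree) == 0,
             paste("species missing from tree:", paste(missing_tree, collapse = ", ")))
  check_that(reference_species %in% sp, "reference species not in profiles")
  check_that(all(sp %in% names(phenotypes)), "phenotypes must cover all species")

  D <- patristic_distances(tree)
  tab <- pcc_vs_reference(profiles, reference_species, min_cells)
  tab$distance <- D[reference_species, tab$species]
  tab$phenotype <- unname(phenotypes[tab$species])

  others <- tab[tab$species != reference_species, , drop = FALSE]
  rho <- if (sum(stats::complete.cases(others[, c("pcc", "distance")])) >= 3) {
    suppressWarnings(stats::cor(others$pcc, others$distance, method = "spearman",
                                use = "complete.obs"))
  } else NA_real_

  ## all-pairs outlier analysis for convergent similarity
  P <- pairwise_pcc(profiles, min_cells)
  pairs <- t(utils::combn(sort(sp), 2))
  pd <- data.frame(a = pairs[, 1], b = pairs[, 2], stringsAsFactors = FALSE)
  pd$pcc <- P[cbind(pd$a, pd$b)]
  pd$distance <- D[cbind(pd$a, pd$b)]
  sis <- sister_pairs(tree)
  pd$sister <- mapply(function(a, b) {
    any(vapply(sis, function(p) all(p == c(a, b)), logical(1)))
  }, pd$a, pd$b)
  ok <- stats::complete.cases(pd[, c("pcc", "distance")])
  pd$resid <- NA_real_
  pd$robust_z <- NA_real_
  if (sum(ok) >= 4) {
    ## fit and flag on the Fisher z scale: differences between correlations
    ## near 1 are invisible on the raw PCC scale
    fz <- atanh(pmin(pmax(pd$pcc[ok], -1 + 1e-12), 1 - 1e-12))
    fit <- theil_sen(pd$distance[ok], fz)
    res <- fz - (fit$intercept + fit$slope * pd$distance[ok])
    s <- stats::mad(res)
    if (s == 0) s <- .Machine$double.eps
    pd$resid[ok] <- res
    pd$robust_z[ok] <- (res - stats::median(res)) / s
  }
  pd$flagged <- !pd$sister & !is.na(pd$robust_z) & pd$robust_z > flag_z
  convergent_pairs <- pd[pd$flagged, c("a", "b", "pcc", "distance", "robust_z")]

  ## the descriptive signature: phenotype-matched but regulatory-dissimilar
  ref_ph <- phenotypes[[reference_species]]
  matched <- others[others$phenotype == ref_ph, , drop = FALSE]
  mismatched <- others[others$phenotype != ref_ph, , drop = FALSE]
  witnesses <- NULL
  if (nrow(matched) && nrow(mismatched)) {
    for (i in seq_len(nrow(matched))) {
      hit <- mismatched$distance < matched$distance[i] & mismatched$pcc > matched$pcc[i]
      hit[is.na(hit)] <- FALSE
      if (any(hit)) {
        witnesses <- rbind(witnesses, data.frame(
          matched_species = matched$species[i],
          mismatched_species = mismatched$species[hit][1],
          stringsAsFactors = FALSE))
      }
    }
  }

  structure(list(
    reference = reference_species,
    species = tab,
    pcc_distance_spearman = rho,
    pairs = pd,
    convergent_pairs = convergent_pairs,
    signature = !is.null(witnesses),
    signature_witnesses = witnesses,
    flag_z = flag_z
  ), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> reference: %s\n", x$reference))
  print(x$species[, c("species", "pcc", "distance", "phenotype")], row.names = FALSE)
  cat(sprintf("Spearman rho(PCC, patristic distance) = %.3f\n", x$pcc_distance_spearman))
  if (nrow(x$convergent_pairs)) {
    cat("Convergent-similarity outlier pair(s):\n")
    print(x$convergent_pairs, row.names = FALSE)
  } else cat("No convergent-similarity outlier pairs flagged.\n")
  cat(sprintf("Phenotype-discordance signature: %s\n", x$signature))
  invisible(x)
}
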