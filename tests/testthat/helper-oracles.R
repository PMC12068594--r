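# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use different mechanics from the production code
# (explicit per-offset loops, full enumeration, Lance-Williams recursion).

DELTA <- 1e-4  # score discretization step, must match the package's

# Explicit per-offset, per-strand rescan of one promoter. Scores are summed
# base by base from the discretized log-odds matrix; the reverse strand is
# handled by reverse-complementing the window substring (the production
# code instead reverse-complements the matrix).
naive_scan <- function(seq, x, alpha_raw, background = rep(0.25, 4)) {
  li <- round(pwm_log_odds(x, background) / DELTA)
  li[pwm_probs(x) == 0] <- -Inf
  L <- ncol(x$matrix)
  chars <- strsplit(toupper(seq), "")[[1]]
  n_off <- length(chars) - L + 1
  if (n_off < 1) return(data.frame(offset = integer(0), strand = character(0),
                                   score = numeric(0), pvalue = numeric(0)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  score_window <- function(w) {
    s <- 0
    for (j in seq_len(L)) {
      b <- match(w[j], c("A", "C", "G", "T"))
      if (is.na(b)) return(-Inf)
      s <- s + li[b, j]
      if (!is.finite(s)) return(-Inf)
    }
    s
  }
  rows <- list()
  for (o in seq_len(n_off)) {
    w <- chars[o:(o + L - 1)]
    s_f <- score_window(w)
    wrc <- rev(unname(comp[w]))
    wrc[is.na(wrc)] <- "N"
    s_r <- score_window(wrc)
    rows[[length(rows) + 1]] <- data.frame(
      offset = o - 1L, strand = c("+", "-"), score = c(s_f, s_r) * DELTA)
  }
  out <- do.call(rbind, rows)
  out$pvalue <- score_pvalue(x, out$score, background)
  out <- out[out$pvalue <= alpha_raw, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exhaustive p-value: enumerate all 4^L windows, discretize each window's
# score identically, and sum background probabilities of windows scoring
# at or above the target.
exhaustive_pvalue <- function(x, scores, background = rep(0.25, 4)) {
  li <- round(pwm_log_odds(x, background) / DELTA)
  li[pwm_probs(x) == 0] <- -Inf
  L <- ncol(x$matrix)
  grids <- expand.grid(rep(list(1:4), L))
  wscore <- rep(0, nrow(grids))
  wprob <- rep(1, nrow(grids))
  for (j in seq_len(L)) {
    wscore <- wscore + li[cbind(grids[[j]], j)]
    wprob <- wprob * background[grids[[j]]]
  }
  vapply(scores, function(s) {
    if (!is.finite(s)) return(1)
    sum(wprob[is.finite(wscore) & wscore >= round(s / DELTA)])
  }, numeric(1))
}

# Row-by-row re-evaluation of the DEG thresholds.
brute_deg_filter <- function(tab, lfc_cut = 1, alpha = 0.05) {
  keep <- character(0)
  for (i in seq_len(nrow(tab))) {
    lfc <- tab$log2fc[i]; padj <- tab$padj[i]
    if (!is.na(lfc) && !is.na(padj) && (lfc > lfc_cut || lfc < -lfc_cut) && padj < alpha) {
      keep <- c(keep, tab$gene_id[i])
    }
  }
  keep
}

# Ward.D2 agglomeration by direct Lance-Williams recursion on Euclidean
# distances, for small n. Returns the sequence of merge heights.
brute_ward_d2_heights <- function(x) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      a <- active[i]; b <- active[j]
      if (d[a, b] < bestd) { bestd <- d[a, b]; best <- c(b, a) }
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, bestd)
    for (k in setdiff(active, c(a, b))) {
      na <- size[a]; nb <- size[b]; nk <- size[k]
      d[a, k] <- d[k, a] <- sqrt(
        ((na + nk) * d[a, k]^2 + (nb + nk) * d[b, k]^2 - nk * d[a, b]^2) /
          (na + nb + nk))
    }
    size[a] <- size[a] + size[b]
    active <- setdiff(active, b)
  }
  heights
}

# A random count PWM for property tests (modest counts keep the DP small).
random_pwm <- function(width, tf_id = "rnd", max_count = 12, pseudocount = 0.5) {
  m <- matrix(sample(0:max_count, 4 * width, replace = TRUE), 4, width)
  pwm(m, tf_id = tf_id, pseudocount = pseudocount)
}

random_dna <- function(n, p = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}
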