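## Position weight matrices: construction, parsing, log-odds scoring and
## exact background p-values by dynamic programming.

## Score discretization step (bits). The DP works on integer multiples of
## this step; scanning uses the same discretized matrix so that reported
## scores and p-values are exactly consistent.
SCORE_DELTA <- 1e-4

#' Construct a position weight matrix
#'
#' @param counts 4 x L numeric matrix of per-position base counts (or
#'   probabilities), rows in A, C, G, T order. An L x 4 matrix with column
#'   names A/C/G/T is transposed automatically.
#' @param tf_id Transcription-factor identifier.
#' @param pseudocount Non-negative value added to every cell before
#'   normalization: p(i,b) = (c(i,b) + k) / (N(i) + 4k). Default 0.1.
#' @param background Base composition used for log-odds and p-values;
#'   normalized to sum to 1. Default uniform.
#' @return Object of class `pwm`.
#' @export
pwm <- function(counts, tf_id = "TF", pseudocount = 0.1,
                background = rep(0.25, 4)) {
  m <- as.matrix(counts)
  if (ncol(m) == 4 && nrow(m) != 4) m <- t(m)
  if (!is.null(rownames(m)) && all(DNA_BASES %in% rownames(m))) m <- m[DNA_BASES, , drop = FALSE]
  check_that(nrow(m) == 4, "PWM must have 4 base rows (A, C, G, T)")
  check_that(all(is.finite(m)) && all(m >= 0), "PWM entries must be non-negative and finite")
  check_that(is.numeric(pseudocount) && length(pseudocount) == 1 && pseudocount >= 0,
             "pseudocount must be a single non-negative number")
  check_that(length(background) == 4 && all(background > 0),
             "background must be a strictly positive 4-vector")
  if (pseudocount == 0 && any(colSums(m) == 0)) {
    stop("PWM has an all-zero column and no pseudocount", call. = FALSE)
  }
  rownames(m) <- DNA_BASES
  colnames(m) <- NULL
  structure(list(tf_id = tf_id, matrix = m, pseudocount = pseudocount,
                 background = background / sum(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  length %d  pseudocount %g\n", x$tf_id, ncol(x$matrix),
              x$pseudocount))
  print(round(pwm_probs(x), 3))
  invisible(x)
}

#' Pseudocount-regularized probability matrix of a PWM
#' @param x A `pwm`.
#' @return 4 x L probability matrix (columns sum to 1).
#' @export
pwm_probs <- function(x) {
  stopifnot(inherits(x, "pwm"))
  k <- x$pseudocount
  sweep(x$matrix + k, 2, colSums(x$matrix) + 4 * k, "/")
}

#' Log-odds score matrix in bits
#'
#' s(i, b) = log2( p'(i, b) / background(b) ) with p' the
#' pseudocount-regularized probability. Cells with zero probability score
#' -Inf and can never be part of a hit.
#' @param x A `pwm`.
#' @param background Optional override of the PWM's background.
#' @return 4 x L numeric matrix of bit scores.
#' @export
pwm_log_odds <- function(x, background = NULL) {
  stopifnot(inherits(x, "pwm"))
  bg <- if (is.null(background)) x$background else background / sum(background)
  check_that(all(bg > 0), "background must be strictly positive")
  log2(pwm_probs(x) / bg)
}

#' Consensus sequence of a PWM (argmax base per column; ties to A<C<G<T)
#' @param x A `pwm`.
#' @return Character string of length `ncol(x$matrix)`.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(pwm_probs(x), 2, which.max)], collapse = "")
}

## Reverse-complement of a log-odds (or count) matrix: complement the base
## rows and reverse the positions.
revcomp_matrix <- function(m) m[4:1, rev(seq_len(ncol(m))), drop = FALSE]

## Discretize a log-odds matrix to integer units of SCORE_DELTA.
## -Inf cells stay -Inf.
discretize_lo <- function(lo) {
  d <- round(lo / SCORE_DELTA)
  d[is.infinite(lo) & lo < 0] <- -Inf
  d
}

#' Parse motif files in JASPAR or MEME minimal format
#'
#' JASPAR records look like `>ID name` followed by four `A [ ... ]` count
#' rows (bare 4-row blocks are also accepted). MEME minimal format supplies
#' `MOTIF` blocks with a `letter-probability matrix` whose probabilities are
#' rescaled by `nsites` (when present) so that an equivalent JASPAR count
#' matrix yields an identical PWM.
#'
#' @param path File path (or a character vector of lines).
#' @param dialect `"auto"` (default), `"jaspar"` or `"meme"`.
#' @param pseudocount,background Passed to [pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_motifs <- function(path, dialect = c("auto", "jaspar", "meme"),
                        pseudocount = 0.1, background = rep(0.25, 4)) {
  dialect <- match.arg(dialect)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  if (dialect == "auto") {
    dialect <- if (any(grepl("^MOTIF\\b", lines)) ||
                   any(grepl("letter-probability matrix", lines))) "meme" else "jaspar"
  }
  motifs <- if (dialect == "jaspar") {
    parse_jaspar(lines, pseudocount, background)
  } else {
    parse_meme(lines, pseudocount, background)
  }
  check_that(length(motifs) > 0, "no motifs found in input")
  stats::setNames(motifs, vapply(motifs, function(m) m$tf_id, character(1)))
}

#' Load a single PWM from a motif file
#'
#' Convenience wrapper around [read_motifs()] for single-motif files.
#' @inheritParams read_motifs
#' @return A `pwm` object (the first motif in the file).
#' @export
load_pwm <- function(path, dialect = c("auto", "jaspar", "meme"),
                     pseudocount = 0.1, background = rep(0.25, 4)) {
  read_motifs(path, dialect, pseudocount, background)[[1]]
}

parse_jaspar <- function(lines, pseudocount, background) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  parse_rows <- function(rows, id) {
    vals <- lapply(rows, function(r) {
      r <- sub("^[ACGTacgt]\\s*", "", r)
      r <- gsub("\\[|\\]", " ", r)
      v <- suppressWarnings(as.numeric(strsplit(trimws(r), "\\s+")[[1]]))
      check_that(!anyNA(v), sprintf("motif '%s': non-numeric matrix entry", id))
      v
    })
    lens <- vapply(vals, length, integer(1))
    check_that(length(unique(lens)) == 1L, sprintf("motif '%s': ragged matrix rows", id))
    m <- do.call(rbind, vals)
    check_that(all(m >= 0), sprintf("motif '%s': negative counts", id))
    letters_given <- grepl("^[ACGTacgt]", rows)
    if (all(letters_given)) {
      ord <- match(toupper(substr(rows, 1, 1)), DNA_BASES)
      check_that(!anyNA(ord) && length(unique(ord)) == 4,
                 sprintf("motif '%s': expected one row each for A, C, G, T", id))
      m <- m[order(ord), , drop = FALSE]
    }
    pwm(m, tf_id = id, pseudocount = pseudocount, background = background)
  }
  if (length(hdr) == 0) {
    check_that(length(lines) %% 4 == 0, "bare JASPAR matrix must have 4 rows per motif")
    idx <- split(seq_along(lines), (seq_along(lines) - 1) %/% 4)
    return(lapply(seq_along(idx), function(i) parse_rows(lines[idx[[i]]], paste0("motif", i))))
  }
  bounds <- c(hdr, length(lines) + 1L)
  lapply(seq_along(hdr), function(i) {
    id <- strsplit(sub("^>\\s*", "", lines[hdr[i]]), "\\s+")[[1]][1]
    rows <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    check_that(length(rows) == 4, sprintf("motif '%s': expected 4 matrix rows, got %d",
                                          id, length(rows)))
    parse_rows(rows, id)
  })
}

parse_meme <- function(lines, pseudocount, background) {
  lines <- trimws(lines)
  mot <- grep("^MOTIF\\b", lines)
  check_that(length(mot) > 0, "no MOTIF blocks in MEME input")
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) && bgl[1] < mot[1]) {
    v <- suppressWarnings(as.numeric(strsplit(lines[bgl[1] + 1L], "\\s+")[[1]]))
    v <- v[!is.na(v)]
    if (length(v) == 4) background <- v
  }
  lapply(mot, function(i) {
    id <- strsplit(lines[i], "\\s+")[[1]][2]
    j <- i + 1L
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) j <- j + 1L
    check_that(j <= length(lines), sprintf("motif '%s': no letter-probability matrix", id))
    w <- suppressWarnings(as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[j])))
    ns <- suppressWarnings(as.numeric(sub(".*\\bnsites=\\s*([0-9.]+).*", "\\1", lines[j])))
    rows <- lines[(j + 1L):(j + w)]
    m <- do.call(rbind, lapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(strsplit(r, "\\s+")[[1]]))
      check_that(length(v) == 4 && !anyNA(v),
                 sprintf("motif '%s': bad letter-probability row", id))
      v
    }))
    if (is.finite(ns) && ns > 0) m <- m * ns
    pwm(t(m), tf_id = id, pseudocount = pseudocount, background = background)
  })
}

## Exact distribution of the discretized log-odds score of a random window
## drawn from `bg`. Returns list(lo = minimum integer score, tail = vector
## with tail[k - lo + 1] = P[S_int >= k]). Mass on windows containing a
## -Inf-scoring base is excluded from the finite distribution (their score
## is -Inf, below every finite threshold). The convolution runs in C
## (.score_dp); results are memoized per (matrix, background).
score_tail_dist <- function(li, bg) {
  key <- paste(c(round(bg, 12), li), collapse = ",")
  hit <- .dist_cache[[key]]
  if (!is.null(hit)) return(hit)
  L <- ncol(li)
  fin <- is.finite(li)
  check_that(all(colSums(fin) > 0), "PWM column with no finite score")
  mins <- vapply(seq_len(L), function(j) min(li[fin[, j], j]), numeric(1))
  off <- matrix(-1L, 4, L)
  off[fin] <- as.integer(li[fin] - rep(mins, each = 4)[fin])
  d <- .score_dp(off, bg)
  res <- list(lo = sum(mins), tail = pmin(1, rev(cumsum(rev(d)))))
  if (length(.dist_cache) > 256L) rm(list = ls(.dist_cache), envir = .dist_cache)
  .dist_cache[[key]] <- res
  res
}

.dist_cache <- new.env(parent = emptyenv())

## Pure-R reference implementation of the same convolution (kept as an
## independent route for property tests; not used in production scans).
score_tail_dist_r <- function(li, bg) {
  L <- ncol(li)
  fin <- is.finite(li)
  check_that(all(colSums(fin) > 0), "PWM column with no finite score")
  mins <- vapply(seq_len(L), function(j) min(li[fin[, j], j]), numeric(1))
  maxs <- vapply(seq_len(L), function(j) max(li[fin[, j], j]), numeric(1))
  d <- 1
  for (j in seq_len(L)) {
    new_len <- length(d) + as.integer(maxs[j] - mins[j])
    nd <- numeric(new_len)
    for (b in 1:4) {
      if (!fin[b, j]) next
      o <- as.integer(li[b, j] - mins[j])
      idx <- (1L + o):(length(d) + o)
      nd[idx] <- nd[idx] + bg[b] * d
    }
    d <- nd
  }
  list(lo = sum(mins), tail = pmin(1, rev(cumsum(rev(d)))))
}

## Look up P[S >= s_int] in a tail distribution; -Inf scores get p = 1.
tail_pvalue <- function(dist, s_int) {
  p <- numeric(length(s_int))
  neg <- !is.finite(s_int)
  p[neg] <- 1
  k <- s_int[!neg] - dist$lo + 1
  pv <- ifelse(k <= 0, if (length(dist$tail)) dist$tail[1] else 1,
               ifelse(k > length(dist$tail), 0, dist$tail[pmax(1, pmin(k, length(dist$tail)))]))
  p[!neg] <- pv
  p
}

#' Exact p-value of a PWM score under the background model
#'
#' Computes P[S >= score] for the log-odds score of a random window drawn
#' i.i.d. from the background, by dynamic programming over the per-position
#' score distribution discretized at 1e-4 bits.
#'
#' @param x A `pwm`.
#' @param score Numeric vector of scores in bits (`-Inf` allowed, p = 1).
#' @param background Optional background override.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
score_pvalue <- function(x, score, background = NULL) {
  stopifnot(inherits(x, "pwm"))
  bg <- if (is.null(background)) x$background else background / sum(background)
  li <- discretize_lo(pwm_log_odds(x, bg))
  dist <- score_tail_dist(li, bg)
  s_int <- ifelse(is.finite(score), round(score / SCORE_DELTA), -Inf)
  tail_pvalue(dist, s_int)
}
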