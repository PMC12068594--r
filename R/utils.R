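## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that generators are reproducible
#' without clobbering the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stream-specific child seed from a master seed, staying < 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + stream * 104729) %% 2147483647
}

#' Encode a DNA string as integer codes A=1, C=2, G=3, T=4, other=NA
#' @noRd
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  m <- match(v, DNA_BASES)
  m
}

## Reverse complement of a plain character string; non-ACGT becomes N.
revcomp_chr <- function(x) {
  v <- rev(strsplit(chartr("ACGTacgt", "TGCATGCA", x), "", fixed = TRUE)[[1]])
  v[!v %in% c(DNA_BASES, tolower(DNA_BASES))] <- "N"
  paste(toupper(v), collapse = "")
}

## Normalize IUPAC ambiguity codes (anything not ACGT) to N.
normalize_ambiguity <- function(x) {
  gsub("[^ACGT]", "N", toupper(x))
}

## Coerce a genome given as DNAStringSet or named character to named character.
as_genome_chr <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    s <- as.character(genome)
    names(s) <- names(genome)
    return(s)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named", call. = FALSE)
    return(genome)
  }
  stop("`genome` must be a named character vector or a DNAStringSet", call. = FALSE)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

## Stop with a consistent input-error message.
check_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
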