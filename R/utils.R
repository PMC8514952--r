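#' @importFrom rlang %||% .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_dbl map_int map_lgl pmap list_rbind
#' @importFrom stringr str_detect str_match str_split str_sub str_to_upper
NULL

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp_cache <- new.env(parent = emptyenv())

#' Reverse complement of a DNA string
#'
#' The most recent large input is memoised, since pipeline stages repeatedly
#' mirror the same locus.
#'
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  if (nchar(x) > 10000L && identical(.revcomp_cache$input, x)) {
    return(.revcomp_cache$output)
  }
  chars <- rev(strsplit(x, "", fixed = TRUE)[[1]])
  out <- paste(COMPLEMENT[chars], collapse = "")
  if (nchar(x) > 10000L) {
    .revcomp_cache$input <- x
    .revcomp_cache$output <- out
  }
  out
}

# vector of single characters for a sequence
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# random background DNA with a given GC fraction (uses current RNG stream)
random_dna <- function(n, gc = 0.42) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# translate an in-frame DNA string; trailing partial codon dropped; stops as
# "*", codons with ambiguous bases as "X" (standard genetic code lookup)
translate_dna <- local({
  gc_map <- NULL
  function(x) {
    if (is.null(gc_map)) gc_map <<- Biostrings::GENETIC_CODE
    n <- 3L * (nchar(x) %/% 3L)
    if (n == 0L) return("")
    starts <- seq.int(1L, n, by = 3L)
    aa <- gc_map[substring(x, starts, starts + 2L)]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
})

has_stop <- function(aa) grepl("*", aa, fixed = TRUE)

# 1-based inclusive interval as a two-element integer vector helper
iv <- function(start, end) c(start = as.integer(start), end = as.integer(end))

# mirror a 1-based inclusive interval on a sequence of length len
mirror_interval <- function(start, end, len) {
  c(start = len - as.integer(end) + 1L, end = len - as.integer(start) + 1L)
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(seq_chars(a) != seq_chars(b))
}

# fraction of G in a DNA string
g_fraction <- function(x) {
  if (nchar(x) == 0L) return(NA_real_)
  mean(seq_chars(x) == "G")
}

# run code with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}
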