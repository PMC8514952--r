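# Independent oracles and fixture builders, deliberately written with plain
# string operations so they share no code path with the implementation.

# reverse complement via chartr, independent of trlocus::revcomp
rc_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

ham_oracle <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# naive double-loop RSS scan: every window x direct Hamming distance
scan_rss_oracle <- function(seq, spacer, layout, max_mm) {
  hep <- "CACAGTG"; non <- "ACAAAAACC"
  w <- 16L + spacer
  n <- nchar(seq)
  rows <- list()
  if (n >= w) {
    for (s in seq_len(n - w + 1L)) {
      win <- substr(seq, s, s + w - 1L)
      if (grepl("N", win, fixed = TRUE)) next
      canon <- if (layout == "heptamer_first") win else rc_oracle(win)
      h <- substr(canon, 1L, 7L)
      m <- substr(canon, w - 8L, w)
      hm <- ham_oracle(h, hep)
      nm <- ham_oracle(m, non)
      if (hm + nm <= max_mm) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, heptamer_mismatches = hm, nonamer_mismatches = nm,
          total_mismatches = hm + nm
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(start = integer(), heptamer_mismatches = integer(),
                      nonamer_mismatches = integer(),
                      total_mismatches = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$total_mismatches, out$start), , drop = FALSE]
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# canonical RSS window in gene-strand orientation for a layout
rss_window_fixture <- function(spacer, layout, heptamer = "CACAGTG",
                               nonamer = "ACAAAAACC", spacer_seq = NULL) {
  if (is.null(spacer_seq)) spacer_seq <- rand_dna(spacer)
  canon <- paste0(heptamer, spacer_seq, nonamer)
  if (layout == "heptamer_first") canon else rc_oracle(canon)
}

# mutate k distinct positions of a string (never to the same base)
mutate_positions <- function(x, pos) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  paste(chars, collapse = "")
}
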