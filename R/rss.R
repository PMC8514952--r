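RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER  <- "ACAAAAACC"

#' Recombination signal sequence motif
#'
#' An RSS is a conserved heptamer (`CACAGTG`) and nonamer (`ACAAAAACC`)
#' separated by a 12-bp or 23-bp spacer. Recombination pairs a 12-RSS with a
#' 23-RSS (the 12/23 rule). On the strand of the gene it flanks, a 3' RSS
#' (V gene, D gene 3' side) reads heptamer-spacer-nonamer
#' (`layout = "heptamer_first"`); a 5' RSS (J gene, D gene 5' side) reads
#' nonamer-spacer-heptamer, with every element reverse-complemented
#' (`layout = "nonamer_first"`), so that the heptamer always abuts the coding
#' edge.
#'
#' @param spacer spacer length, 12 or 23.
#' @param layout `"heptamer_first"` (3' RSS) or `"nonamer_first"` (5' RSS).
#' @param heptamer,nonamer canonical motifs; defaults are the classic ones.
#' @return an object of class `rss_motif`.
#' @export
rss_motif <- function(spacer, layout = c("heptamer_first", "nonamer_first"),
                      heptamer = RSS_HEPTAMER, nonamer = RSS_NONAMER) {
  layout <- match.arg(layout)
  if (!spacer %in% c(12L, 23L)) stop("spacer length must be 12 or 23")
  if (nchar(heptamer) != 7L) stop("heptamer must be 7 nt")
  if (nchar(nonamer) != 9L) stop("nonamer must be 9 nt")
  structure(
    list(heptamer = heptamer, nonamer = nonamer,
         spacer = as.integer(spacer), layout = layout),
    class = "rss_motif"
  )
}

#' @export
print.rss_motif <- function(x, ...) {
  cat(sprintf("<rss_motif> %d-RSS, %s (%s / %d-nt spacer / %s)\n",
              x$spacer, x$layout, x$heptamer, x$spacer, x$nonamer))
  invisible(x)
}

# The four layouts the pipeline uses, keyed by segment edge.
#' Standard RSS motifs by segment edge
#'
#' Convenience constructors for the four arrangements used in annotation:
#' `v3` (23-RSS, 3' of V), `j5` (12-RSS, 5' of J), `d5` (12-RSS, 5' of D) and
#' `d3` (23-RSS, 3' of D).
#'
#' @param edge one of `"v3"`, `"j5"`, `"d5"`, `"d3"`.
#' @return an `rss_motif`.
#' @export
standard_rss_motif <- function(edge = c("v3", "j5", "d5", "d3")) {
  edge <- match.arg(edge)
  switch(edge,
    v3 = rss_motif(23L, "heptamer_first"),
    j5 = rss_motif(12L, "nonamer_first"),
    d5 = rss_motif(12L, "nonamer_first"),
    d3 = rss_motif(23L, "heptamer_first")
  )
}

rss_window_width <- function(motif, deviation = 0L) {
  7L + motif$spacer + as.integer(deviation) + 9L
}

# Per-window-position expected characters (NA over the spacer) plus the
# indices holding heptamer and nonamer, in canonical-orientation order.
rss_layout_map <- function(motif, deviation = 0L) {
  w <- rss_window_width(motif, deviation)
  hep <- seq_chars(motif$heptamer)
  non <- seq_chars(motif$nonamer)
  if (motif$layout == "heptamer_first") {
    hep_idx <- 1:7                       # canonical positions 1..7
    non_idx <- (w - 8L):w                # canonical positions 1..9
    hep_exp <- hep
    non_exp <- non
  } else {
    # window = revcomp(nonamer) + spacer + revcomp(heptamer); reading the
    # window backwards on the other strand restores canonical orientation
    hep_idx <- w:(w - 6L)                # canonical position 1 at window end
    non_idx <- 9:1
    hep_exp <- COMPLEMENT[hep]           # expected char at hep_idx[k] for canonical pos k
    non_exp <- COMPLEMENT[non]
  }
  list(width = w, hep_idx = hep_idx, non_idx = non_idx,
       hep_exp = unname(hep_exp), non_exp = unname(non_exp))
}

# Extract canonical-orientation element sequences from a window string.
rss_elements <- function(window, motif, deviation = 0L) {
  w <- nchar(window)
  sp <- motif$spacer + deviation
  if (motif$layout == "heptamer_first") {
    list(heptamer = substr(window, 1L, 7L),
         spacer = substr(window, 8L, 7L + sp),
         nonamer = substr(window, 8L + sp, w))
  } else {
    rc <- revcomp(window)
    list(heptamer = substr(rc, 1L, 7L),
         spacer = substr(rc, 8L, 7L + sp),
         nonamer = substr(rc, 8L + sp, w))
  }
}

#' Score one candidate RSS window
#'
#' Counts substitutions (Hamming distance, no indels) of the observed heptamer
#' and nonamer against the canonical motifs, orientation handled per the motif
#' layout. The window is rejected when the total mutation count exceeds
#' `max_mismatches`, when the heptamer core (`CAC`, canonical positions 1-3)
#' is required but broken, when the window length implies a spacer deviation
#' beyond `spacer_tol`, or when it contains an ambiguous base.
#'
#' @param window DNA string of length `7 + spacer + 9` (+/- `spacer_tol`).
#' @param motif an [rss_motif()].
#' @param max_mismatches maximum accepted total mutation count.
#' @param require_core require intact `CAC` heptamer core.
#' @param spacer_tol allowed spacer-length deviation (0 or 1).
#' @return one-row tibble: element sequences (canonical orientation), per-element
#'   and total mismatch counts, `spacer_deviation`, `accepted`, `reason`.
#' @export
score_rss <- function(window, motif, max_mismatches = 6L,
                      require_core = TRUE, spacer_tol = 0L) {
  stopifnot(inherits(motif, "rss_motif"))
  deviation <- nchar(window) - rss_window_width(motif, 0L)
  if (abs(deviation) > spacer_tol) {
    return(tibble(
      heptamer_seq = NA_character_, spacer_seq = NA_character_,
      nonamer_seq = NA_character_, heptamer_mismatches = NA_integer_,
      nonamer_mismatches = NA_integer_, total_mismatches = NA_integer_,
      spacer_deviation = as.integer(deviation),
      accepted = FALSE, reason = "spacer length"
    ))
  }
  el <- rss_elements(window, motif, deviation)
  if (grepl("N", window, fixed = TRUE)) {
    return(tibble(
      heptamer_seq = el$heptamer, spacer_seq = el$spacer, nonamer_seq = el$nonamer,
      heptamer_mismatches = NA_integer_, nonamer_mismatches = NA_integer_,
      total_mismatches = NA_integer_, spacer_deviation = as.integer(deviation),
      accepted = FALSE, reason = "ambiguous base"
    ))
  }
  hm <- hamming(el$heptamer, motif$heptamer)
  nm <- hamming(el$nonamer, motif$nonamer)
  core_ok <- substr(el$heptamer, 1L, 3L) == substr(motif$heptamer, 1L, 3L)
  accepted <- TRUE
  reason <- NA_character_
  if (hm + nm > max_mismatches) {
    accepted <- FALSE; reason <- "too many mismatches"
  } else if (require_core && !core_ok) {
    accepted <- FALSE; reason <- "heptamer core"
  }
  tibble(
    heptamer_seq = el$heptamer, spacer_seq = el$spacer, nonamer_seq = el$nonamer,
    heptamer_mismatches = as.integer(hm), nonamer_mismatches = as.integer(nm),
    total_mismatches = as.integer(hm + nm),
    spacer_deviation = as.integer(deviation),
    accepted = accepted, reason = reason
  )
}

#' Scan a sequence exhaustively for RSS hits
#'
#' Slides the RSS window over every start position (plus every allowed spacer
#' deviation) and keeps windows whose total mutation count is at most
#' `max_mismatches` (and, optionally, whose heptamer core is intact). Windows
#' containing `N` are discarded. Hits are returned sorted by
#' (total mismatches, position); overlapping hits are not deduplicated.
#'
#' @param seq DNA string to scan.
#' @param motif an [rss_motif()].
#' @param max_mismatches maximum total mutation count to report.
#' @param require_core require intact `CAC` heptamer core.
#' @param spacer_tol allowed spacer-length deviation.
#' @return tibble of hits: `start`, `end` (1-based inclusive window span),
#'   element sequences, mismatch counts, `spacer_deviation`.
#' @export
scan_rss <- function(seq, motif, max_mismatches = 6L,
                     require_core = FALSE, spacer_tol = 0L) {
  stopifnot(inherits(motif, "rss_motif"))
  chars <- seq_chars(seq)
  n <- length(chars)
  is_n <- chars == "N"
  out <- list()
  for (deviation in seq.int(-spacer_tol, spacer_tol)) {
    lay <- rss_layout_map(motif, deviation)
    w <- lay$width
    if (n < w) next
    starts <- seq_len(n - w + 1L)
    hep_mm <- integer(length(starts))
    non_mm <- integer(length(starts))
    for (k in seq_along(lay$hep_idx)) {
      hep_mm <- hep_mm + (chars[starts + lay$hep_idx[k] - 1L] != lay$hep_exp[k])
    }
    for (k in seq_along(lay$non_idx)) {
      non_mm <- non_mm + (chars[starts + lay$non_idx[k] - 1L] != lay$non_exp[k])
    }
    # windows containing any ambiguous base
    ncum <- c(0L, cumsum(is_n))
    n_in_window <- ncum[starts + w] - ncum[starts]
    keep <- (hep_mm + non_mm <= max_mismatches) & n_in_window == 0L
    if (require_core) {
      core_pos <- if (motif$layout == "heptamer_first") lay$hep_idx[1:3] else lay$hep_idx[1:3]
      core_ok <- rep(TRUE, length(starts))
      for (k in 1:3) {
        core_ok <- core_ok & (chars[starts + lay$hep_idx[k] - 1L] == lay$hep_exp[k])
      }
      keep <- keep & core_ok
    }
    if (!any(keep)) next
    ks <- starts[keep]
    windows <- substring(seq, ks, ks + w - 1L)
    els <- map(seq_along(ks), function(i) rss_elements(windows[i], motif, deviation))
    out[[length(out) + 1L]] <- tibble(
      start = ks, end = ks + w - 1L,
      heptamer_seq = map_chr(els, "heptamer"),
      spacer_seq = map_chr(els, "spacer"),
      nonamer_seq = map_chr(els, "nonamer"),
      heptamer_mismatches = hep_mm[keep],
      nonamer_mismatches = non_mm[keep],
      total_mismatches = hep_mm[keep] + non_mm[keep],
      spacer_deviation = as.integer(deviation)
    )
  }
  if (length(out) == 0L) {
    return(tibble(
      start = integer(), end = integer(), heptamer_seq = character(),
      spacer_seq = character(), nonamer_seq = character(),
      heptamer_mismatches = integer(), nonamer_mismatches = integer(),
      total_mismatches = integer(), spacer_deviation = integer()
    ))
  }
  arrange(list_rbind(out), .data$total_mismatches, .data$start)
}

#' Build a position weight matrix from RSS hits
#'
#' Per-position relative nucleotide frequencies over the heptamers or nonamers
#' of a hit table (rejected hits, i.e. rows with `accepted == FALSE`, are
#' excluded when an `accepted` column is present).
#'
#' @param hits tibble with `heptamer_seq` / `nonamer_seq` columns.
#' @param element `"heptamer"` or `"nonamer"`.
#' @return a 4 x width numeric matrix (rows A, C, G, T; columns positions),
#'   class `rss_pwm`; every column sums to 1.
#' @export
build_pwm <- function(hits, element = c("heptamer", "nonamer")) {
  element <- match.arg(element)
  if ("accepted" %in% names(hits)) hits <- filter(hits, .data$accepted)
  seqs <- hits[[paste0(element, "_seq")]]
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0L) stop("no hits to build a PWM from")
  width <- if (element == "heptamer") 7L else 9L
  stopifnot(all(nchar(seqs) == width))
  m <- matrix(0, nrow = 4L, ncol = width, dimnames = list(DNA_BASES, NULL))
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  for (j in seq_len(width)) {
    tab <- table(factor(chars[, j], levels = DNA_BASES))
    m[, j] <- as.numeric(tab) / length(seqs)
  }
  structure(m, element = element, n = length(seqs), class = c("rss_pwm", "matrix"))
}

#' Export a PWM as a tab-delimited matrix
#'
#' Rows A, C, G, T; columns positions. Suitable for sequence-logo rendering.
#'
#' @param pwm an [build_pwm()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_pwm <- function(pwm, path) {
  df <- as.data.frame(unclass(pwm))
  names(df) <- paste0("pos", seq_len(ncol(df)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Simulate mutated RSS hits
#'
#' Draws `n` copies of the canonical heptamer + nonamer with independent
#' per-position substitution probability `rate` (every position mutable; a
#' substituted position takes one of the three other bases uniformly). Used to
#' emulate observed RSS conservation and to test PWM estimation.
#'
#' @param n number of RSS instances.
#' @param rate per-position substitution probability.
#' @param motif an [rss_motif()] supplying the canonical elements.
#' @return tibble shaped like [scan_rss()] output.
#' @export
simulate_rss_hits <- function(n, rate = 0.1, motif = standard_rss_motif("v3")) {
  mutate_all_positions <- function(x) {
    chars <- seq_chars(x)
    hit <- stats::runif(length(chars)) < rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    }
    paste(chars, collapse = "")
  }
  hep <- vapply(seq_len(n), function(i) mutate_all_positions(motif$heptamer), "")
  non <- vapply(seq_len(n), function(i) mutate_all_positions(motif$nonamer), "")
  tibble(
    start = NA_integer_, end = NA_integer_,
    heptamer_seq = hep, spacer_seq = NA_character_, nonamer_seq = non,
    heptamer_mismatches = vapply(hep, hamming, 0, b = motif$heptamer),
    nonamer_mismatches = vapply(non, hamming, 0, b = motif$nonamer),
    total_mismatches = NA_integer_, spacer_deviation = 0L
  ) |> mutate(total_mismatches = .data$heptamer_mismatches + .data$nonamer_mismatches)
}

#' Summarize RSS conservation per segment type
#'
#' For an annotation table, counts segments with and without an accepted RSS
#' and the min/max mutation counts over present RSSs, per segment type (and
#' per RSS side for D genes).
#'
#' @param annotations gene-level annotation tibble with columns `type` and
#'   `rss_mismatches` (NA = missing RSS); D genes carry `rss5_mismatches` /
#'   `rss3_mismatches` instead.
#' @return tibble with `segment`, `n_with_rss`, `n_missing_rss`,
#'   `min_mismatches`, `max_mismatches`.
#' @export
rss_mutation_summary <- function(annotations) {
  rows <- list()
  base <- filter(annotations, .data$type %in% c("V", "J"))
  if (nrow(base) > 0L) {
    rows[["vj"]] <- base |>
      group_by(segment = .data$type) |>
      summarize(
        n_with_rss = sum(!is.na(.data$rss_mismatches)),
        n_missing_rss = sum(is.na(.data$rss_mismatches)),
        min_mismatches = if (any(!is.na(.data$rss_mismatches))) min(.data$rss_mismatches, na.rm = TRUE) else NA_integer_,
        max_mismatches = if (any(!is.na(.data$rss_mismatches))) max(.data$rss_mismatches, na.rm = TRUE) else NA_integer_,
        .groups = "drop"
      )
  }
  dd <- filter(annotations, .data$type == "D")
  if (nrow(dd) > 0L) {
    for (side in c("rss5_mismatches", "rss3_mismatches")) {
      x <- dd[[side]]
      rows[[side]] <- tibble(
        segment = paste0("D_", sub("_mismatches", "", side)),
        n_with_rss = sum(!is.na(x)), n_missing_rss = sum(is.na(x)),
        min_mismatches = if (any(!is.na(x))) min(x, na.rm = TRUE) else NA_integer_,
        max_mismatches = if (any(!is.na(x))) max(x, na.rm = TRUE) else NA_integer_
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble(segment = character(), n_with_rss = integer(),
                  n_missing_rss = integer(), min_mismatches = integer(),
                  max_mismatches = integer()))
  }
  list_rbind(unname(rows))
}
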