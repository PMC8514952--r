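# Nucleotide substitution scores used for candidate seeding and boundary
# refinement; mild mismatch penalty keeps divergent germline copies aligned
# end to end.
nt_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3, baseOnly = TRUE)
}

# k-mer anchor positions of `ref` inside `subject_seq`, as implied reference
# start positions on the subject, clustered into candidate anchors.
kmer_anchors <- function(ref, subject_seq, k = 11L, band = 40L) {
  n <- nchar(ref)
  # short references get shorter seeds so one substitution cannot erase
  # every exact k-mer
  k <- min(k, max(8L, n %/% 2L))
  if (n < k || nchar(subject_seq) < k) return(integer())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(ref, starts, starts + k - 1L)
  keep <- !str_detect(kmers, "N")
  if (!any(keep)) return(integer())
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[keep]))
  hits <- Biostrings::matchPDict(pd, Biostrings::DNAString(subject_seq))
  implied <- integer()
  koff <- starts[keep]
  for (i in seq_along(hits)) {
    s <- BiocGenerics::start(hits[[i]])
    if (length(s)) implied <- c(implied, s - koff[i] + 1L)
  }
  if (length(implied) == 0L) return(integer())
  implied <- sort(implied)
  grp <- cumsum(c(TRUE, diff(implied) > band))
  vapply(split(implied, grp), function(g) as.integer(round(stats::median(g))), 1L)
}

# anchors for all references on the requested strands with one PDict match
# per (strand, seed width); returns (ref, strand, pos, n_seeds) where pos is
# on the strand's own frame
combined_anchors <- function(refs, locus_seq, strands, k = 11L, band = 40L) {
  k_eff <- vapply(refs, function(r) min(k, max(8L, nchar(r) %/% 2L)), 1L)
  out <- list()
  subjects <- list("+" = Biostrings::DNAString(locus_seq))
  if ("-" %in% strands) subjects[["-"]] <- Biostrings::DNAString(revcomp(locus_seq))
  for (kw in unique(k_eff)) {
    rset <- names(refs)[k_eff == kw]
    kmers <- character(0); kref <- character(0); koff <- integer(0)
    for (rn in rset) {
      n <- nchar(refs[[rn]])
      if (n < kw) next
      # long references do not need every overlapping seed
      stride <- if (n >= 60L) 3L else 1L
      starts <- seq.int(1L, n - kw + 1L, by = stride)
      km <- substring(refs[[rn]], starts, starts + kw - 1L)
      ok <- !str_detect(km, "N")
      kmers <- c(kmers, km[ok]); kref <- c(kref, rep(rn, sum(ok)))
      koff <- c(koff, starts[ok])
    }
    if (length(kmers) == 0L) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))
    for (strand in strands) {
      hits <- Biostrings::matchPDict(pd, subjects[[strand]])
      counts <- S4Vectors::elementNROWS(hits)
      hot <- which(counts > 0L)
      if (length(hot) == 0L) next
      implied <- integer(0); iref <- character(0)
      for (i in hot) {
        s <- BiocGenerics::start(hits[[i]])
        implied <- c(implied, s - koff[i] + 1L)
        iref <- c(iref, rep(kref[i], length(s)))
      }
      tb <- tibble(ref = iref, pos = implied) |> arrange(.data$ref, .data$pos)
      grp <- tb |>
        group_by(.data$ref) |>
        mutate(cluster = cumsum(c(TRUE, diff(.data$pos) > band))) |>
        group_by(.data$ref, .data$cluster) |>
        summarize(pos = as.integer(round(stats::median(.data$pos))),
                  n_seeds = n(), .groups = "drop") |>
        mutate(strand = strand)
      out[[length(out) + 1L]] <- grp
    }
  }
  if (length(out) == 0L) {
    return(tibble(ref = character(), cluster = integer(), pos = integer(),
                  n_seeds = integer(), strand = character()))
  }
  list_rbind(out)
}

align_ref_in_window <- function(ref, window_seq) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ref),
    subject = Biostrings::DNAString(window_seq),
    type = "global-local",
    substitutionMatrix = nt_submat(),
    gapOpening = 10, gapExtension = 2
  )
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  ni <- Biostrings::nindel(pa)
  ins <- unname(ni@deletion[, "WidthSum"])   # subject nt absent from the reference
  del <- unname(ni@insertion[, "WidthSum"])  # reference nt absent from the subject
  runs <- unname(ni@deletion[, "Length"] + ni@insertion[, "Length"])
  list(
    sub_start = BiocGenerics::start(Biostrings::subject(pa)@range),
    sub_end = BiocGenerics::end(Biostrings::subject(pa)@range),
    # gap-compressed identity: an indel run counts as one aligned column, so a
    # single structural deletion does not mask an otherwise near-exact copy
    identity = 100 * nm / (nm + nmm + runs),
    score = Biostrings::score(pa),
    ins_nt = ins, del_nt = del, indel_nt = ins + del
  )
}

#' Seed candidate germline genes by homology
#'
#' Locates approximate copies of each reference sequence on both strands of a
#' locus: exact k-mer anchors (via [Biostrings::matchPDict()]) are clustered
#' by implied reference start, each cluster window is aligned globally in the
#' reference / locally in the window, and candidates above the identity floor
#' are kept. Overlapping candidates are resolved greedily by
#' (identity, length, position); coordinates are always reported on the
#' forward frame of `locus_seq` with the matched strand.
#'
#' @param locus_seq locus DNA string (gene orientation).
#' @param refs named character vector of reference germline regions.
#' @param min_identity identity floor in percent.
#' @param min_cov minimum fraction of the reference covered by the aligned
#'   span; guards against short gappy alignments whose gap-compressed
#'   identity looks deceptively high.
#' @param k seed k-mer length.
#' @param both_strands also search the reverse complement.
#' @param max_overlap fraction of the shorter candidate that may overlap a
#'   better one before it is dropped.
#' @return tibble: `start`, `end`, `strand`, `ref`, `identity`, `score`,
#'   `indel_nt`, sorted by position.
#' @export
homology_seed <- function(locus_seq, refs, min_identity = 70, min_cov = 0.6,
                          k = 11L, both_strands = TRUE, max_overlap = 0.5) {
  if (length(refs) == 0L) stop("empty reference set")
  if (is.null(names(refs)) || any(!nzchar(names(refs)))) {
    stop("references must be named")
  }
  L <- nchar(locus_seq)
  strands <- if (both_strands) c("+", "-") else "+"
  anchors_all <- combined_anchors(refs, locus_seq, strands, k = k)
  cand <- list()
  if (nrow(anchors_all) > 0L) {
    # at each locus site, try references best-seed-support-first and stop once
    # one aligns convincingly
    anchors_all <- anchors_all |>
      arrange(.data$strand, .data$pos) |>
      group_by(.data$strand) |>
      mutate(site = cumsum(c(TRUE, diff(.data$pos) > 200L))) |>
      group_by(.data$strand, .data$site) |>
      arrange(desc(.data$n_seeds), .data$ref, .by_group = TRUE) |>
      slice_head(n = 3L) |>
      ungroup()
    for (site_df in split(anchors_all, ~ strand + site, drop = TRUE)) {
      settled <- NULL  # strand-frame intervals already matched convincingly
      for (r in seq_len(nrow(site_df))) {
        strand <- site_df$strand[r]
        rn <- site_df$ref[r]
        ref <- refs[[rn]]
        m <- nchar(ref)
        a <- site_df$pos[r]
        if (!is.null(settled)) {
          ov <- pmin(settled$end, a + m - 1L) - pmax(settled$start, a)
          if (any(ov > 0.5 * m)) next
        }
        sseq <- if (strand == "+") locus_seq else revcomp(locus_seq)
        ws <- max(1L, a - 30L)
        we <- min(L, a + m - 1L + 30L)
        if (we - ws + 1L < max(k, m %/% 3L)) next
        al <- align_ref_in_window(ref, substr(sseq, ws, we))
        if (al$identity < min_identity) next
        if ((al$sub_end - al$sub_start + 1L) < min_cov * m) next
        if (al$score <= 0) next  # gap-riddled chance matches score negative
        s <- ws + al$sub_start - 1L
        e <- ws + al$sub_end - 1L
        if (al$identity >= 85) {
          settled <- bind_rows(settled, tibble(start = s, end = e))
        }
        if (strand == "-") {
          mi <- mirror_interval(s, e, L)
          s <- mi[["start"]]; e <- mi[["end"]]
        }
        cand[[length(cand) + 1L]] <- tibble(
          start = s, end = e, strand = strand, ref = rn,
          identity = al$identity, score = al$score, indel_nt = al$indel_nt
        )
      }
    }
  }
  if (length(cand) == 0L) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  ref = character(), identity = double(), score = double(),
                  indel_nt = integer()))
  }
  out <- list_rbind(cand) |>
    arrange(desc(.data$identity), desc(.data$end - .data$start), .data$start)
  # greedy overlap resolution: keep best-scoring, drop lower-scoring overlaps
  kept <- list()
  for (i in seq_len(nrow(out))) {
    row <- out[i, ]
    clash <- FALSE
    for (kp in kept) {
      ov <- min(row$end, kp$end) - max(row$start, kp$start) + 1L
      if (ov > 0L && ov > max_overlap * min(row$end - row$start + 1L,
                                            kp$end - kp$start + 1L)) {
        clash <- TRUE
        break
      }
    }
    if (!clash) kept[[length(kept) + 1L]] <- row
  }
  arrange(list_rbind(kept), .data$start)
}
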