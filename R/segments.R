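#' Annotation parameters
#'
#' One bag of tunables for the structural describers, with the defaults used
#' throughout: RSS acceptance at 6 total mutations with an intact CAC heptamer
#' core (9 mutations for reporting a defective RSS), no spacer-length
#' tolerance, V-exon plausible length 250-350 nt, leader part 1 of 10-60 nt
#' across a 60-600 nt intron with an 11-nt leader part 2, J regions of
#' 40-80 nt, D cores of 6-25 nt.
#'
#' @param rss_accept_max max total RSS mutations for an accepted ("present") RSS.
#' @param rss_report_max max total mutations when reporting a defective RSS.
#' @param require_core require intact CAC heptamer core for acceptance.
#' @param spacer_tol allowed spacer-length deviation (0 or 1).
#' @param v_exon_len plausible V-exon length bounds (nt).
#' @param l_part1_len leader part 1 length bounds (nt).
#' @param intron_len leader intron length bounds (nt).
#' @param l_part2_len leader part 2 length (nt).
#' @param j_region_len J region length bounds (nt).
#' @param j_default_len J region length assumed when no donor is found.
#' @param d_core_len D core length bounds (nt).
#' @param d_rss_accept_max max total mutations per D RSS; stricter than the
#'   V/J cutoff because a D call rests on its two RSSs alone, with no coding
#'   homology to corroborate it.
#' @param d_near_j maximum distance (nt) from a D gene to the next J gene
#'   downstream for the pipeline to keep the D call (D genes sit at the head
#'   of D-J-C clusters); ignored when no J genes are found.
#' @param min_identity homology-seeding identity floor (percent).
#' @param require_g_rich require D-core G fraction >= 0.5.
#' @return list of class `tr_params`.
#' @export
annotate_params <- function(rss_accept_max = 6L, rss_report_max = 9L,
                            require_core = TRUE, spacer_tol = 0L,
                            v_exon_len = c(250L, 350L),
                            l_part1_len = c(10L, 60L),
                            intron_len = c(60L, 600L), l_part2_len = 11L,
                            j_region_len = c(40L, 80L), j_default_len = 57L,
                            d_core_len = c(6L, 25L),
                            d_rss_accept_max = 5L, d_near_j = 5000L,
                            min_identity = 70, require_g_rich = FALSE) {
  structure(as.list(environment()), class = "tr_params")
}

new_segment <- function(type, start, end, strand, features, defects,
                        extra = list()) {
  features$start <- as.integer(unname(features$start))
  features$end <- as.integer(unname(features$end))
  structure(
    list(type = type, start = as.integer(unname(start)),
         end = as.integer(unname(end)),
         strand = strand, features = features,
         defects = unique(defects), extra = extra),
    class = "tr_segment"
  )
}

#' @export
print.tr_segment <- function(x, ...) {
  cat(sprintf("<tr_segment> %s [%d-%d] (%s)%s\n", x$type, x$start, x$end,
              x$strand,
              if (length(x$defects)) paste0(" defects: ", paste(x$defects, collapse = ",")) else ""))
  invisible(x)
}

mirror_segment <- function(seg, L) {
  mi <- mirror_interval(seg$start, seg$end, L)
  seg$start <- mi[["start"]]; seg$end <- mi[["end"]]
  if (nrow(seg$features) > 0L) {
    fm <- t(vapply(seq_len(nrow(seg$features)), function(k) {
      mirror_interval(seg$features$start[k], seg$features$end[k], L)
    }, c(start = 0L, end = 0L)))
    seg$features$start <- fm[, "start"]
    seg$features$end <- fm[, "end"]
  }
  seg$strand <- if (seg$strand == "+") "-" else "+"
  seg
}

# best accepted RSS hit near an expected coding boundary; ties broken by
# distance to the boundary, then leftmost
pick_rss <- function(hits, boundary_pos, edge = c("after", "before")) {
  edge <- match.arg(edge)
  if (nrow(hits) == 0L) return(NULL)
  dist <- if (edge == "after") abs(hits$start - boundary_pos) else abs(hits$end - boundary_pos)
  hits <- hits[order(hits$total_mismatches, dist, hits$start), ]
  hits[1, ]
}

# scan for an accepted RSS near a coding boundary; when none, check whether a
# defective one (mutation count <= report max, core not required) sits at the
# exact expected junction position (+/- 1 nt), so that "defective" is only
# recorded for a recognizable-but-rejected signal, not for arbitrary sequence
rss_near <- function(seq, window_start, window_end, motif, boundary_pos, edge,
                     params) {
  L <- nchar(seq)
  w <- rss_window_width(motif)
  ws <- max(1L, window_start); we <- min(L, window_end)
  if (we - ws + 1L >= w) {
    sub <- substr(seq, ws, we)
    acc <- scan_rss(sub, motif, max_mismatches = params$rss_accept_max,
                    require_core = params$require_core,
                    spacer_tol = params$spacer_tol)
    if (nrow(acc) > 0L) {
      acc <- mutate(acc, start = .data$start + ws - 1L, end = .data$end + ws - 1L)
      return(list(hit = pick_rss(acc, boundary_pos, edge), status = "present"))
    }
  }
  best <- NULL
  s <- if (edge == "after") boundary_pos else boundary_pos - w + 1L
  e <- s + w - 1L
  if (s >= 1L && e <= L) {
    sc <- score_rss(substr(seq, s, e), motif,
                    max_mismatches = params$rss_report_max, require_core = FALSE)
    if (!is.na(sc$total_mismatches)) best <- mutate(sc, start = s, end = e)
  }
  if (!is.null(best) && best$total_mismatches <= params$rss_report_max) {
    return(list(hit = best, status = "defective"))
  }
  list(hit = NULL, status = "missing")
}

rss_features <- function(hit, motif, prefix = "RSS") {
  sp <- motif$spacer + hit$spacer_deviation
  if (motif$layout == "heptamer_first") {
    tibble(
      feature = paste0(prefix, c("-HEPTAMER", "-SPACER", "-NONAMER")),
      start = c(hit$start, hit$start + 7L, hit$start + 7L + sp),
      end = c(hit$start + 6L, hit$start + 6L + sp, hit$end)
    )
  } else {
    tibble(
      feature = paste0(prefix, c("-NONAMER", "-SPACER", "-HEPTAMER")),
      start = c(hit$start, hit$start + 9L, hit$start + 9L + sp),
      end = c(hit$start + 8L, hit$start + 8L + sp, hit$end)
    )
  }
}

# map reference template amino-acid positions onto a translated query via
# global(pattern)-local(subject) alignment; returns integer vector over
# template positions (NA where deleted)
map_template_positions <- function(template_aa, query_aa) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(template_aa),
    subject = Biostrings::AAString(query_aa),
    type = "global-local",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 2
  )
  alp <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  als <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  s0 <- BiocGenerics::start(Biostrings::subject(pa)@range) - 1L
  p_pos <- 0L; s_pos <- s0
  out <- rep(NA_integer_, nchar(template_aa))
  for (k in seq_along(alp)) {
    if (alp[k] != "-") p_pos <- p_pos + 1L
    if (als[k] != "-") s_pos <- s_pos + 1L
    if (alp[k] != "-" && als[k] != "-") out[p_pos] <- s_pos
  }
  out
}

last_mapped <- function(map, pos) {
  cand <- map[seq_len(min(pos, length(map)))]
  cand <- cand[!is.na(cand)]
  if (length(cand)) cand[length(cand)] else NA_integer_
}

#' Describe a candidate V gene
#'
#' Refines a homology-seeded candidate into a full V-gene description:
#' the 3' boundary is the heptamer start of the best 23-RSS near the
#' candidate end; the V-exon start comes from end-anchored alignment of the
#' reference exon; the leader (L-PART1, intron, L-PART2) is located upstream
#' by reference-leader alignment when a leader reference is available, else by
#' motif-constrained search (ATG...GT donor, AG acceptor, leader frame,
#' stop-free peptide, nearest intron first). The framework/CDR partition and
#' the four conserved V-domain residues (Cys 23, Trp 41, hydrophobic 89,
#' Cys 104 in template numbering) are placed by aligning the translated exon
#' to the reference template; conserved-residue presence is recorded, never
#' enforced. Structural defects are recorded as codes for the classifier.
#'
#' @param locus_seq locus DNA (gene orientation of the locus).
#' @param candidate one-row tibble from [homology_seed()] (`start`, `end`,
#'   `strand`, `ref`, `identity`).
#' @param refs reference bundle: `V` (named exon sequences) and optionally
#'   `v_leaders` (named leader sequences, L-PART1 + L-PART2 concatenated).
#' @param params an [annotate_params()].
#' @return a `tr_segment` of type `"V"`, or `NULL` when no plausible exon can
#'   be placed (the drop reason is attached as attribute `"reason"`).
#' @export
describe_v <- function(locus_seq, candidate, refs, params = annotate_params()) {
  L <- nchar(locus_seq)
  if (candidate$strand == "-") {
    rc <- revcomp(locus_seq)
    mi <- mirror_interval(candidate$start, candidate$end, L)
    cand2 <- candidate
    cand2$start <- mi[["start"]]; cand2$end <- mi[["end"]]; cand2$strand <- "+"
    seg <- describe_v(rc, cand2, refs, params)
    if (is.null(seg)) return(NULL)
    return(mirror_segment(seg, L))
  }
  ref_exon <- refs$V[[candidate$ref]]
  if (is.null(ref_exon)) stop("candidate reference not in refs$V: ", candidate$ref)
  m <- nchar(ref_exon)
  defects <- character(0)
  feats <- list()

  # 1. 23-RSS at the 3' edge
  motif <- standard_rss_motif("v3")
  rssr <- rss_near(locus_seq, candidate$end - 50L, candidate$end + 80L, motif,
                   boundary_pos = candidate$end + 1L, edge = "after", params)
  rss_hit <- rssr$hit
  rss_mm <- NA_integer_
  if (rssr$status == "present") {
    rss_mm <- rss_hit$total_mismatches
  } else if (rssr$status == "defective") {
    defects <- c(defects, "defective_rss")
  } else {
    defects <- c(defects, "missing_rss")
  }
  v_end <- if (!is.null(rss_hit)) rss_hit$start - 1L else candidate$end
  if (!is.null(rss_hit)) feats$rss <- rss_features(rss_hit, motif)

  # 2. V-exon start by end-anchored reference alignment
  ws <- max(1L, v_end - m - 40L)
  if (v_end - ws + 1L < 30L) return(NULL)
  al <- align_ref_in_window(ref_exon, substr(locus_seq, ws, v_end))
  v_start <- ws + al$sub_start - 1L
  exon_seq <- substr(locus_seq, v_start, v_end)
  exon_len <- nchar(exon_seq)
  if ((al$ins_nt - al$del_nt) %% 3L != 0L) defects <- c(defects, "frameshift")
  if (exon_len < params$v_exon_len[1] || exon_len > params$v_exon_len[2]) {
    defects <- c(defects, "length_out_of_range")
  }
  aa <- translate_dna(exon_seq)
  if (nchar(aa) < 30L) return(NULL)
  if (has_stop(aa)) defects <- c(defects, "stop_codon")
  feats$exon <- tibble(feature = "V-EXON", start = v_start, end = v_end)

  # 3. framework/CDR partition + conserved residues via template alignment
  template_aa <- translate_dna(ref_exon)
  pos_map <- map_template_positions(template_aa, aa)
  aa_at <- function(p) {
    i <- if (p <= length(pos_map)) pos_map[p] else NA_integer_
    if (is.na(i)) NA_character_ else substr(aa, i, i)
  }
  conserved <- c(
    first_cys_23 = identical(aa_at(23L), "C"),
    trp_41 = identical(aa_at(41L), "W"),
    hydrophobic_89 = isTRUE(aa_at(89L) %in% HYDROPHOBIC_AA),
    second_cys_104 = identical(aa_at(104L), "C")
  )
  if (!all(conserved)) defects <- c(defects, "missing_conserved_residue")
  region_ends <- vapply(
    c(fr1 = 26L, cdr1 = 38L, fr2 = 55L, cdr2 = 65L, fr3 = 104L),
    function(p) last_mapped(pos_map, p), 1L
  )
  labels <- c("FR1", "CDR1", "FR2", "CDR2", "FR3")
  prev_nt <- 0L
  regions <- list()
  for (k in seq_along(labels)) {
    if (is.na(region_ends[k])) next
    end_nt <- 3L * region_ends[k]
    if (end_nt <= prev_nt) next
    regions[[k]] <- tibble(feature = labels[k],
                           start = v_start + prev_nt, end = v_start + end_nt - 1L)
    prev_nt <- end_nt
  }
  if (v_start + prev_nt <= v_end && prev_nt > 0L) {
    regions[[length(labels) + 1L]] <- tibble(
      feature = "CDR3-GERMLINE", start = v_start + prev_nt, end = v_end
    )
  }
  feats$regions <- list_rbind(regions[!vapply(regions, is.null, TRUE)])

  # 4. leader
  leader_ref <- refs$v_leaders[[candidate$ref]] %||% NULL
  lead <- locate_leader(locus_seq, v_start, leader_ref, params)
  if (is.null(lead)) {
    defects <- c(defects, "missing_leader")
  } else {
    feats$leader <- tibble(
      feature = c("L-PART1", "L-INTRON", "L-PART2"),
      start = c(lead$l_part1[1], lead$intron[1], lead$l_part2[1]),
      end = c(lead$l_part1[2], lead$intron[2], lead$l_part2[2])
    )
    if (!lead$init_ok) defects <- c(defects, "missing_init")
    if (!lead$donor_ok) defects <- c(defects, "broken_donor")
    if (!lead$acceptor_ok) defects <- c(defects, "broken_acceptor")
    if (lead$leader_stop) defects <- c(defects, "stop_codon")
  }

  features <- list_rbind(feats[!vapply(feats, is.null, TRUE)])
  gene_start <- if (!is.null(lead)) lead$l_part1[1] else v_start
  gene_end <- if (!is.null(rss_hit)) rss_hit$end else v_end
  new_segment(
    "V", gene_start, gene_end, "+", features, defects,
    extra = list(
      ref = candidate$ref, identity = candidate$identity,
      rss = rss_hit, rss_status = rssr$status, rss_mismatches = rss_mm,
      conserved = conserved, v_exon = c(v_start, v_end), exon_aa = aa,
      exon_nt = exon_seq
    )
  )
}

# locate L-PART1/intron/L-PART2 upstream of a V-exon start
locate_leader <- function(locus_seq, v_start, leader_ref, params) {
  p2 <- params$l_part2_len
  l2s <- v_start - p2; l2e <- v_start - 1L
  if (l2s < 3L) return(NULL)
  acceptor_ok <- substr(locus_seq, l2s - 2L, l2s - 1L) == "AG"
  win_lo <- max(1L, l2s - 2L - params$intron_len[2] - params$l_part1_len[2])
  win_hi <- l2s - 3L - params$intron_len[1] + 2L
  if (win_hi - win_lo < params$l_part1_len[1]) return(NULL)

  if (!is.null(leader_ref)) {
    # reference-guided: when the leader reference finds no credible match
    # upstream, the leader is reported absent (no motif fallback, which would
    # chance on spurious ATG/GT pairs in background sequence)
    lp1_ref <- substr(leader_ref, 1L, nchar(leader_ref) - p2)
    al <- align_ref_in_window(lp1_ref, substr(locus_seq, win_lo, win_hi))
    if (al$identity < 60 || al$score <= 0) return(NULL)
    if (al$identity >= 60) {
      s <- win_lo + al$sub_start - 1L
      e <- win_lo + al$sub_end - 1L
      intron <- c(e + 1L, l2s - 1L)  # includes terminal AG
      ilen <- intron[2] - intron[1] + 1L
      if (ilen >= 10L) {
        lp1 <- substr(locus_seq, s, e)
        lp2 <- substr(locus_seq, l2s, l2e)
        leader_nt <- paste0(lp1, lp2)
        return(list(
          l_part1 = c(s, e), intron = intron, l_part2 = c(l2s, l2e),
          init_ok = substr(lp1, 1L, 3L) == "ATG",
          donor_ok = substr(locus_seq, e + 1L, e + 2L) == "GT",
          acceptor_ok = acceptor_ok,
          leader_stop = nchar(leader_nt) %% 3L == 0L && has_stop(translate_dna(leader_nt))
        ))
      }
    }
  }
  # motif-constrained fallback: nearest valid (GT intron start, ATG) pair
  for (ilen in seq.int(params$intron_len[1], params$intron_len[2])) {
    istart <- l2s - ilen
    if (istart < params$l_part1_len[1] + 1L) break
    if (substr(locus_seq, istart, istart + 1L) != "GT") next
    for (l1 in seq.int(params$l_part1_len[1], params$l_part1_len[2])) {
      if ((l1 + p2) %% 3L != 0L) next
      s <- istart - l1
      if (s < 1L) break
      if (substr(locus_seq, s, s + 2L) != "ATG") next
      leader_nt <- paste0(substr(locus_seq, s, istart - 1L),
                          substr(locus_seq, l2s, l2e))
      if (has_stop(translate_dna(leader_nt))) next
      return(list(
        l_part1 = c(s, istart - 1L), intron = c(istart, l2s - 1L),
        l_part2 = c(l2s, l2e),
        init_ok = TRUE, donor_ok = TRUE, acceptor_ok = acceptor_ok,
        leader_stop = FALSE
      ))
    }
  }
  NULL
}

#' Find D genes: RSS-flanked G-rich cores
#'
#' Reports every arrangement of an accepted 12-RSS (nonamer first), a core of
#' plausible length, and an accepted 23-RSS (heptamer first) within the search
#' interval. The core G fraction is reported and only filtered when
#' `params$require_g_rich` is set.
#'
#' @param locus_seq locus DNA.
#' @param interval `c(start, end)` search interval (1-based inclusive);
#'   defaults to the whole sequence.
#' @param params an [annotate_params()].
#' @param strand search the `"+"` frame or the mirrored `"-"` frame.
#' @return list of `tr_segment`s of type `"D"`.
#' @export
find_d <- function(locus_seq, interval = NULL, params = annotate_params(),
                   strand = "+") {
  L <- nchar(locus_seq)
  if (strand == "-") {
    rc <- revcomp(locus_seq)
    interval2 <- if (is.null(interval)) NULL else {
      mi <- mirror_interval(interval[1], interval[2], L)
      c(mi[["start"]], mi[["end"]])
    }
    segs <- find_d(rc, interval2, params, strand = "+")
    return(map(segs, mirror_segment, L = L))
  }
  if (is.null(interval)) interval <- c(1L, L)
  s <- max(1L, interval[1]); e <- min(L, interval[2])
  sub <- substr(locus_seq, s, e)
  m5 <- standard_rss_motif("d5"); m3 <- standard_rss_motif("d3")
  h5 <- scan_rss(sub, m5, max_mismatches = params$d_rss_accept_max,
                 require_core = params$require_core, spacer_tol = params$spacer_tol)
  h3 <- scan_rss(sub, m3, max_mismatches = params$d_rss_accept_max,
                 require_core = params$require_core, spacer_tol = params$spacer_tol)
  if (nrow(h5) == 0L || nrow(h3) == 0L) return(list())
  out <- list()
  for (i in seq_len(nrow(h5))) {
    for (j in seq_len(nrow(h3))) {
      core_s <- h5$end[i] + 1L
      core_e <- h3$start[j] - 1L
      core_len <- core_e - core_s + 1L
      if (core_len < params$d_core_len[1] || core_len > params$d_core_len[2]) next
      core_seq <- substr(sub, core_s, core_e)
      gf <- g_fraction(core_seq)
      if (params$require_g_rich && (is.na(gf) || gf < 0.5)) next
      off <- s - 1L
      hit5 <- h5[i, ] |> mutate(start = .data$start + off, end = .data$end + off)
      hit3 <- h3[j, ] |> mutate(start = .data$start + off, end = .data$end + off)
      features <- bind_rows(
        rss_features(hit5, m5, prefix = "RSS5"),
        tibble(feature = "D-REGION", start = core_s + off, end = core_e + off),
        rss_features(hit3, m3, prefix = "RSS3")
      )
      out[[length(out) + 1L]] <- new_segment(
        "D", hit5$start, hit3$end, "+", features, character(0),
        extra = list(
          core = c(core_s + off, core_e + off), core_seq = core_seq,
          g_fraction = gf,
          rss5 = hit5, rss3 = hit3,
          rss5_mismatches = hit5$total_mismatches,
          rss3_mismatches = hit3$total_mismatches
        )
      )
    }
  }
  out
}

J_MOTIF_REGEX <- "[WF][GA].G"

#' Find J genes: 12-RSS, region, motif and donor splice
#'
#' A candidate is an accepted 12-RSS (nonamer first, 5' of the region)
#' followed by a region of plausible length ending at a GT donor; among
#' donor choices the one best matching the `GTAAGT` consensus is taken
#' (ties: shortest region). The `[W/F]-[G/A]-X-G` motif is searched in all
#' three frames and the frame recorded. Candidates without motif or donor are
#' kept but flagged; a region length that is not a codon multiple is recorded
#' as a frameshift. When no accepted RSS exists near `region_hint` (a
#' homology-seeded region interval), a defective/missing RSS is recorded and
#' the region is anchored on the hint instead.
#'
#' @param locus_seq locus DNA.
#' @param interval search interval `c(start, end)`; whole sequence if NULL.
#' @param params an [annotate_params()].
#' @param region_hint optional `c(start, end)` of a homology-seeded J region.
#' @param strand `"+"` or `"-"` (mirrored search).
#' @return list of `tr_segment`s of type `"J"`.
#' @export
find_j <- function(locus_seq, interval = NULL, params = annotate_params(),
                   region_hint = NULL, strand = "+") {
  L <- nchar(locus_seq)
  if (strand == "-") {
    rc <- revcomp(locus_seq)
    conv <- function(x) {
      if (is.null(x)) return(NULL)
      mi <- mirror_interval(x[1], x[2], L)
      c(mi[["start"]], mi[["end"]])
    }
    segs <- find_j(rc, conv(interval), params, region_hint = conv(region_hint),
                   strand = "+")
    return(map(segs, mirror_segment, L = L))
  }
  if (is.null(interval)) interval <- c(1L, L)
  s <- max(1L, interval[1]); e <- min(L, interval[2])
  sub <- substr(locus_seq, s, e)
  motif <- standard_rss_motif("j5")
  hits <- scan_rss(sub, motif, max_mismatches = params$rss_accept_max,
                   require_core = params$require_core,
                   spacer_tol = params$spacer_tol)
  off <- s - 1L
  segs <- list()
  if (nrow(hits) > 0L) {
    hits <- hits |> mutate(start = .data$start + off, end = .data$end + off)
    # cluster overlapping/shifted windows; keep the best per site
    hits <- arrange(hits, .data$start)
    grp <- cumsum(c(TRUE, diff(hits$start) > 10L))
    hits <- hits |>
      mutate(.grp = grp) |>
      group_by(.data$.grp) |>
      arrange(.data$total_mismatches, .data$start, .by_group = TRUE) |>
      slice(1L) |>
      ungroup() |>
      select(-".grp")
    for (i in seq_len(nrow(hits))) {
      segs[[length(segs) + 1L]] <- describe_j_at(
        locus_seq, hits[i, ], rss_status = "present", params
      )
    }
  } else if (!is.null(region_hint)) {
    near <- rss_near(locus_seq, 1L, 0L, motif,
                     boundary_pos = region_hint[1] - 1L, edge = "before", params)
    if (near$status == "defective") {
      segs[[1L]] <- describe_j_at(locus_seq, near$hit, rss_status = "defective", params)
    } else {
      segs[[1L]] <- describe_j_at(locus_seq, NULL, rss_status = "missing", params,
                                  region_start = region_hint[1])
    }
  }
  segs[!vapply(segs, is.null, TRUE)]
}

describe_j_at <- function(locus_seq, rss_hit, rss_status, params,
                          region_start = NULL) {
  L <- nchar(locus_seq)
  defects <- character(0)
  feats <- list()
  motif <- standard_rss_motif("j5")
  if (!is.null(rss_hit)) {
    region_start <- rss_hit$end + 1L
    feats$rss <- rss_features(rss_hit, motif)
  }
  if (rss_status == "defective") defects <- c(defects, "defective_rss")
  if (rss_status == "missing") defects <- c(defects, "missing_rss")
  if (is.null(region_start) || region_start > L) return(NULL)

  # donor search extends past the nominal region bounds so that genuinely
  # short or long regions are still anchored on their consensus donor and can
  # then be flagged length_out_of_range
  lo <- max(region_start + 20L, region_start + params$j_region_len[1] - 25L)
  hi <- min(L - 2L, region_start + params$j_region_len[2] + 23L)
  donor_end <- NA_integer_
  if (hi >= lo) {
    cand_ends <- lo:hi
    is_gt <- substring(locus_seq, cand_ends + 1L, cand_ends + 1L) == "G" &
      substring(locus_seq, cand_ends + 2L, cand_ends + 2L) == "T"
    cand_ends <- cand_ends[is_gt]
    if (length(cand_ends) > 0L) {
      ctx <- substring(locus_seq, cand_ends + 1L, pmin(L, cand_ends + 6L))
      score <- vapply(ctx, function(x) {
        n <- min(nchar(x), 6L)
        sum(seq_chars(substr(x, 1, n)) == seq_chars(substr(DONOR_CONSENSUS, 1, n)))
      }, 0)
      rlen_cand <- cand_ends - region_start + 1L
      in_bounds <- rlen_cand >= params$j_region_len[1] &
        rlen_cand <= params$j_region_len[2]
      ord <- order(-score, -in_bounds, cand_ends)
      donor_end <- cand_ends[ord[1]]
    }
  }
  if (is.na(donor_end)) {
    defects <- c(defects, "broken_donor")
    region_end <- min(L, region_start + params$j_default_len - 1L)
  } else {
    region_end <- donor_end
  }
  region <- substr(locus_seq, region_start, region_end)
  rlen <- nchar(region)
  if (rlen < params$j_region_len[1] || rlen > params$j_region_len[2]) {
    defects <- c(defects, "length_out_of_range")
  }
  if (rlen %% 3L != 0L) defects <- c(defects, "frameshift")

  motif_aa <- NA_character_; motif_frame <- NA_integer_
  for (f in 1:3) {
    aa <- translate_dna(substr(region, f, rlen))
    m <- regexpr(J_MOTIF_REGEX, aa)
    if (m[1] > 0L) {
      motif_aa <- substr(aa, m[1], m[1] + 3L)
      motif_frame <- f
      break
    }
  }
  if (is.na(motif_frame)) defects <- c(defects, "missing_motif")
  frame_for_stop <- if (!is.na(motif_frame)) motif_frame else 1L
  if (rlen %% 3L == 0L) {
    aa1 <- translate_dna(substr(region, frame_for_stop, rlen))
    if (has_stop(aa1)) defects <- c(defects, "stop_codon")
  }
  feats$region <- tibble(feature = "J-REGION", start = region_start, end = region_end)
  if (!is.na(donor_end)) {
    feats$donor <- tibble(feature = "J-DONOR", start = donor_end + 1L, end = donor_end + 2L)
  }
  gene_start <- if (!is.null(rss_hit)) rss_hit$start else region_start
  new_segment(
    "J", gene_start, region_end, "+",
    list_rbind(feats[!vapply(feats, is.null, TRUE)]), defects,
    extra = list(
      rss = rss_hit, rss_status = rss_status,
      rss_mismatches = if (rss_status == "present") rss_hit$total_mismatches else NA_integer_,
      motif = motif_aa, motif_frame = motif_frame,
      region = c(region_start, region_end), region_len = rlen
    )
  )
}

#' Find C genes: reference-guided exon chains
#'
#' Each reference exon is located independently by homology inside the search
#' interval; hits are chained in reference exon order, requiring an `AG`
#' acceptor before every exon and a `GT` donor after every non-terminal exon
#' (splice failures are recorded as defects, the chain is still reported).
#' The terminal untranslated exon, where the reference has one, is exempt from
#' the translation requirement. The translated length is computed from the
#' spliced coding exons.
#'
#' @param locus_seq locus DNA.
#' @param interval search interval; whole sequence if NULL.
#' @param c_refs named character vector of reference C coding sequences
#'   (spliced exons concatenated).
#' @param c_exons sidecar exon table: `ref`, `label`, `start`, `end`
#'   (coordinates in the reference sequence), `translated`.
#' @param params an [annotate_params()].
#' @param strand `"+"` or `"-"`.
#' @param max_intron maximum intron length when chaining exons.
#' @return list of `tr_segment`s of type `"C"`.
#' @export
find_c <- function(locus_seq, interval = NULL, c_refs, c_exons,
                   params = annotate_params(), strand = "+", max_intron = 5000L) {
  if (missing(c_exons) || is.null(c_exons) || nrow(c_exons) == 0L) {
    stop("C references require an exon-boundary table")
  }
  L <- nchar(locus_seq)
  if (strand == "-") {
    rc <- revcomp(locus_seq)
    interval2 <- if (is.null(interval)) NULL else {
      mi <- mirror_interval(interval[1], interval[2], L)
      c(mi[["start"]], mi[["end"]])
    }
    segs <- find_c(rc, interval2, c_refs, c_exons, params, strand = "+",
                   max_intron = max_intron)
    return(map(segs, mirror_segment, L = L))
  }
  if (is.null(interval)) interval <- c(1L, L)
  s <- max(1L, interval[1]); e <- min(L, interval[2])
  sub <- substr(locus_seq, s, e)
  off <- s - 1L
  segs <- list()
  for (rn in names(c_refs)) {
    etab <- c_exons |> filter(.data$ref == rn)
    if (nrow(etab) == 0L) stop("no exon boundaries for reference ", rn)
    exon_seqs <- stats::setNames(
      substring(c_refs[[rn]], etab$start, etab$end), etab$label
    )
    hits <- homology_seed(sub, exon_seqs, min_identity = params$min_identity,
                          both_strands = FALSE)
    if (nrow(hits) == 0L) next
    hits <- hits |> mutate(start = .data$start + off, end = .data$end + off)
    first_label <- etab$label[1]
    starts <- hits |> filter(.data$ref == first_label) |> arrange(.data$start)
    for (i in seq_len(nrow(starts))) {
      chain <- starts[i, ]
      ok <- TRUE
      for (k in seq_len(nrow(etab))[-1]) {
        nxt <- hits |>
          filter(.data$ref == etab$label[k],
                 .data$start > chain$end[nrow(chain)],
                 .data$start - chain$end[nrow(chain)] <= max_intron) |>
          arrange(.data$start)
        if (nrow(nxt) == 0L) {
          # short exons can lose every exact seed to one or two substitutions;
          # rescue by direct alignment in the window after the previous exon
          prev_end <- chain$end[nrow(chain)]
          ws <- prev_end + 3L
          we <- min(nchar(locus_seq), prev_end + max_intron)
          if (we - ws + 1L >= nchar(exon_seqs[[k]])) {
            al <- align_ref_in_window(exon_seqs[[k]], substr(locus_seq, ws, we))
            if (al$identity >= 85) {
              nxt <- tibble(
                start = ws + al$sub_start - 1L, end = ws + al$sub_end - 1L,
                strand = "+", ref = etab$label[k], identity = al$identity,
                score = al$score, indel_nt = al$indel_nt
              )
            }
          }
        }
        if (nrow(nxt) == 0L) { ok <- FALSE; break }
        chain <- bind_rows(chain, nxt[1, ])
      }
      if (!ok) next
      defects <- character(0)
      for (k in seq_len(nrow(chain))) {
        acc <- substr(locus_seq, chain$start[k] - 2L, chain$start[k] - 1L)
        if (acc != "AG") defects <- c(defects, "broken_acceptor")
        if (k < nrow(chain)) {
          don <- substr(locus_seq, chain$end[k] + 1L, chain$end[k] + 2L)
          if (don != "GT") defects <- c(defects, "broken_donor")
        }
      }
      coding <- paste(
        substring(locus_seq, chain$start[etab$translated], chain$end[etab$translated]),
        collapse = ""
      )
      if (nchar(coding) %% 3L != 0L) defects <- c(defects, "frameshift")
      aa <- translate_dna(coding)
      if (has_stop(aa)) defects <- c(defects, "stop_codon")
      features <- tibble(feature = chain$ref, start = chain$start, end = chain$end)
      segs[[length(segs) + 1L]] <- new_segment(
        "C", chain$start[1], chain$end[nrow(chain)], "+", features,
        unique(defects),
        extra = list(
          ref = rn, exons = chain |> select("ref", "start", "end"),
          translated_length = nchar(aa), identity = mean(chain$identity),
          translated = etab$translated
        )
      )
    }
  }
  segs
}
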