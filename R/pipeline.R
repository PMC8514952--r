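segment_sort_score <- function(seg) {
  # comparable greedy score: alignment identity for V/C, RSS quality for D/J
  switch(seg$type,
    V = seg$extra$identity %||% 0,
    C = seg$extra$identity %||% 0,
    D = 100 - 5 * ((seg$extra$rss5_mismatches %||% 9) + (seg$extra$rss3_mismatches %||% 9)) / 2,
    J = 100 - 5 * (seg$extra$rss_mismatches %||% 9)
  )
}

resolve_overlaps <- function(segs) {
  if (length(segs) <= 1L) return(segs)
  score <- vapply(segs, segment_sort_score, 0)
  len <- vapply(segs, function(s) s$end - s$start + 1L, 0L)
  pos <- vapply(segs, function(s) s$start, 0L)
  ord <- order(-score, -len, pos)
  kept <- list()
  for (i in ord) {
    s <- segs[[i]]
    clash <- FALSE
    for (kp in kept) {
      if (s$start <= kp$end && kp$start <= s$end) { clash <- TRUE; break }
    }
    if (!clash) kept[[length(kept) + 1L]] <- s
  }
  kept[order(vapply(kept, function(s) s$start, 0L))]
}

segments_to_tibble <- function(segs) {
  if (length(segs) == 0L) {
    return(tibble(
      gene_id = character(), type = character(), start = integer(),
      end = integer(), strand = character(), functionality = character(),
      defects = character(), in_frame_pseudo = logical(),
      rss_mismatches = integer(), rss5_mismatches = integer(),
      rss3_mismatches = integer(), identity = double(), ref = character(),
      motif = character(), translated_length = integer(), g_fraction = double(),
      exon_nt = character()
    ))
  }
  list_rbind(map(segs, function(s) {
    cl <- classify_segment(list(type = s$type, defects = s$defects))
    tibble(
      gene_id = NA_character_, type = s$type, start = s$start, end = s$end,
      strand = s$strand, functionality = cl$call,
      defects = if (length(s$defects)) paste(sort(s$defects), collapse = ",") else NA_character_,
      in_frame_pseudo = cl$in_frame_pseudo,
      rss_mismatches = as.integer(s$extra$rss_mismatches %||% NA_integer_),
      rss5_mismatches = as.integer(s$extra$rss5_mismatches %||% NA_integer_),
      rss3_mismatches = as.integer(s$extra$rss3_mismatches %||% NA_integer_),
      identity = s$extra$identity %||% NA_real_,
      ref = s$extra$ref %||% NA_character_,
      motif = s$extra$motif %||% NA_character_,
      translated_length = as.integer(s$extra$translated_length %||% NA_integer_),
      g_fraction = s$extra$g_fraction %||% NA_real_,
      exon_nt = s$extra$exon_nt %||% NA_character_
    )
  }))
}

#' Regenerate an organization string from ordered annotations
#'
#' Collapses the position-ordered gene list into blocks of consecutive genes
#' of the same type and orientation, written `"V(28)-D(1)-J(6)-C(1)-..."` with
#' `rev` marking reverse-orientation blocks.
#'
#' @param genes annotation tibble with `type`, `strand`, ordered or orderable
#'   by `start`.
#' @return character scalar (empty string for an empty locus).
#' @export
organization_string <- function(genes) {
  if (nrow(genes) == 0L) return("")
  genes <- arrange(genes, .data$start)
  sym <- paste0(genes$type, ifelse(genes$strand == "-", "rev", ""))
  r <- rle(sym)
  paste(sprintf("%s(%d)", r$values, r$lengths), collapse = "-")
}

#' Locus span in kb
#'
#' Distance from the start of the first gene to the end of the last, in kb,
#' rounded to integer.
#'
#' @param genes annotation tibble (or a `tr_locus_report`).
#' @return integer kb (0 for an empty locus).
#' @export
summarize_span <- function(genes) {
  if (inherits(genes, "tr_locus_report")) genes <- genes$annotations
  if (nrow(genes) == 0L) return(0L)
  as.integer(round((max(genes$end) - min(genes$start) + 1L) / 1000))
}

assign_clusters <- function(genes) {
  if (nrow(genes) == 0L) return(mutate(genes, cluster = integer(0)))
  genes <- arrange(genes, .data$start)
  c_seen <- cumsum(genes$type == "C")
  n_c <- sum(genes$type == "C")
  # D/J belong to the cluster of the next C downstream; C genes close their own
  cl <- ifelse(genes$type == "C", c_seen, c_seen + 1L)
  if (n_c > 0L) cl <- pmin(cl, n_c) else cl <- rep(1L, nrow(genes))
  mutate(genes, cluster = as.integer(cl))
}

#' Annotate one locus end to end
#'
#' Runs the full pipeline on a locus sequence in transcriptional orientation:
#' homology seeding of V/J/C candidates against the reference bundle,
#' structural description per segment type ([describe_v()], [find_j()],
#' [find_d()], [find_c()]), cross-type overlap resolution, functionality
#' classification, D-J-C cluster assignment, V subgroup assignment at the
#' identity threshold, and naming. Deterministic given inputs and parameters.
#'
#' @param locus_seq locus DNA string (use [extract_locus()] for reverse loci),
#'   or a length-1 named character.
#' @param refs reference bundle: `V` (named exon sequences), optionally
#'   `v_leaders`, `J` (named J-region sequences), `C` + `c_exons` (see
#'   [find_c()]), optionally `reference_names` for V naming.
#' @param params an [annotate_params()].
#' @param locus_name locus label for the report (e.g. `"TRB"`).
#' @param seq_id sequence id used in emitted features.
#' @param subgroup_threshold percent identity threshold for V subgroups.
#' @param tree_override use the phylogeny-adjacency override when assigning
#'   subgroups (requires a tree with bootstrap supports; see
#'   [assign_subgroups()]).
#' @param group compute V subgroups and the NJ tree; disable for pure
#'   detection runs (V genes then get positional names).
#' @param verbose message dropped candidates with their stage and reason.
#' @return object of class `tr_locus_report`: `annotations` (one row per
#'   gene: coordinates, strand, functionality call, defect codes, RSS
#'   mutation counts, subgroup, cluster, name), `features` (nested sub-part
#'   intervals, GFF3-ready), `counts`, `organization`, `span_kb`,
#'   `rss_summary`, `subgroups`, `tree`, `params`.
#' @export
annotate_locus <- function(locus_seq, refs, params = annotate_params(),
                           locus_name = "locus", seq_id = NULL,
                           subgroup_threshold = 75, tree_override = FALSE,
                           group = TRUE, verbose = FALSE) {
  if (!is.null(names(locus_seq))) {
    if (is.null(seq_id)) seq_id <- names(locus_seq)[1]
    locus_seq <- unname(locus_seq[1])
  }
  if (is.null(seq_id)) seq_id <- locus_name
  log_drop <- function(stage, why) {
    if (verbose) message("[", stage, "] dropped candidate: ", why)
  }
  segs <- list()

  # --- V genes ---------------------------------------------------------------
  if (!is.null(refs$V) && length(refs$V) > 0L) {
    vc <- homology_seed(locus_seq, refs$V, min_identity = params$min_identity)
    for (i in seq_len(nrow(vc))) {
      seg <- describe_v(locus_seq, vc[i, ], refs, params)
      if (is.null(seg)) log_drop("describe_v", paste0("candidate at ", vc$start[i]))
      else segs[[length(segs) + 1L]] <- seg
    }
  }

  # --- J genes ---------------------------------------------------------------
  if (!is.null(refs$J) && length(refs$J) > 0L) {
    jc <- homology_seed(locus_seq, refs$J, min_identity = params$min_identity)
    for (i in seq_len(nrow(jc))) {
      iv <- c(max(1L, jc$start[i] - 60L), min(nchar(locus_seq), jc$end[i] + 30L))
      found <- find_j(locus_seq, iv, params,
                      region_hint = c(jc$start[i], jc$end[i]),
                      strand = jc$strand[i])
      if (length(found) == 0L) {
        log_drop("find_j", paste0("seed at ", jc$start[i]))
        next
      }
      # keep the candidate overlapping the homology seed
      ovl <- vapply(found, function(s) {
        min(s$end, jc$end[i]) - max(s$start, jc$start[i])
      }, 0L)
      segs[[length(segs) + 1L]] <- found[[which.max(ovl)]]
    }
  }

  # --- D genes ---------------------------------------------------------------
  d_segs <- list()
  for (strand in c("+", "-")) {
    d_segs <- c(d_segs, find_d(locus_seq, NULL, params, strand = strand))
  }
  # D genes head D-J-C clusters: keep candidates with a J gene shortly
  # downstream (in gene orientation)
  j_segs <- segs[vapply(segs, function(s) s$type == "J", TRUE)]
  if (length(j_segs) > 0L && length(d_segs) > 0L) {
    j_tbl <- tibble(
      start = vapply(j_segs, function(s) s$start, 0L),
      end = vapply(j_segs, function(s) s$end, 0L),
      strand = vapply(j_segs, function(s) s$strand, "")
    )
    keep <- vapply(d_segs, function(d) {
      same <- j_tbl[j_tbl$strand == d$strand, ]
      if (nrow(same) == 0L) return(FALSE)
      gap <- if (d$strand == "+") same$start - d$end else d$start - same$end
      any(gap >= 0L & gap <= params$d_near_j)
    }, TRUE)
    d_segs <- d_segs[keep]
  }
  segs <- c(segs, d_segs)

  # --- C genes ---------------------------------------------------------------
  if (!is.null(refs$C) && length(refs$C) > 0L) {
    for (strand in c("+", "-")) {
      segs <- c(segs, find_c(locus_seq, NULL, refs$C, refs$c_exons, params,
                             strand = strand))
    }
  }

  segs <- resolve_overlaps(segs)
  genes <- segments_to_tibble(segs) |>
    arrange(.data$start) |>
    assign_clusters()
  if (nrow(genes) > 0L) {
    genes <- genes |>
      group_by(.data$type) |>
      arrange(.data$start, .by_group = TRUE) |>
      mutate(gene_id = sprintf("%s%03d", .data$type, row_number())) |>
      ungroup() |>
      arrange(.data$start)
  }

  # --- V subgroups + naming --------------------------------------------------
  subgroups <- NULL
  tree <- NULL
  v_tbl <- genes |> filter(.data$type == "V", !is.na(.data$exon_nt))
  if (!group) {
    v_tbl <- v_tbl[0, ]
  }
  if (nrow(v_tbl) >= 2L) {
    vseqs <- stats::setNames(v_tbl$exon_nt, v_tbl$gene_id)
    idm <- pairwise_identity(vseqs)
    if (nrow(v_tbl) >= 3L) tree <- nj_tree((100 - idm) / 100)
    subgroups <- assign_subgroups(
      idm, tree = if (tree_override) tree else NULL,
      threshold = subgroup_threshold
    )
  } else if (nrow(v_tbl) == 1L) {
    subgroups <- tibble(id = v_tbl$gene_id, subgroup = 1L, provenance = "threshold")
  }

  prefix <- sub("/.*$", "", locus_name)
  if (!startsWith(prefix, "TR")) prefix <- "TR"
  locus_order <- genes |>
    transmute(id = .data$gene_id, type = .data$type, position = .data$start,
              cluster = .data$cluster)
  names_tbl <- if (nrow(genes) > 0L) {
    name_segments(subgroups, tree = tree,
                  reference_names = refs$reference_names %||% NULL,
                  locus_order = locus_order, locus_prefix = prefix)
  } else tibble(id = character(), name = character(), provenance = character())
  genes <- genes |>
    left_join(names_tbl |> select(gene_id = "id", name = "name"), by = "gene_id") |>
    left_join(
      (subgroups %||% tibble(id = character(), subgroup = integer())) |>
        select(gene_id = "id", subgroup = "subgroup"),
      by = "gene_id"
    )

  features <- report_features(segs, genes, seq_id)
  counts <- genes |> count(.data$type, .data$functionality)
  structure(
    list(
      locus_name = locus_name, seq_id = seq_id,
      annotations = genes, features = features, counts = counts,
      organization = organization_string(genes),
      span_kb = summarize_span(genes),
      rss_summary = rss_mutation_summary(genes),
      subgroups = subgroups, tree = tree, params = params
    ),
    class = "tr_locus_report"
  )
}

report_features <- function(segs, genes, seq_id) {
  if (length(segs) == 0L) return(empty_features())
  rows <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    g <- genes[genes$start == s$start & genes$end == s$end & genes$type == s$type, ]
    gid <- if (nrow(g) > 0L) g$gene_id[1] else sprintf("seg%03d", i)
    gname <- if (nrow(g) > 0L) g$name[1] else NA_character_
    gfun <- if (nrow(g) > 0L) g$functionality[1] else NA_character_
    gsub <- if (nrow(g) > 0L && !is.na(g$subgroup[1])) as.character(g$subgroup[1]) else NA_character_
    gdef <- if (nrow(g) > 0L) g$defects[1] else NA_character_
    sub_feats <- s$features
    rows[[i]] <- bind_rows(
      tibble(seqid = seq_id, type = "gene", start = s$start, end = s$end,
             strand = s$strand, ID = gid, Parent = NA_character_, name = gname,
             functionality = gfun, defects = gdef, subgroup = gsub,
             score = NA_real_),
      tibble(seqid = seq_id, type = sub_feats$feature,
             start = sub_feats$start, end = sub_feats$end, strand = s$strand,
             ID = paste0(gid, ".", sub_feats$feature, ".", seq_len(nrow(sub_feats))),
             Parent = gid, name = NA_character_, functionality = NA_character_,
             defects = NA_character_, subgroup = NA_character_, score = NA_real_)
    )
  }
  normalize_features(list_rbind(rows))
}

#' Annotate several loci of a genome
#'
#' Extracts each configured locus in transcriptional orientation and runs
#' [annotate_locus()] independently (no cross-locus state).
#'
#' @param store named sequences from [load_sequences()] (or a FASTA path).
#' @param loci locus definitions from [read_locus_config()].
#' @param refs reference bundle, see [annotate_locus()].
#' @param params an [annotate_params()].
#' @param ... passed on to [annotate_locus()].
#' @return named list of `tr_locus_report`, one per locus.
#' @export
annotate_genome <- function(store, loci, refs, params = annotate_params(), ...) {
  if (is.character(store) && length(store) == 1L && file.exists(store)) {
    store <- load_sequences(store)
  }
  out <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    seq <- extract_locus(store, locus)
    out[[locus$locus_name]] <- annotate_locus(
      seq, refs, params, locus_name = locus$locus_name,
      seq_id = locus$seq_id, ...
    )
  }
  out
}

#' Tag V genes of a nested TRA/D locus by sub-locus
#'
#' Votes each V gene by its best alignment identity against a TRA and a TRD
#' reference set: near-equal best hits (within `margin` percentage points)
#' are tagged `shared`; a clear winner tags `A` or `D`. V genes lying inside
#' the embedded D-J-C cluster interval are tagged `D` positionally,
#' regardless of the vote.
#'
#' @param v_genes annotation tibble rows of type V (needs `gene_id`,
#'   `exon_nt`, `start`, `end`).
#' @param refs_a,refs_d named character vectors of TRA / TRD V references.
#' @param djc_interval optional `c(start, end)` of the embedded D-J-C cluster.
#' @param margin identity margin (percentage points) for the shared call.
#' @return tibble: `gene_id`, `tag` (`A`/`D`/`shared`), `provenance`,
#'   `a_identity`, `d_identity`.
#' @export
shared_v_assignment <- function(v_genes, refs_a, refs_d, djc_interval = NULL,
                                margin = 5) {
  best_identity <- function(seq, refs) {
    if (length(refs) == 0L || is.na(seq)) return(NA_real_)
    max(vapply(refs, function(r) {
      al <- align_ref_in_window(r, seq)
      al$identity
    }, 0))
  }
  out <- vector("list", nrow(v_genes))
  for (i in seq_len(nrow(v_genes))) {
    a_id <- best_identity(v_genes$exon_nt[i], refs_a)
    d_id <- best_identity(v_genes$exon_nt[i], refs_d)
    positional <- !is.null(djc_interval) &&
      v_genes$start[i] >= djc_interval[1] && v_genes$end[i] <= djc_interval[2]
    tag <- if (positional) {
      "D"
    } else if (is.na(a_id) || is.na(d_id)) {
      if (is.na(d_id)) "A" else "D"
    } else if (abs(a_id - d_id) <= margin) {
      "shared"
    } else if (a_id > d_id) "A" else "D"
    out[[i]] <- tibble(
      gene_id = v_genes$gene_id[i], tag = tag,
      provenance = if (positional) "positional" else "vote",
      a_identity = a_id, d_identity = d_id
    )
  }
  list_rbind(out)
}

#' @export
print.tr_locus_report <- function(x, ...) {
  cat("<tr_locus_report> ", x$locus_name, " (", x$seq_id, ")\n", sep = "")
  cat("  genes: ", nrow(x$annotations), "  span: ", x$span_kb, " kb\n", sep = "")
  if (nrow(x$annotations) > 0L) {
    tab <- x$annotations |> count(.data$type)
    cat("  ", paste(sprintf("%s=%d", tab$type, tab$n), collapse = ", "), "\n", sep = "")
    cat("  organization: ", x$organization, "\n", sep = "")
    ftab <- x$annotations |> count(.data$functionality)
    cat("  functionality: ",
        paste(sprintf("%s=%d", ftab$functionality, ftab$n), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write a locus report to GFF3/BED
#'
#' @param report a `tr_locus_report`.
#' @param path GFF3 output path (BED companion written alongside).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "tr_locus_report"))
  write_annotations(report$features, path)
}
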