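#' Parse or build a locus architecture specification
#'
#' An architecture is an ordered list of gene blocks written
#' `"V(28)-D(1)-J(6)-C(1)-D(1)-J(9)-C(1)-Vrev(1)"`: segment type, optional
#' lower-case sub-locus tag (`a`, `d`, `ad` for TRA/TRD/shared blocks of the
#' nested TRA/D locus), optional `rev` for reverse-orientation blocks, and the
#' block gene count. Spacing gives the uniform intergenic-distance bounds in
#' nt; `gc` the background GC fraction.
#'
#' @param organization architecture string, or a blocks tibble with columns
#'   `type`, `tag`, `strand`, `count`.
#' @param spacing length-2 numeric, uniform intergenic spacing bounds (nt).
#' @param gc background GC fraction.
#' @param locus_type which locus the gene scaffolds should emulate
#'   (`"TRB"`, `"TRG"`, `"TRA/D"`); inferred from tags/blocks when `NULL`.
#' @return an object of class `tr_architecture`.
#' @export
architecture_spec <- function(organization, spacing = c(300, 3000), gc = 0.42,
                              locus_type = NULL) {
  if (is.character(organization) && length(organization) == 1L) {
    toks <- strsplit(organization, "-", fixed = TRUE)[[1]]
    m <- str_match(toks, "^([VDJC])([a-z]*)\\((\\d+)\\)$")
    if (anyNA(m[, 1])) {
      stop("unparseable architecture token(s): ",
           paste(toks[is.na(m[, 1])], collapse = ", "))
    }
    letters <- m[, 3]
    rev <- grepl("rev$", letters)
    tag <- sub("rev$", "", letters)
    blocks <- tibble(
      type = m[, 2],
      tag = ifelse(nzchar(tag), tag, NA_character_),
      strand = ifelse(rev, "-", "+"),
      count = as.integer(m[, 4])
    )
  } else {
    blocks <- as_tibble(organization)
    if (!"tag" %in% names(blocks)) blocks$tag <- NA_character_
    if (!"strand" %in% names(blocks)) blocks$strand <- "+"
  }
  stopifnot(all(blocks$type %in% c("V", "D", "J", "C")), all(blocks$count >= 0L))
  if (nrow(blocks) == 0L) stop("architecture needs at least one block")
  if (is.null(locus_type)) {
    locus_type <- if (any(blocks$tag %in% c("a", "d", "ad"), na.rm = TRUE)) {
      "TRA/D"
    } else if (any(blocks$type == "D")) "TRB" else "TRG"
  }
  structure(
    list(blocks = blocks, spacing = as.numeric(spacing), gc = gc,
         locus_type = locus_type),
    class = "tr_architecture"
  )
}

#' @export
format.tr_architecture <- function(x, ...) {
  with(x$blocks, paste(sprintf(
    "%s%s%s(%d)", type, ifelse(is.na(tag), "", tag),
    ifelse(strand == "-", "rev", ""), count
  ), collapse = "-"))
}

#' @export
print.tr_architecture <- function(x, ...) {
  cat("<tr_architecture> [", x$locus_type, "] ", format(x), "\n", sep = "")
  invisible(x)
}

#' Published locus organizations
#'
#' Returns the organization of the greater horseshoe bat TR loci as an
#' architecture spec: TRB with its two D-J-C clusters and one
#' reverse-oriented V downstream of the second C; TRG as two identical
#' V(7)-J(4)-C(1) clusters; the nested TRA/D locus with its shared V blocks,
#' embedded single-D D-J-C cluster and reversed TRDV.
#'
#' @param locus_name `"TRB"`, `"TRG"` or `"TRA/D"`.
#' @param ... passed to [architecture_spec()] (e.g. `spacing`).
#' @return a `tr_architecture`.
#' @export
locus_architecture <- function(locus_name = c("TRB", "TRG", "TRA/D"), ...) {
  locus_name <- match.arg(locus_name)
  org <- switch(locus_name,
    "TRB" = "V(28)-D(1)-J(6)-C(1)-D(1)-J(9)-C(1)-Vrev(1)",
    "TRG" = "V(7)-J(4)-C(1)-V(7)-J(4)-C(1)",
    "TRA/D" = paste0("Va(55)-Vad(10)-Vd(1)-Va(8)-Vd(1)-Va(2)-Vd(1)-Va(4)-",
                     "Vd(2)-Dd(1)-Jd(4)-Cd(1)-Vdrev(1)-Ja(60)-Ca(1)")
  )
  architecture_spec(org, locus_type = locus_name, ...)
}

DEFECT_CODES <- c(
  "missing_rss", "defective_rss", "missing_leader", "broken_donor",
  "broken_acceptor", "stop_codon", "frameshift", "missing_init",
  "length_out_of_range", "missing_motif", "missing_conserved_residue"
)

#' Defect and divergence model for the synthetic generator
#'
#' Injection probabilities per defect code (scalar, or a vector named by
#' segment type such as `c(J = 1)` to restrict injection to one type), the RSS
#' mutation model (independent per-position substitution at `rss_rate` over
#' the 13 non-core heptamer/nonamer positions, count capped at
#' `rss_max_mismatches`), and the seeded-divergence rates used to derive
#' family founders and gene copies from the neutral scaffolds.
#'
#' @param ... defect-code probabilities, e.g. `stop_codon = 0.1` or
#'   `stop_codon = c(J = 1)`.
#' @param rss_rate per-position RSS substitution rate.
#' @param rss_max_mismatches cap on planted per-RSS mutation counts.
#' @param founder_divergence substitution rate scaffold -> family founder.
#' @param member_divergence substitution rate founder -> V gene copy.
#' @param j_divergence substitution rate J scaffold -> J gene copy.
#' @param c_divergence substitution rate C scaffold -> C gene copy.
#' @param new_family_prob probability that the next V gene founds a new family.
#' @return an object of class `tr_defect_model`.
#' @export
defect_model <- function(..., rss_rate = 0.1, rss_max_mismatches = 6L,
                         founder_divergence = 0.3, member_divergence = 0.05,
                         j_divergence = 0.1, c_divergence = 0.03,
                         new_family_prob = 0.8) {
  rates <- list(...)
  bad <- setdiff(names(rates), DEFECT_CODES)
  if (length(bad)) stop("unknown defect code(s): ", paste(bad, collapse = ", "))
  for (r in rates) stopifnot(all(r >= 0), all(r <= 1))
  structure(
    list(rates = rates, rss_rate = rss_rate,
         rss_max_mismatches = as.integer(rss_max_mismatches),
         founder_divergence = founder_divergence,
         member_divergence = member_divergence,
         j_divergence = j_divergence, c_divergence = c_divergence,
         new_family_prob = new_family_prob),
    class = "tr_defect_model"
  )
}

defect_prob <- function(model, code, type) {
  r <- model$rates[[code]]
  if (is.null(r)) return(0)
  if (is.null(names(r))) return(unname(r[1]))
  if (type %in% names(r)) unname(r[[type]]) else 0
}

draw_defects <- function(model, type) {
  applicable <- switch(type,
    V = c("missing_rss", "defective_rss", "missing_leader", "broken_donor",
          "broken_acceptor", "stop_codon", "frameshift", "missing_init",
          "length_out_of_range", "missing_conserved_residue"),
    D = c("missing_rss", "defective_rss"),
    J = c("missing_rss", "defective_rss", "broken_donor", "stop_codon",
          "frameshift", "missing_motif", "length_out_of_range"),
    C = c("broken_donor", "broken_acceptor", "stop_codon", "frameshift")
  )
  hit <- vapply(applicable, function(code) {
    stats::runif(1L) < defect_prob(model, code, type)
  }, TRUE)
  applicable[hit]
}

# --- cassette builders (local 1-based coordinates, gene orientation) ---------

new_parts <- function() list(labels = character(), seqs = character())

add_part <- function(parts, label, seq) {
  parts$labels <- c(parts$labels, label)
  parts$seqs <- c(parts$seqs, seq)
  parts
}

finish_cassette <- function(parts, span_labels) {
  lens <- nchar(parts$seqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  keep <- !is.na(parts$labels) & lens > 0L
  features <- tibble(feature = parts$labels[keep],
                     start = starts[keep], end = ends[keep])
  in_span <- features$feature %in% span_labels
  list(
    cassette = paste(parts$seqs, collapse = ""),
    features = features,
    span = c(start = min(features$start[in_span]), end = max(features$end[in_span]))
  )
}

delete_nt <- function(seq, pos, n = 1L) {
  paste0(substr(seq, 1L, pos - 1L), substr(seq, pos + n, nchar(seq)))
}

build_v_cassette <- function(founder, model, defects) {
  leader <- paste0(founder$l_part1, founder$l_part2)
  leader <- mutate_coding(leader, model$member_divergence, anchor_nt = 1:3)
  l_part1 <- substr(leader, 1L, L_PART1_LEN)
  l_part2 <- substr(leader, L_PART1_LEN + 1L, nchar(leader))
  intron <- mutate_intron(founder$intron, model$member_divergence)
  anchor_nt <- as.vector(vapply(unname(V_CONSERVED),
                                function(c) (3L * c - 2L):(3L * c), integer(3)))
  v_exon <- mutate_coding(founder$v_exon, model$member_divergence, anchor_nt = anchor_nt)
  rss <- draw_rss(23L, model$rss_rate, model$rss_max_mismatches)
  rss_mm <- rss$mismatches
  leader_ok <- TRUE

  if ("missing_init" %in% defects) substr(l_part1, 2L, 2L) <- "C"
  if ("broken_donor" %in% defects) substr(intron, 1L, 1L) <- "A"
  if ("broken_acceptor" %in% defects) {
    substr(intron, nchar(intron), nchar(intron)) <- "C"
  }
  if ("missing_leader" %in% defects) {
    l_part1 <- random_dna(nchar(l_part1))
    intron <- random_dna(nchar(intron))
    l_part2 <- random_dna(nchar(l_part2))
    leader_ok <- FALSE
  }
  if ("missing_conserved_residue" %in% defects) {
    v_exon <- set_codon(v_exon, V_CONSERVED[["first_cys"]], "GCC")
  }
  if ("stop_codon" %in% defects) {
    pool <- setdiff(5:100, c(unname(V_CONSERVED), 42:71))
    v_exon <- set_codon(v_exon, sample(pool, 1L), sample(STOP_CODONS, 1L))
  }
  if ("length_out_of_range" %in% defects) {
    v_exon <- delete_nt(v_exon, 3L * 42L - 2L, 90L)  # codons 42-71, in frame
  }
  if ("frameshift" %in% defects) {
    v_exon <- delete_nt(v_exon, 3L * 50L, 1L)
  }
  if ("missing_rss" %in% defects) {
    abl <- ablated_rss_elements()
    rss$heptamer <- abl$heptamer; rss$nonamer <- abl$nonamer
    rss_mm <- NA_integer_
  }
  if ("defective_rss" %in% defects) {
    substr(rss$heptamer, 2L, 2L) <- "G"  # break the CAC core
    rss_mm <- NA_integer_
  }

  parts <- new_parts()
  if (leader_ok) {
    parts <- add_part(parts, "L-PART1", l_part1)
    parts <- add_part(parts, "L-INTRON", intron)
    parts <- add_part(parts, "L-PART2", l_part2)
  } else {
    parts <- add_part(parts, NA_character_, paste0(l_part1, intron, l_part2))
  }
  parts <- add_part(parts, "V-EXON", v_exon)
  parts <- add_part(parts, "RSS-HEPTAMER", rss$heptamer)
  parts <- add_part(parts, "RSS-SPACER", rss$spacer)
  parts <- add_part(parts, "RSS-NONAMER", rss$nonamer)
  span_from <- if (leader_ok) "L-PART1" else "V-EXON"
  span_to <- if ("missing_rss" %in% defects) "V-EXON" else "RSS-NONAMER"
  out <- finish_cassette(parts, span_labels = unique(c(
    span_from, "V-EXON", if (span_to != "V-EXON") c("RSS-HEPTAMER", "RSS-SPACER", "RSS-NONAMER")
  )))
  out$meta <- list(rss_mismatches = rss_mm)
  out
}

build_j_cassette <- function(scaffold_region, model, defects) {
  region <- mutate_coding(scaffold_region, model$j_divergence,
                          anchor_nt = as.vector(vapply(J_MOTIF_CODONS,
                            function(c) (3L * c - 2L):(3L * c), integer(3))))
  rss <- draw_rss(12L, model$rss_rate, model$rss_max_mismatches)
  rss_mm <- rss$mismatches
  donor <- DONOR_CONSENSUS

  if ("missing_motif" %in% defects) {
    region <- set_codon(region, J_MOTIF_CODONS, rep("CCT", 4L))
  }
  if ("stop_codon" %in% defects) {
    region <- set_codon(region, sample(setdiff(2:18, J_MOTIF_CODONS), 1L),
                        sample(STOP_CODONS, 1L))
  }
  if ("frameshift" %in% defects) {
    region <- delete_nt(region, 8L, 1L)
  }
  if ("length_out_of_range" %in% defects) {
    region <- delete_nt(region, 13L, 18L)  # codons 5-10: region shrinks below range
  }
  if ("broken_donor" %in% defects) substr(donor, 1L, 1L) <- "A"
  if ("missing_rss" %in% defects) {
    abl <- ablated_rss_elements()
    rss$heptamer <- abl$heptamer; rss$nonamer <- abl$nonamer
    rss_mm <- NA_integer_
  }
  if ("defective_rss" %in% defects) {
    substr(rss$heptamer, 2L, 2L) <- "G"
    rss_mm <- NA_integer_
  }

  parts <- new_parts()
  # 5' RSS: elements reverse-complemented on the gene strand, nonamer first
  parts <- add_part(parts, "RSS-NONAMER", revcomp(rss$nonamer))
  parts <- add_part(parts, "RSS-SPACER", revcomp(rss$spacer))
  parts <- add_part(parts, "RSS-HEPTAMER", revcomp(rss$heptamer))
  parts <- add_part(parts, "J-REGION", region)
  parts <- add_part(parts, "J-DONOR", substr(donor, 1L, 2L))
  parts <- add_part(parts, NA_character_, substr(donor, 3L, nchar(donor)))
  span_labels <- c(
    if (!"missing_rss" %in% defects) c("RSS-NONAMER", "RSS-SPACER", "RSS-HEPTAMER"),
    "J-REGION"
  )
  out <- finish_cassette(parts, span_labels = span_labels)
  out$meta <- list(rss_mismatches = rss_mm)
  out
}

build_d_cassette <- function(core, model, defects) {
  rss5 <- draw_rss(12L, model$rss_rate, model$rss_max_mismatches)
  rss3 <- draw_rss(23L, model$rss_rate, model$rss_max_mismatches)
  mm5 <- rss5$mismatches; mm3 <- rss3$mismatches
  side <- if (length(intersect(defects, c("missing_rss", "defective_rss")))) {
    sample(c("5", "3"), 1L)
  } else NA_character_
  if ("missing_rss" %in% defects) {
    abl <- ablated_rss_elements()
    if (side == "5") {
      rss5$heptamer <- abl$heptamer; rss5$nonamer <- abl$nonamer; mm5 <- NA_integer_
    } else {
      rss3$heptamer <- abl$heptamer; rss3$nonamer <- abl$nonamer; mm3 <- NA_integer_
    }
  }
  if ("defective_rss" %in% defects) {
    if (side == "5") { substr(rss5$heptamer, 2L, 2L) <- "G"; mm5 <- NA_integer_ }
    else { substr(rss3$heptamer, 2L, 2L) <- "G"; mm3 <- NA_integer_ }
  }
  parts <- new_parts()
  parts <- add_part(parts, "RSS5-NONAMER", revcomp(rss5$nonamer))
  parts <- add_part(parts, "RSS5-SPACER", revcomp(rss5$spacer))
  parts <- add_part(parts, "RSS5-HEPTAMER", revcomp(rss5$heptamer))
  parts <- add_part(parts, "D-REGION", core)
  parts <- add_part(parts, "RSS3-HEPTAMER", rss3$heptamer)
  parts <- add_part(parts, "RSS3-SPACER", rss3$spacer)
  parts <- add_part(parts, "RSS3-NONAMER", rss3$nonamer)
  out <- finish_cassette(parts, span_labels = unique(parts$labels[!is.na(parts$labels)]))
  out$meta <- list(rss5_mismatches = mm5, rss3_mismatches = mm3)
  out
}

build_c_cassette <- function(scaffold, model, defects) {
  coding <- mutate_coding(scaffold$coding, model$c_divergence)
  if ("stop_codon" %in% defects) {
    coding <- set_codon(coding, sample(2:(nchar(coding) %/% 3L - 1L), 1L),
                        sample(STOP_CODONS, 1L))
  }
  exons <- scaffold$exons
  exon_seqs <- map_chr(seq_len(nrow(exons)), function(i) {
    if (exons$translated[i]) {
      substr(coding, exons$start[i], exons$end[i])
    } else {
      mutate_free(scaffold$utr, model$c_divergence)
    }
  })
  if ("frameshift" %in% defects) exon_seqs[1] <- delete_nt(exon_seqs[1], 10L, 1L)
  introns <- vapply(scaffold$introns, mutate_intron, "", rate = model$c_divergence)
  if ("broken_donor" %in% defects) substr(introns[1], 1L, 1L) <- "A"
  if ("broken_acceptor" %in% defects) {
    substr(introns[1], nchar(introns[1]), nchar(introns[1])) <- "C"
  }
  parts <- new_parts()
  parts <- add_part(parts, NA_character_, "AG")  # acceptor of the J-C intron
  for (i in seq_len(nrow(exons))) {
    parts <- add_part(parts, exons$label[i], exon_seqs[i])
    if (i <= length(introns)) parts <- add_part(parts, NA_character_, introns[i])
  }
  out <- finish_cassette(parts, span_labels = exons$label)
  out$meta <- list(c_type = scaffold$type)
  out
}

# --- locus generation --------------------------------------------------------

#' Generate a synthetic TR locus with known ground truth
#'
#' Plants V, D, J and C genes in random background DNA following an
#' architecture spec. Every gene is derived from a neutral scaffold by seeded
#' divergence, satisfies its type's structural definition before defect
#' injection (leader with init codon and GT/AG splice sites, conserved
#' V-domain residues, RSS with controlled mutation counts, J motif and donor,
#' C exon chains), and carries its intended functionality class, derived from
#' the injected defect codes through the same severity table the classifier
#' uses. Reverse-oriented blocks are reverse-complemented in place.
#'
#' @param arch a [architecture_spec()] / [locus_architecture()].
#' @param defects a [defect_model()].
#' @param seed integer seed; generation is reproducible given the seed.
#' @param seq_id sequence id of the generated locus.
#' @param max_length error if the locus would exceed this many nt.
#' @return object of class `tr_synthetic_locus`: `sequence` (named character),
#'   `genes` (truth tibble: type, tag, family, span, strand, intended
#'   functionality, defect codes, RSS mutation counts), `features` (per-part
#'   sub-intervals, GFF3-ready), `refs` (reference bundle for the pipeline:
#'   family-founder V exons and leaders, J scaffold, C coding sequences with
#'   exon sidecar table, D cores), and `params`.
#' @export
generate_locus <- function(arch, defects = defect_model(), seed = 1L,
                           seq_id = NULL, max_length = 5e6) {
  stopifnot(inherits(arch, "tr_architecture"), inherits(defects, "tr_defect_model"))
  scaff <- tr_scaffolds(arch$locus_type)
  if (is.null(seq_id)) {
    seq_id <- paste0("synthetic_", gsub("/", "", arch$locus_type))
  }
  with_local_seed(seed, {
    plan <- arch$blocks |>
      mutate(block = row_number()) |>
      tidyr::uncount(.data$count) |>
      mutate(idx = row_number())
    if (nrow(plan) == 0L) stop("architecture contains no genes")

    # V family structure per tag pool; founders derived lazily from the scaffold
    founders <- new.env(parent = emptyenv())
    v_founder <- function(tag, fam) {
      key <- paste0(tag, "_", fam)
      if (is.null(founders[[key]])) {
        leader <- paste0(scaff$V$l_part1, scaff$V$l_part2)
        leader <- mutate_coding(leader, defects$founder_divergence, anchor_nt = 1:3)
        anchor_nt <- as.vector(vapply(unname(V_CONSERVED),
                                      function(c) (3L * c - 2L):(3L * c), integer(3)))
        founders[[key]] <- list(
          l_part1 = substr(leader, 1L, L_PART1_LEN),
          l_part2 = substr(leader, L_PART1_LEN + 1L, nchar(leader)),
          intron = mutate_intron(scaff$V$intron, defects$founder_divergence),
          v_exon = mutate_coding(scaff$V$v_exon, defects$founder_divergence,
                                 anchor_nt = anchor_nt)
        )
      }
      founders[[key]]
    }
    fam_counter <- new.env(parent = emptyenv())
    plan$family <- NA_integer_
    for (i in seq_len(nrow(plan))) {
      if (plan$type[i] != "V") next
      pool <- paste0("pool_", plan$tag[i] %||% "")
      cur <- fam_counter[[pool]] %||% 0L
      if (cur == 0L || stats::runif(1L) < defects$new_family_prob) {
        cur <- cur + 1L
        fam_counter[[pool]] <- cur
      }
      plan$family[i] <- cur
    }

    type_counter <- integer(0)
    d_index <- 0L
    built <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      type <- plan$type[i]
      tag <- plan$tag[i]
      inj <- draw_defects(defects, type)
      cas <- switch(type,
        V = build_v_cassette(v_founder(tag %||% "", plan$family[i]), defects, inj),
        J = build_j_cassette(scaff$J, defects, inj),
        D = {
          d_index <- d_index + 1L
          core <- scaff$D[((d_index - 1L) %% length(scaff$D)) + 1L]
          build_d_cassette(core, defects, inj)
        },
        C = {
          ctype <- if (arch$locus_type == "TRA/D") {
            if (identical(tag, "d")) "TRD" else "TRA"
          } else gsub("/", "", arch$locus_type)
          build_c_cassette(scaff$C[[ctype]], defects, inj)
        }
      )
      n_prev <- type_counter[type]
      type_counter[type] <- if (is.na(n_prev)) 1L else n_prev + 1L
      cas$gene_id <- sprintf("%s%03d", type, type_counter[type])
      cas$type <- type
      cas$tag <- tag
      cas$family <- plan$family[i]
      cas$strand <- plan$strand[i]
      cas$defect_codes <- inj
      built[[i]] <- cas
    }

    total <- sum(vapply(built, function(b) nchar(b$cassette), 0)) +
      (nrow(plan) + 1L) * mean(arch$spacing)
    if (total > max_length) {
      stop("architecture requires ~", round(total), " nt > max_length ", max_length)
    }

    chunks <- character(0)
    offset <- 0L
    genes <- vector("list", nrow(plan))
    feats <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      gap <- as.integer(round(stats::runif(1L, arch$spacing[1], arch$spacing[2])))
      chunks <- c(chunks, random_dna(gap, arch$gc))
      offset <- offset + gap
      b <- built[[i]]
      cas <- b$cassette
      fe <- b$features
      span <- b$span
      len <- nchar(cas)
      if (b$strand == "-") {
        cas <- revcomp(cas)
        mi <- mirror_interval(span[["start"]], span[["end"]], len)
        span <- c(start = mi[["start"]], end = mi[["end"]])
        fm <- t(vapply(seq_len(nrow(fe)), function(k) {
          mirror_interval(fe$start[k], fe$end[k], len)
        }, c(start = 0L, end = 0L)))
        fe$start <- fm[, "start"]; fe$end <- fm[, "end"]
      }
      chunks <- c(chunks, cas)
      intended <- severity_call(b$type, b$defect_codes)$call
      genes[[i]] <- tibble(
        gene_id = b$gene_id, type = b$type, tag = b$tag %||% NA_character_,
        family = b$family,
        start = offset + span[["start"]], end = offset + span[["end"]],
        strand = b$strand,
        intended_functionality = intended,
        defects = if (length(b$defect_codes)) paste(b$defect_codes, collapse = ",") else NA_character_,
        rss_mismatches = b$meta$rss_mismatches %||% NA_integer_,
        rss5_mismatches = b$meta$rss5_mismatches %||% NA_integer_,
        rss3_mismatches = b$meta$rss3_mismatches %||% NA_integer_
      )
      feats[[i]] <- bind_rows(
        tibble(feature = "gene", start = span[["start"]], end = span[["end"]]),
        b$features
      ) |>
        mutate(
          start = .data$start + offset, end = .data$end + offset,
          seqid = seq_id, strand = b$strand,
          ID = ifelse(.data$feature == "gene", b$gene_id,
                      paste0(b$gene_id, ".", .data$feature, ".", row_number())),
          Parent = ifelse(.data$feature == "gene", NA_character_, b$gene_id),
          name = b$gene_id,
          functionality = ifelse(.data$feature == "gene", intended, NA_character_),
          defects = ifelse(.data$feature == "gene",
                           if (length(b$defect_codes)) paste(b$defect_codes, collapse = ",") else NA_character_,
                           NA_character_)
        )
      offset <- offset + len
    }
    gap <- as.integer(round(stats::runif(1L, arch$spacing[1], arch$spacing[2])))
    chunks <- c(chunks, random_dna(gap, arch$gc))
    sequence <- paste(chunks, collapse = "")

    genes <- list_rbind(genes)
    genes$start <- as.integer(unname(genes$start))
    genes$end <- as.integer(unname(genes$end))
    features <- list_rbind(feats) |>
      mutate(start = as.integer(unname(.data$start)),
             end = as.integer(unname(.data$end))) |>
      mutate(type = .data$feature) |>
      select(-"feature") |>
      normalize_features()

    refs <- synthetic_refs(scaff, founders, arch)
    structure(
      list(
        sequence = stats::setNames(sequence, seq_id),
        genes = genes, features = features, refs = refs,
        params = list(arch = arch, defects = defects, seed = seed)
      ),
      class = "tr_synthetic_locus"
    )
  })
}

synthetic_refs <- function(scaff, founders, arch) {
  fk <- ls(founders)
  v_refs <- character(0); v_leaders <- character(0)
  v_tags <- character(0)
  for (key in fk) {
    f <- founders[[key]]
    nm <- paste0("VF_", key)
    v_refs[nm] <- f$v_exon
    v_leaders[nm] <- paste0(f$l_part1, f$l_part2)
    v_tags[nm] <- sub("_\\d+$", "", key)
  }
  c_refs <- character(0)
  c_exons <- list()
  for (cn in names(scaff$C)) {
    s <- scaff$C[[cn]]
    full <- paste0(s$coding, s$utr %||% "")
    nm <- paste0("CREF_", cn)
    c_refs[nm] <- full
    c_exons[[nm]] <- s$exons |> mutate(ref = nm, .before = 1L)
  }
  list(
    V = v_refs, v_leaders = v_leaders, v_tags = v_tags,
    J = c(JREF = scaff$J),
    C = c_refs, c_exons = list_rbind(c_exons),
    D = stats::setNames(scaff$D, paste0("DREF", seq_along(scaff$D)))
  )
}

#' @export
print.tr_synthetic_locus <- function(x, ...) {
  cat("<tr_synthetic_locus> ", names(x$sequence), ": ",
      format(nchar(x$sequence), big.mark = ","), " nt, ",
      nrow(x$genes), " planted genes (",
      paste(sprintf("%s=%d", names(table(x$genes$type)), table(x$genes$type)),
            collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic locus to FASTA plus truth GFF3
#'
#' @param locus a [generate_locus()] result.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return named list of written paths, invisibly.
#' @export
write_synthetic_locus <- function(locus, dir, prefix = names(locus$sequence)) {
  stopifnot(inherits(locus, "tr_synthetic_locus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  gff <- file.path(dir, paste0(prefix, ".truth.gff3"))
  write_sequences(locus$sequence, fasta)
  write_annotations(locus$features, gff, bed = FALSE)
  invisible(list(fasta = fasta, gff3 = gff))
}
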