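# Neutral gene scaffolds for the synthetic-locus generator.
#
# Scaffolds are built in code from seeded draws of stop-free codons with the
# structural anchors of each gene type imposed (init codon, splice
# dinucleotides, conserved V-domain residues, J motif, G-rich D cores, exon
# chains). They are deliberately not copied from any germline database; family
# founders and gene copies are derived from them by seeded divergence.

STOP_CODONS <- c("TAA", "TAG", "TGA")

ALL_CODONS <- {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

sample_sense_codons <- function(n) {
  paste(sample(SENSE_CODONS, n, replace = TRUE), collapse = "")
}

# V-exon framework scheme (template codon positions; unique-numbering style):
# FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104, CDR3 stub 105+.
V_SCHEME <- list(
  fr1 = c(1L, 26L), cdr1 = c(27L, 38L), fr2 = c(39L, 55L),
  cdr2 = c(56L, 65L), fr3 = c(66L, 104L)
)
V_CONSERVED <- c(first_cys = 23L, trp = 41L, hydrophobic = 89L, second_cys = 104L)
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "Y", "C")

V_EXON_CODONS <- 107L      # 104 framework codons + 3-codon germline CDR3 stub
L_PART1_LEN <- 46L
L_PART2_LEN <- 11L
L_INTRON_LEN <- 87L
J_REGION_CODONS <- 19L     # 57 nt, inside the 51-66 bp range typical of J genes
J_MOTIF_CODONS <- 13:16    # [W/F]-[G/A]-X-G tetrapeptide, in frame from region start
DONOR_CONSENSUS <- "GTAAGT"

set_codon <- function(seq, codon_idx, value) {
  for (i in seq_along(codon_idx)) {
    substr(seq, 3L * codon_idx[i] - 2L, 3L * codon_idx[i]) <- value[i]
  }
  seq
}

random_intron <- function(len) {
  stopifnot(len >= 10L)
  paste0(DONOR_CONSENSUS, random_dna(len - 8L, gc = 0.4), "AG")
}

# C-gene exon plans: per-locus spliced coding length (aa * 3) cut into exons,
# plus an untranslated terminal exon where the locus type has one.
c_exon_plan <- function(locus_type) {
  switch(locus_type,
    "TRA" = list(aa = 136L, cuts = c(273L, 318L, 408L),
                 labels = c("EX1", "EX2", "EX3"), utr = "EX4UTR", utr_len = 80L),
    "TRD" = list(aa = 142L, cuts = c(285L, 330L, 426L),
                 labels = c("EX1", "EX2", "EX3"), utr = "EX4UTR", utr_len = 80L),
    "TRG" = list(aa = 163L, cuts = c(291L, 396L, 489L),
                 labels = c("EX1", "EX2", "EX3"), utr = NULL, utr_len = 0L),
    "TRB" = list(aa = 175L, cuts = c(288L, 306L, 413L, 525L),
                 labels = c("EX1", "EX2", "EX3", "EX4"), utr = NULL, utr_len = 0L),
    stop("unknown C plan: ", locus_type)
  )
}

D_CORES <- list(
  "TRB" = c("GGGACAGGGGGG", "GGGACAGGGGGACGG"),   # 12 and 15 bp, G-rich
  "TRD" = "GGGGATACGGGGGG"                        # 14 bp, G-rich
)

.scaffold_cache <- new.env(parent = emptyenv())

# Deterministic scaffolds; independent of the user's RNG stream.
tr_scaffolds <- function(locus_type = c("TRB", "TRG", "TRA/D")) {
  locus_type <- match.arg(locus_type)
  key <- gsub("/", "", locus_type)
  if (!is.null(.scaffold_cache[[key]])) return(.scaffold_cache[[key]])
  sc <- with_local_seed(604501L + nchar(key), {
    v_scaffold <- function() {
      leader <- paste0("ATG", sample_sense_codons(18L))  # 57 nt
      exon <- sample_sense_codons(V_EXON_CODONS)
      exon <- set_codon(exon, unname(V_CONSERVED), c("TGC", "TGG", "CTG", "TGT"))
      list(
        l_part1 = substr(leader, 1L, L_PART1_LEN),
        l_part2 = substr(leader, L_PART1_LEN + 1L, L_PART1_LEN + L_PART2_LEN),
        intron = random_intron(L_INTRON_LEN),
        v_exon = exon
      )
    }
    j_scaffold <- function() {
      region <- sample_sense_codons(J_REGION_CODONS)
      set_codon(region, J_MOTIF_CODONS, c("TTT", "GGA", "AAA", "GGA"))  # F G K G
    }
    c_scaffold <- function(ctype) {
      plan <- c_exon_plan(ctype)
      coding <- sample_sense_codons(plan$aa)
      starts <- c(1L, utils::head(plan$cuts, -1L) + 1L)
      exons <- tibble(
        label = plan$labels, start = starts, end = plan$cuts, translated = TRUE
      )
      utr <- NULL
      if (!is.null(plan$utr)) {
        utr <- random_dna(plan$utr_len, gc = 0.45)
        exons <- bind_rows(exons, tibble(
          label = plan$utr, start = plan$cuts[length(plan$cuts)] + 1L,
          end = plan$cuts[length(plan$cuts)] + plan$utr_len, translated = FALSE
        ))
      }
      introns <- vapply(seq_len(nrow(exons) - 1L), function(i) random_intron(100L + 25L * i), "")
      list(type = ctype, coding = coding, utr = utr, exons = exons, introns = introns)
    }
    ctypes <- switch(locus_type,
      "TRB" = "TRB", "TRG" = "TRG", "TRA/D" = c("TRA", "TRD"))
    list(
      locus_type = locus_type,
      V = v_scaffold(),
      J = j_scaffold(),
      D = if (locus_type == "TRB") D_CORES[["TRB"]] else D_CORES[["TRD"]],
      C = lapply(ctypes, c_scaffold)
    )
  })
  names(sc$C) <- vapply(sc$C, function(x) x$type, "")
  .scaffold_cache[[key]] <- sc
  sc
}

# --- seeded mutation helpers -------------------------------------------------

# substitute positions of an in-frame coding sequence at `rate`, never touching
# `anchor_nt` positions and never creating an in-frame stop codon
mutate_coding <- function(seq, rate, anchor_nt = integer()) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  chars <- seq_chars(seq)
  n <- length(chars)
  targets <- setdiff(which(stats::runif(n) < rate), anchor_nt)
  for (p in targets) {
    ci <- (p - 1L) %/% 3L            # 0-based codon index
    cs <- 3L * ci + 1L
    if (cs + 2L > n) next            # trailing partial codon: leave alone
    codon <- chars[cs:(cs + 2L)]
    for (alt in sample(setdiff(DNA_BASES, chars[p]))) {
      trial <- codon
      trial[p - cs + 1L] <- alt
      if (!paste(trial, collapse = "") %in% STOP_CODONS) {
        chars[p] <- alt
        break
      }
    }
  }
  paste(chars, collapse = "")
}

# substitute freely at `rate`, protecting the given positions
mutate_free <- function(seq, rate, protect = integer()) {
  if (rate <= 0 || nchar(seq) == 0L) return(seq)
  chars <- seq_chars(seq)
  targets <- setdiff(which(stats::runif(length(chars)) < rate), protect)
  for (p in targets) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  paste(chars, collapse = "")
}

mutate_intron <- function(seq, rate) {
  n <- nchar(seq)
  mutate_free(seq, rate, protect = c(1L, 2L, n - 1L, n))
}

# replacement elements for an ablated RSS: redrawn until unrecognizable
# (combined mutation count >= 12 against the canonical motifs), so an injected
# "missing" signal can never read as merely defective
ablated_rss_elements <- function() {
  repeat {
    h <- random_dna(7L)
    n <- random_dna(9L)
    if (hamming(h, RSS_HEPTAMER) + hamming(n, RSS_NONAMER) >= 12L) {
      return(list(heptamer = h, nonamer = n))
    }
  }
}

# draw one RSS in canonical orientation (heptamer + spacer + nonamer) with a
# truncated-binomial mutation count over the 13 non-core element positions
draw_rss <- function(spacer, rate, max_mm = 6L) {
  hep <- seq_chars(RSS_HEPTAMER)
  non <- seq_chars(RSS_NONAMER)
  mutable <- list(hep = 4:7, non = 1:9)
  n_pos <- length(mutable$hep) + length(mutable$non)
  repeat {
    n_mm <- stats::rbinom(1L, n_pos, rate)
    if (n_mm <= max_mm) break
  }
  if (n_mm > 0L) {
    picks <- sample(n_pos, n_mm)
    for (p in picks) {
      if (p <= length(mutable$hep)) {
        i <- mutable$hep[p]
        hep[i] <- sample(setdiff(DNA_BASES, hep[i]), 1L)
      } else {
        i <- mutable$non[p - length(mutable$hep)]
        non[i] <- sample(setdiff(DNA_BASES, non[i]), 1L)
      }
    }
  }
  list(
    heptamer = paste(hep, collapse = ""),
    spacer = random_dna(spacer, gc = 0.45),
    nonamer = paste(non, collapse = ""),
    mismatches = as.integer(n_mm)
  )
}
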