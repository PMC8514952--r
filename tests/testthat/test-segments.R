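# Small generated loci provide ground truth for the describers.
make_locus <- function(org, seed, model = defect_model(), spacing = c(150, 400),
                       locus_type = NULL) {
  generate_locus(architecture_spec(org, spacing = spacing, locus_type = locus_type),
                 model, seed = seed)
}

test_that("describe_v recovers exact planted V structure and residues", {
  syn <- make_locus("V(1)", seed = 21)
  seq <- unname(syn$sequence)
  cand <- homology_seed(seq, syn$refs$V)
  expect_equal(nrow(cand), 1L)
  seg <- describe_v(seq, cand[1, ], syn$refs)
  g <- syn$genes[1, ]
  expect_equal(seg$start, g$start)
  expect_equal(seg$end, g$end)
  expect_length(seg$defects, 0L)
  expect_true(all(seg$extra$conserved))
  # sub-features line up with the planted parts
  truth <- syn$features[syn$features$type != "gene", ]
  for (lab in c("L-PART1", "L-PART2", "V-EXON", "RSS-HEPTAMER", "RSS-NONAMER")) {
    t <- truth[truth$type == lab, ]
    f <- seg$features[seg$features$feature == lab, ]
    expect_equal(f$start, t$start, info = lab)
    expect_equal(f$end, t$end, info = lab)
  }
  # framework/CDR partition tiles the exon in order
  reg <- seg$features[seg$features$feature %in%
                        c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3-GERMLINE"), ]
  expect_equal(reg$feature, c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3-GERMLINE"))
  expect_true(all(diff(reg$start) > 0))
  expect_equal(reg$start[-1], reg$end[-nrow(reg)] + 1L)
  vex <- seg$features[seg$features$feature == "V-EXON", ]
  expect_equal(reg$start[1], vex$start)
  expect_equal(reg$end[nrow(reg)], vex$end)
})

test_that("an ablated leader donor is flagged but the exon still described", {
  syn <- make_locus("V(1)", seed = 22, model = defect_model(broken_donor = 1))
  seq <- unname(syn$sequence)
  cand <- homology_seed(seq, syn$refs$V)
  seg <- describe_v(seq, cand[1, ], syn$refs)
  expect_true("broken_donor" %in% seg$defects)
  vex_t <- syn$features[syn$features$type == "V-EXON", ]
  vex_f <- seg$features[seg$features$feature == "V-EXON", ]
  expect_equal(vex_f$start, vex_t$start)
  expect_equal(vex_f$end, vex_t$end)
  expect_equal(classify_segment(list(type = "V", defects = seg$defects))$call, "P")
})

test_that("V defect injections are read back as the intended codes", {
  cases <- list(
    list(code = "missing_init", seed = 31),
    list(code = "broken_acceptor", seed = 32),
    list(code = "missing_leader", seed = 33),
    list(code = "stop_codon", seed = 34),
    list(code = "missing_conserved_residue", seed = 35),
    list(code = "defective_rss", seed = 36),
    list(code = "missing_rss", seed = 37),
    list(code = "length_out_of_range", seed = 38),
    list(code = "frameshift", seed = 39)
  )
  for (cs in cases) {
    model <- defect_model()
    model$rates[[cs$code]] <- 1
    syn <- make_locus("V(1)", seed = cs$seed, model = model)
    seq <- unname(syn$sequence)
    cand <- homology_seed(seq, syn$refs$V)
    seg <- describe_v(seq, cand[1, ], syn$refs)
    expect_true(cs$code %in% seg$defects, info = cs$code)
  }
})

test_that("find_d reports RSS-flanked cores within the length bounds", {
  set.seed(51)
  core <- "GGGACAGGGG"
  cassette <- paste0(
    rc_oracle(paste0("CACAGTG", rand_dna(12), "ACAAAAACC")),
    core,
    paste0("CACAGTG", rand_dna(23), "ACAAAAACC")
  )
  seq <- paste0(rand_dna(500), cassette, rand_dna(500))
  segs <- find_d(seq)
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$extra$core_seq, core)
  expect_equal(segs[[1]]$extra$core[2] - segs[[1]]$extra$core[1] + 1L, 10L)
  expect_equal(segs[[1]]$extra$g_fraction, 0.7)
  expect_equal(segs[[1]]$start, 501L)

  # a 40-nt gap between the signals is no D gene
  wide <- paste0(
    rc_oracle(paste0("CACAGTG", rand_dna(12), "ACAAAAACC")),
    rand_dna(40),
    paste0("CACAGTG", rand_dna(23), "ACAAAAACC")
  )
  expect_length(find_d(paste0(rand_dna(300), wide, rand_dna(300))), 0L)
})

test_that("find_j anchors the region between 12-RSS and donor, with motif", {
  syn <- make_locus("J(1)", seed = 61)
  seq <- unname(syn$sequence)
  g <- syn$genes[1, ]
  segs <- find_j(seq, c(max(1L, g$start - 100L), min(nchar(seq), g$end + 100L)))
  expect_length(segs, 1L)
  seg <- segs[[1]]
  expect_equal(seg$start, g$start)
  expect_equal(seg$end, g$end)
  expect_match(seg$extra$motif, "^[WF][GA].G$")
  expect_equal(seg$extra$motif_frame, 1L)
  truth_reg <- syn$features[syn$features$type == "J-REGION", ]
  found_reg <- seg$features[seg$features$feature == "J-REGION", ]
  expect_equal(found_reg$start, truth_reg$start)
  expect_equal(found_reg$end, truth_reg$end)

  # ablated motif: candidate kept, flagged
  syn2 <- make_locus("J(1)", seed = 62, model = defect_model(missing_motif = 1))
  g2 <- syn2$genes[1, ]
  segs2 <- find_j(unname(syn2$sequence), c(g2$start - 100L, g2$end + 100L))
  expect_length(segs2, 1L)
  expect_true("missing_motif" %in% segs2[[1]]$defects)
})

test_that("find_c recovers reference-guided exon chains exactly", {
  syn <- make_locus("C(1)", seed = 71, locus_type = "TRB")
  seq <- unname(syn$sequence)
  segs <- find_c(seq, NULL, syn$refs$C, syn$refs$c_exons)
  expect_length(segs, 1L)
  seg <- segs[[1]]
  truth <- syn$features[!syn$features$type %in% "gene", ]
  expect_equal(seg$features$feature, truth$type)
  expect_equal(seg$features$start, truth$start)
  expect_equal(seg$features$end, truth$end)
  expect_equal(seg$extra$translated_length, 175L)  # four-exon C chain
  expect_length(seg$defects, 0L)
  expect_error(find_c(seq, NULL, syn$refs$C, NULL), "exon-boundary table")
})

test_that("C splice ablations and coding defects are detected", {
  for (cs in list(c("broken_donor", 81), c("broken_acceptor", 82),
                  c("stop_codon", 83), c("frameshift", 84))) {
    model <- defect_model()
    model$rates[[cs[1]]] <- 1
    syn <- make_locus("C(1)", seed = as.integer(cs[2]), model = model)
    segs <- find_c(unname(syn$sequence), NULL, syn$refs$C, syn$refs$c_exons)
    expect_length(segs, 1L)
    expect_true(cs[1] %in% segs[[1]]$defects, info = cs[1])
  }
})

test_that("finders are strand-equivariant", {
  syn <- make_locus("V(1)-D(1)-J(1)-C(1)", seed = 91)
  seq <- unname(syn$sequence)
  L <- nchar(seq)
  rep_f <- annotate_locus(seq, syn$refs, group = FALSE)
  rep_r <- annotate_locus(rc_oracle(seq), syn$refs, group = FALSE)
  f <- rep_f$annotations[order(rep_f$annotations$start), ]
  r <- rep_r$annotations[order(-rep_r$annotations$end), ]
  expect_equal(nrow(f), nrow(r))
  expect_equal(r$type, f$type)
  expect_equal(L - r$end + 1L, f$start)
  expect_equal(L - r$start + 1L, f$end)
  expect_equal(r$strand, c("+" = "-", "-" = "+")[f$strand], ignore_attr = TRUE)
  expect_equal(r$functionality, f$functionality)
})

test_that("described V parts never overlap and splice sites are literal", {
  syn <- make_locus("V(3)", seed = 95)
  seq <- unname(syn$sequence)
  cand <- homology_seed(seq, syn$refs$V)
  for (i in seq_len(nrow(cand))) {
    seg <- describe_v(seq, cand[i, ], syn$refs)
    parts <- seg$features[seg$features$feature %in%
                            c("L-PART1", "L-INTRON", "L-PART2", "V-EXON"), ]
    parts <- parts[order(parts$start), ]
    expect_equal(parts$feature, c("L-PART1", "L-INTRON", "L-PART2", "V-EXON"))
    expect_true(all(parts$start[-1] > parts$end[-4]))
    intron <- parts[parts$feature == "L-INTRON", ]
    expect_equal(substr(seq, intron$start, intron$start + 1L), "GT")
    expect_equal(substr(seq, intron$end - 1L, intron$end), "AG")
  }
})
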