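test_that("architecture strings parse and format round-trip", {
  arch <- architecture_spec("V(28)-D(1)-J(6)-C(1)-D(1)-J(9)-C(1)-Vrev(1)")
  expect_equal(sum(arch$blocks$count[arch$blocks$type == "V"]), 29L)
  expect_equal(sum(arch$blocks$count[arch$blocks$type == "J"]), 15L)
  expect_equal(arch$blocks$strand[nrow(arch$blocks)], "-")
  expect_equal(format(arch), "V(28)-D(1)-J(6)-C(1)-D(1)-J(9)-C(1)-Vrev(1)")

  tagged <- architecture_spec("Va(2)-Vad(1)-Dd(1)")
  expect_equal(tagged$blocks$tag, c("a", "ad", "d"))
  expect_equal(tagged$locus_type, "TRA/D")

  expect_error(architecture_spec("V(2)-Q(1)"), "unparseable")
})

test_that("published organizations carry the reported block structure", {
  trb <- locus_architecture("TRB")
  tot <- tapply(trb$blocks$count, trb$blocks$type, sum)
  expect_equal(as.vector(tot[c("V", "D", "J", "C")]), c(29L, 2L, 15L, 2L))
  expect_equal(trb$blocks$strand[nrow(trb$blocks)], "-")  # final reversed V

  trg <- locus_architecture("TRG")
  expect_equal(nrow(trg$blocks), 6L)
  expect_identical(trg$blocks$count, rep(c(7L, 4L, 1L), 2))  # two identical clusters

  trad <- locus_architecture("TRA/D")
  expect_equal(sum(trad$blocks$count[trad$blocks$type == "D"]), 1L)
  expect_true(any(trad$blocks$tag == "ad", na.rm = TRUE))  # shared V block
  rev_v <- trad$blocks[trad$blocks$strand == "-", ]
  expect_equal(rev_v$type, "V")
  expect_equal(rev_v$tag, "d")  # the reversed V sits in the embedded cluster
})

test_that("generation is reproducible and matches the requested plan", {
  arch <- architecture_spec("V(2)-D(1)-J(3)-C(1)", spacing = c(100, 300))
  a <- generate_locus(arch, seed = 7)
  b <- generate_locus(arch, seed = 7)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$genes, b$genes)
  expect_equal(nrow(a$genes), 7L)
  expect_equal(unname(table(a$genes$type)[c("V", "D", "J", "C")]),
               c(2L, 1L, 3L, 1L), ignore_attr = TRUE)
  c_ <- generate_locus(arch, seed = 8)
  expect_false(identical(a$sequence, c_$sequence))
})

test_that("reverse-oriented genes validate after reverse complement", {
  arch <- architecture_spec("Vrev(1)", spacing = c(100, 200))
  syn <- generate_locus(arch, defect_model(rss_rate = 0), seed = 5)
  g <- syn$genes[1, ]
  expect_equal(g$strand, "-")
  cassette <- rc_oracle(substr(syn$sequence, g$start, g$end))
  expect_equal(substr(cassette, 1, 3), "ATG")        # leader init codon
  expect_equal(substr(cassette, nchar(cassette) - 8, nchar(cassette)),
               "ACAAAAACC")                          # canonical-orientation nonamer
})

test_that("forced defects set the intended functionality", {
  arch <- architecture_spec("V(1)-J(4)-C(1)", spacing = c(100, 300))
  syn <- generate_locus(arch, defect_model(stop_codon = c(J = 1)), seed = 3)
  j <- syn$genes[syn$genes$type == "J", ]
  expect_true(all(j$intended_functionality == "P"))
  expect_true(all(grepl("stop_codon", j$defects)))
  # other types untouched
  expect_equal(syn$genes$intended_functionality[syn$genes$type == "V"], "F")

  syn2 <- generate_locus(arch, defect_model(missing_motif = c(J = 1)), seed = 3)
  expect_true(all(syn2$genes$intended_functionality[syn2$genes$type == "J"] == "ORF"))
})

test_that("planted structures satisfy their structural definitions", {
  syn <- generate_locus(architecture_spec("V(3)-D(1)-J(3)-C(1)", spacing = c(150, 400)),
                        seed = 13)
  seq <- unname(syn$sequence)
  feats <- syn$features
  # leader introns literally start GT and end AG
  introns <- feats[feats$type == "L-INTRON", ]
  for (k in seq_len(nrow(introns))) {
    expect_equal(substr(seq, introns$start[k], introns$start[k] + 1L), "GT")
    expect_equal(substr(seq, introns$end[k] - 1L, introns$end[k]), "AG")
  }
  # V exons translate without stops and keep the conserved residues
  vex <- feats[feats$type == "V-EXON", ]
  for (k in seq_len(nrow(vex))) {
    aa <- trlocus:::translate_dna(substr(seq, vex$start[k], vex$end[k]))
    expect_false(grepl("*", aa, fixed = TRUE))
    expect_equal(substr(aa, 23, 23), "C")
    expect_equal(substr(aa, 41, 41), "W")
    expect_equal(substr(aa, 104, 104), "C")
  }
  # D core G-rich between its signals
  dcore <- feats[feats$type == "D-REGION", ]
  core_seq <- substr(seq, dcore$start, dcore$end)
  expect_gte(mean(strsplit(core_seq, "")[[1]] == "G"), 0.5)
  # J regions end at a GT donor and code the motif
  jreg <- feats[feats$type == "J-REGION", ]
  for (k in seq_len(nrow(jreg))) {
    expect_equal(substr(seq, jreg$end[k] + 1L, jreg$end[k] + 2L), "GT")
    aa <- trlocus:::translate_dna(substr(seq, jreg$start[k], jreg$end[k]))
    expect_true(grepl("[WF][GA].G", aa))
  }
})

test_that("planted RSS mutation counts follow the configured distribution", {
  # many D genes -> two RSS draws per gene
  arch <- architecture_spec("D(500)", spacing = c(40, 80), locus_type = "TRB")
  syn <- generate_locus(arch, defect_model(rss_rate = 0.1, rss_max_mismatches = 6L),
                        seed = 29)
  counts <- c(syn$genes$rss5_mismatches, syn$genes$rss3_mismatches)
  expect_equal(length(counts), 1000L)
  # truncated Binomial(13, 0.1) over 0..6
  p <- dbinom(0:6, 13, 0.1)
  p <- p / sum(p)
  obs <- tabulate(counts + 1L, nbins = 7L)
  keep <- p * length(counts) >= 1
  gof <- suppressWarnings(chisq.test(obs[keep], p = p[keep] / sum(p[keep])))
  expect_gt(gof$p.value, 0.01)
})

test_that("oversized architectures are refused", {
  arch <- architecture_spec("V(50)", spacing = c(5000, 6000))
  expect_error(generate_locus(arch, seed = 1, max_length = 1e4), "max_length")
})

test_that("truth tables and glance summaries agree", {
  syn <- generate_locus(architecture_spec("V(2)-J(1)", spacing = c(50, 100)), seed = 4)
  expect_identical(generics::tidy(syn), syn$genes)
  gl <- generics::glance(syn)
  expect_equal(gl$n_genes, 3L)
  expect_equal(gl$n_v, 2L)
  expect_equal(gl$seed, 4L)
})
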