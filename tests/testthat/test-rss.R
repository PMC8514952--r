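test_that("score_rss counts element mutations and applies rejection rules", {
  v3 <- standard_rss_motif("v3")
  sp <- rand_dna(23, seed = 1)

  canon <- paste0("CACAGTG", sp, "ACAAAAACC")
  hit <- score_rss(canon, v3)
  expect_true(hit$accepted)
  expect_equal(hit$total_mismatches, 0L)
  expect_equal(hit$heptamer_seq, "CACAGTG")
  expect_equal(hit$spacer_seq, sp)

  one <- score_rss(paste0("CACTGTG", sp, "ACAAAAACC"), v3)
  expect_equal(one$heptamer_mismatches, 1L)
  expect_equal(one$total_mismatches, 1L)
  expect_true(one$accepted)

  short_spacer <- paste0("CACAGTG", substr(sp, 1, 22), "ACAAAAACC")
  rej <- score_rss(short_spacer, v3, spacer_tol = 0L)
  expect_false(rej$accepted)
  expect_equal(rej$reason, "spacer length")
  tol <- score_rss(short_spacer, v3, spacer_tol = 1L)
  expect_true(tol$accepted)
  expect_equal(tol$spacer_deviation, -1L)

  amb <- score_rss(paste0("CACAGTN", sp, "ACAAAAACC"), v3)
  expect_false(amb$accepted)
  expect_equal(amb$reason, "ambiguous base")

  core <- score_rss(paste0("TACAGTG", sp, "ACAAAAACC"), v3, require_core = TRUE)
  expect_false(core$accepted)
  expect_equal(core$reason, "heptamer core")

  many <- score_rss(paste0("CACAGTG", sp, "GGGGGGGGG"), v3, max_mismatches = 6L)
  expect_false(many$accepted)
  expect_equal(many$reason, "too many mismatches")
})

test_that("score_rss reads nonamer-first windows in canonical orientation", {
  j5 <- standard_rss_motif("j5")
  win <- rss_window_fixture(12, "nonamer_first")
  hit <- score_rss(win, j5)
  expect_true(hit$accepted)
  expect_equal(hit$total_mismatches, 0L)
  expect_equal(hit$heptamer_seq, "CACAGTG")
  expect_equal(hit$nonamer_seq, "ACAAAAACC")
})

test_that("scan_rss finds planted signals and orders hits by mutation count", {
  set.seed(5)
  bg <- rand_dna(400)
  win <- rss_window_fixture(23, "heptamer_first", spacer_seq = rand_dna(23))
  seq <- paste0(substr(bg, 1, 50), win, substr(bg, 90, 400))
  hits <- scan_rss(seq, standard_rss_motif("v3"), max_mismatches = 2)
  expect_equal(hits$start[1], 51L)
  expect_equal(hits$total_mismatches[1], 0L)

  # two planted signals with 1 and 3 mutations come back in that order
  w1 <- mutate_positions(paste0("CACAGTG", rand_dna(23), "ACAAAAACC"), 5)
  w3 <- mutate_positions(paste0("CACAGTG", rand_dna(23), "ACAAAAACC"), c(5, 32, 34))
  seq2 <- paste0(rand_dna(60), w1, rand_dna(60), w3, rand_dna(60))
  hits2 <- scan_rss(seq2, standard_rss_motif("v3"), max_mismatches = 3)
  planted <- hits2[hits2$start %in% c(61L, 61L + 39L + 60L), ]
  expect_equal(planted$total_mismatches, c(1L, 3L))

  expect_equal(nrow(scan_rss(rand_dna(20), standard_rss_motif("v3"), 9)), 0L)
})

test_that("scan_rss agrees with the naive window-by-window oracle", {
  set.seed(17)
  seq <- rand_dna(2000)
  # plant a couple of degraded signals so agreement is not vacuous
  seq <- paste0(substr(seq, 1, 300),
                mutate_positions(rss_window_fixture(12, "nonamer_first",
                                                    spacer_seq = rand_dna(12)), c(2, 20)),
                substr(seq, 340, 2000))
  for (edge in c("v3", "j5", "d5", "d3")) {
    motif <- standard_rss_motif(edge)
    layout <- motif$layout
    for (mm in c(2L, 5L)) {
      got <- scan_rss(seq, motif, max_mismatches = mm)
      want <- scan_rss_oracle(seq, motif$spacer, layout, mm)
      expect_equal(got$start, want$start, info = paste(edge, mm))
      expect_equal(got$heptamer_mismatches, want$heptamer_mismatches)
      expect_equal(got$nonamer_mismatches, want$nonamer_mismatches)
    }
  }
})

test_that("scanning is strand-consistent under reverse complement", {
  set.seed(23)
  seq <- paste0(rand_dna(150),
                rss_window_fixture(23, "heptamer_first", spacer_seq = rand_dna(23)),
                rand_dna(150))
  fwd <- scan_rss(seq, rss_motif(23, "heptamer_first"), max_mismatches = 3)
  # the same physical signal on the reverse complement reads nonamer-first
  rev <- scan_rss(rc_oracle(seq), rss_motif(23, "nonamer_first"), max_mismatches = 3)
  L <- nchar(seq)
  expect_setequal(L - rev$end + 1L, fwd$start)
  expect_equal(sort(rev$total_mismatches), sort(fwd$total_mismatches))
})

test_that("PWMs are per-position frequencies that sum to one", {
  hits <- tibble::tibble(
    heptamer_seq = c("CACAGTG", "CACAGTG"),
    nonamer_seq = c("ACAAAAACC", "ACAAAAACC")
  )
  pwm <- build_pwm(hits, "heptamer")
  expect_equal(unname(colSums(pwm)), rep(1, 7))
  expect_equal(unname(pwm["C", 1]), 1)

  two <- build_pwm(tibble::tibble(heptamer_seq = c("CACAGTG", "AACAGTG")), "heptamer")
  expect_equal(unname(two["C", 1]), 0.5)
  expect_equal(unname(two["A", 1]), 0.5)

  single <- build_pwm(tibble::tibble(nonamer_seq = "ACAAAAACC"), "nonamer")
  expect_true(all(single %in% c(0, 1)))
  expect_equal(ncol(single), 9L)

  expect_error(build_pwm(tibble::tibble(heptamer_seq = character()), "heptamer"),
               "no hits")
})

test_that("PWM of simulated signals recovers the consensus frequency", {
  set.seed(97)
  hits <- simulate_rss_hits(100, rate = 0.1)
  lo <- qbinom(0.005, 100, 0.9) / 100
  hi <- qbinom(0.995, 100, 0.9) / 100
  hep <- build_pwm(hits, "heptamer")
  non <- build_pwm(hits, "nonamer")
  hep_cons <- strsplit("CACAGTG", "")[[1]]
  non_cons <- strsplit("ACAAAAACC", "")[[1]]
  for (j in 1:7) expect_gte(hep[hep_cons[j], j], lo)
  for (j in 1:7) expect_lte(hep[hep_cons[j], j], hi)
  for (j in 1:9) expect_gte(non[non_cons[j], j], lo)
  for (j in 1:9) expect_lte(non[non_cons[j], j], hi)
})

test_that("PWM export writes a tab-delimited A/C/G/T by position matrix", {
  pwm <- build_pwm(tibble::tibble(heptamer_seq = c("CACAGTG", "CACAGTG")), "heptamer")
  f <- withr::local_tempfile(fileext = ".tsv")
  export_pwm(pwm, f)
  back <- read.delim(f, row.names = 1)
  expect_equal(rownames(back), c("A", "C", "G", "T"))
  expect_equal(ncol(back), 7L)
  expect_equal(unname(colSums(back)), rep(1, 7))
})

test_that("mutation summaries report presence, absence and count ranges", {
  ann <- tibble::tibble(
    type = c("V", "V", "V", "J", "D"),
    rss_mismatches = c(0L, 3L, NA, 2L, NA),
    rss5_mismatches = c(NA, NA, NA, NA, 1L),
    rss3_mismatches = c(NA, NA, NA, NA, 4L)
  )
  s <- rss_mutation_summary(ann)
  v <- s[s$segment == "V", ]
  expect_equal(v$n_with_rss, 2L)
  expect_equal(v$n_missing_rss, 1L)
  expect_equal(v$min_mismatches, 0L)
  expect_equal(v$max_mismatches, 3L)
  expect_equal(s[s$segment == "D_rss5", ]$min_mismatches, 1L)

  # all-canonical locus: every range collapses to zero
  syn <- generate_locus(architecture_spec("V(2)-J(2)", spacing = c(50, 150)),
                        defect_model(rss_rate = 0), seed = 2)
  s2 <- rss_mutation_summary(syn$genes)
  expect_true(all(s2$min_mismatches == 0L))
  expect_true(all(s2$max_mismatches == 0L))
  expect_true(all(s2$n_missing_rss == 0L))
})
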