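test_that("load_sequences uppercases, validates ids and alphabet", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "acgt"), f)
  store <- load_sequences(f)
  expect_identical(store, c(x = "ACGT"))

  writeLines(c(">x", "ACGT", ">x", "GGGG"), f)
  expect_error(load_sequences(f), "duplicated.*x")

  writeLines(c(">x", "ACQT"), f)
  expect_error(load_sequences(f), "non-ACGTN")

  expect_error(load_sequences(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("synthetic locus FASTA round-trips through write and load", {
  syn <- generate_locus(architecture_spec("V(1)-J(1)-C(1)", spacing = c(50, 100)),
                        seed = 3)
  d <- withr::local_tempdir()
  paths <- write_synthetic_locus(syn, d)
  store <- load_sequences(paths$fasta)
  expect_identical(unname(store), unname(syn$sequence))
  expect_identical(names(store), names(syn$sequence))
})

test_that("extract_locus slices forward and reverse-complements reverse loci", {
  store <- c(chr = "ACGTT")
  fwd <- locus_definition("TRB", "chr", 2, 4, "+")
  rev <- locus_definition("TRB", "chr", 2, 4, "-")
  expect_identical(extract_locus(store, fwd), "CGT")
  expect_identical(extract_locus(store, rev), "ACG")

  # involution on random sequences
  set.seed(42)
  for (i in 1:5) {
    s <- c(chr = rand_dna(100))
    a <- sample(1:50, 1); b <- a + sample(10:40, 1)
    f <- locus_definition("TRG", "chr", a, b, "+")
    r <- locus_definition("TRG", "chr", a, b, "-")
    expect_identical(extract_locus(s, r), rc_oracle(extract_locus(s, f)))
  }

  oob <- locus_definition("TRB", "chr", 2, 9, "+")
  expect_error(extract_locus(store, oob), "out of bounds")
})

test_that("locus config files parse into locus definitions", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c(
    "# loci of the assembly",
    "TRB = chr26, 7911840, 8164121, -, MOXD2, EPHB6",
    "TRG = chr20, 51976009, 52427198, -, AMPH, STARD3NL"
  ), f)
  loci <- read_locus_config(f)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$locus_name, c("TRB", "TRG"))
  expect_equal(loci$start[1], 7911840L)
  expect_equal(loci$strand, c("-", "-"))
  expect_equal(loci$flank5[2], "AMPH")
})

test_that("GFF3 emission follows the standard and round-trips exactly", {
  feats <- tibble::tibble(
    seqid = "s", type = c("gene", "V-EXON", "gene"),
    start = c(1L, 3L, 50L), end = c(7L, 6L, 80L),
    strand = c("+", "+", "-"),
    ID = c("g1", "g1.ex", "g2"), Parent = c(NA, "g1", NA),
    name = c("TRBV1", NA, "TRBV2"), functionality = c("F", NA, "P"),
    defects = c(NA, NA, "stop_codon"), subgroup = c("1", NA, "2"),
    score = c(NA, NA, NA)
  )
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotations(feats, gff)

  raw <- readLines(gff)
  expect_true(any(grepl("^##gff-version 3", raw)))
  g1 <- strsplit(grep("ID=g1;|ID=g1$", raw, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(g1[4:5]), c(1L, 7L))   # 1-based inclusive columns
  g2 <- strsplit(grep("ID=g2", raw, value = TRUE)[1], "\t")[[1]]
  expect_equal(g2[7], "-")

  back <- read_annotations(gff)
  expect_equal(nrow(back), 3L)
  ord <- match(feats$ID, back$ID)
  expect_equal(back$start[ord], feats$start)
  expect_equal(back$end[ord], feats$end)
  expect_equal(back$strand[ord], feats$strand)
  expect_equal(back$type[ord], feats$type)
  expect_equal(back$Parent[ord], feats$Parent)
  expect_equal(back$functionality[ord], feats$functionality)

  # BED companion is 0-based half-open
  bed <- sub("\\.gff3$", ".bed", gff)
  expect_true(file.exists(bed))
  b1 <- strsplit(readLines(bed)[1], "\t")[[1]]
  expect_equal(as.integer(b1[2:3]), c(0L, 7L))

  expect_error(
    write_annotations(dplyr::mutate(feats, start = NA_integer_), gff),
    "unresolved"
  )
})

test_that("truth features of a generated locus survive a GFF3 round-trip", {
  syn <- generate_locus(architecture_spec("V(2)-J(2)", spacing = c(50, 150)),
                        seed = 11)
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_annotations(syn$features, gff, bed = FALSE)
  back <- read_annotations(gff)
  key <- function(df) {
    df <- df[order(df$ID), c("type", "start", "end", "strand", "ID")]
    rownames(df) <- NULL
    df
  }
  expect_equal(key(as.data.frame(back)), key(as.data.frame(syn$features)))
})
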