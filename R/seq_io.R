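#' Read a FASTA file into a named sequence store
#'
#' Reads DNA sequences with [Biostrings::readDNAStringSet()], uppercases them
#' and enforces the pipeline alphabet `A/C/G/T/N`. Record ids must be unique
#' and records non-empty.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase DNA sequences.
#' @export
load_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    withCallingHandlers(
      Biostrings::readDNAStringSet(path),
      # invalid letters are silently dropped with a warning; surface them
      warning = function(w) stop("non-ACGTN characters: ", conditionMessage(w))
    ),
    error = function(e) stop("malformed FASTA in '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("no FASTA records in '", path, "'")
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicated FASTA id(s): ", paste(dup, collapse = ", "))
  }
  if (any(Biostrings::width(set) == 0L)) {
    stop("empty FASTA record(s): ",
         paste(ids[Biostrings::width(set) == 0L], collapse = ", "))
  }
  seqs <- str_to_upper(as.character(set))
  names(seqs) <- ids
  bad <- str_detect(seqs, "[^ACGTN]")
  if (any(bad)) {
    stop("non-ACGTN characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  seqs
}

#' Write a named sequence store to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Define a locus as a named genomic interval
#'
#' A locus definition names one of the three T-cell receptor loci, the
#' sequence it lives on, its 1-based inclusive coordinates, the strand of
#' transcription, and the flanking (borne) gene labels used to delimit it.
#'
#' @param locus_name one of `"TRA/D"`, `"TRG"`, `"TRB"`.
#' @param seq_id sequence (chromosome) identifier.
#' @param start,end 1-based inclusive interval, `start <= end`.
#' @param strand `"+"` (forward) or `"-"` (reverse).
#' @param flank5,flank3 labels of the 5' and 3' flanking genes.
#' @return one-row tibble with the locus definition.
#' @export
locus_definition <- function(locus_name, seq_id, start, end, strand = "+",
                             flank5 = NA_character_, flank3 = NA_character_) {
  locus_name <- match.arg(locus_name, c("TRA/D", "TRG", "TRB"))
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 1L && start <= end)) stop("invalid interval: need 1 <= start <= end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  tibble(locus_name = locus_name, seq_id = seq_id, start = start, end = end,
         strand = strand, flank5 = flank5, flank3 = flank3)
}

#' Read locus definitions from a flat key-value config file
#'
#' Each non-comment line has the form
#' `TRB = NC_046309.1, 7911840, 8164121, -, MOXD2, EPHB6`
#' (locus name, then sequence id, start, end, strand and the two flanking gene
#' labels). Coordinates are 1-based inclusive.
#'
#' @param path config file path.
#' @return tibble of locus definitions, one row per locus.
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no locus definitions in '", path, "'")
  parse_line <- function(ln) {
    kv <- str_match(ln, "^([^=]+)=(.*)$")
    if (is.na(kv[1, 1])) stop("unparseable config line: ", ln)
    fields <- trimws(strsplit(kv[1, 3], ",", fixed = TRUE)[[1]])
    if (length(fields) < 4L) stop("config line needs seq_id,start,end,strand: ", ln)
    locus_definition(
      locus_name = trimws(kv[1, 2]),
      seq_id = fields[1],
      start = as.integer(fields[2]), end = as.integer(fields[3]),
      strand = fields[4],
      flank5 = if (length(fields) >= 5L) fields[5] else NA_character_,
      flank3 = if (length(fields) >= 6L) fields[6] else NA_character_
    )
  }
  list_rbind(map(lines, parse_line))
}

#' Extract a locus sequence in transcriptional orientation
#'
#' Slices the named interval out of the store; when `strand = "-"` the reverse
#' complement is returned so that downstream scanning always proceeds 5' to 3'
#' in gene orientation.
#'
#' @param store named character vector from [load_sequences()].
#' @param locus one-row tibble from [locus_definition()] / [read_locus_config()].
#' @return character scalar of length `end - start + 1`.
#' @export
extract_locus <- function(store, locus) {
  stopifnot(nrow(locus) == 1L)
  if (!locus$seq_id %in% names(store)) {
    stop("sequence id not in store: ", locus$seq_id)
  }
  full <- store[[locus$seq_id]]
  if (locus$end > nchar(full)) {
    stop("interval [", locus$start, ",", locus$end, "] out of bounds for '",
         locus$seq_id, "' (length ", nchar(full), ")")
  }
  s <- substr(full, locus$start, locus$end)
  if (locus$strand == "-") revcomp(s) else s
}

# canonical empty feature table shared by writers and the pipeline
empty_features <- function() {
  tibble(
    seqid = character(), type = character(),
    start = integer(), end = integer(), strand = character(),
    ID = character(), Parent = character(),
    name = character(), functionality = character(), defects = character(),
    subgroup = character(), score = double()
  )
}

normalize_features <- function(features) {
  tmpl <- empty_features()
  for (col in names(tmpl)) {
    if (!col %in% names(features)) features[[col]] <- tmpl[[col]][NA_integer_][seq_len(nrow(features))]
  }
  features[names(tmpl)]
}

#' Write annotations to GFF3 (and a BED6 companion)
#'
#' Features are emitted 1-based inclusive per the GFF3 standard, ordered
#' deterministically by (seqid, start, type, ID), with gene sub-features nested
#' through `Parent` attributes. Functionality class, defect codes, subgroup and
#' name travel as attributes. A BED6 companion (0-based half-open, per BED) is
#' written next to the GFF3 unless `bed = FALSE`.
#'
#' @param features tibble with columns `seqid, type, start, end, strand, ID`
#'   and optionally `Parent, name, functionality, defects, subgroup, score`.
#' @param path output GFF3 path.
#' @param bed also write `sub("\\.gff3?$", ".bed", path)`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(features, path, bed = TRUE) {
  features <- normalize_features(as_tibble(features))
  if (nrow(features) > 0L) {
    if (anyNA(features$start) || anyNA(features$end)) {
      stop("unresolved interval: NA start/end in features")
    }
    features <- arrange(features, .data$seqid, .data$start, .data$type, .data$ID)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand
  )
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$ID <- features$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(features$Parent), NA_character_, features$Parent)
  for (col in c("name", "functionality", "defects", "subgroup")) {
    if (any(!is.na(features[[col]]))) S4Vectors::mcols(gr)[[col]] <- features[[col]]
  }
  if (any(!is.na(features$score))) S4Vectors::mcols(gr)$score <- features$score
  rtracklayer::export(gr, path, format = "gff3")
  if (isTRUE(bed)) {
    bed_path <- sub("\\.gff3?$", ".bed", path)
    if (identical(bed_path, path)) bed_path <- paste0(path, ".bed")
    bed_gr <- gr
    S4Vectors::mcols(bed_gr) <- NULL
    S4Vectors::mcols(bed_gr)$name <- features$ID
    S4Vectors::mcols(bed_gr)$score <- ifelse(is.na(features$score), 0, features$score)
    rtracklayer::export(bed_gr, bed_path, format = "bed")
  }
  invisible(path)
}

#' Read a GFF3 annotation file back into a feature tibble
#'
#' Inverse of [write_annotations()]: coordinates stay 1-based inclusive and
#' the attribute columns written by this package are restored.
#'
#' @param path GFF3 file.
#' @return feature tibble (same shape as the [write_annotations()] input).
#' @export
read_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(mc)) {
    vapply(as.list(mc$Parent), function(p) if (length(p)) as.character(p[1]) else NA_character_, "")
  } else rep(NA_character_, length(gr))
  grab <- function(col) if (col %in% names(mc)) as.character(mc[[col]]) else rep(NA_character_, length(gr))
  out <- tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(mc$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = grab("ID"),
    Parent = parent,
    name = grab("name"),
    functionality = grab("functionality"),
    defects = grab("defects"),
    subgroup = grab("subgroup"),
    score = if ("score" %in% names(mc)) suppressWarnings(as.numeric(mc$score)) else rep(NA_real_, length(gr))
  )
  arrange(out, .data$seqid, .data$start, .data$type, .data$ID)
}
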