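#' Default defect-severity table
#'
#' Maps each structural defect code to the functionality class it forces, per
#' segment type. Pseudogene-forcing defects are those that destroy the coding
#' potential or a required splice site (stop codon, frameshift, missing
#' initiation codon, broken acceptor/donor); signal and motif defects
#' (missing/defective RSS, absent leader, out-of-range length, absent J motif,
#' missing conserved framework residue) leave an open reading frame and demote
#' to ORF. D genes carry no reading frame, so only their RSSs matter.
#'
#' @return tibble with columns `code`, `segment_type`, `forces` (`"P"`/`"ORF"`).
#' @export
default_severity_table <- function() {
  p <- function(code, types) tibble(code = code, segment_type = types, forces = "P")
  o <- function(code, types) tibble(code = code, segment_type = types, forces = "ORF")
  bind_rows(
    p("stop_codon", c("V", "J", "C")),
    p("frameshift", c("V", "J", "C")),
    p("missing_init", "V"),
    p("broken_acceptor", c("V", "C")),
    p("broken_donor", c("V", "J", "C")),
    o("missing_rss", c("V", "D", "J")),
    o("defective_rss", c("V", "D", "J")),
    o("missing_leader", "V"),
    o("length_out_of_range", c("V", "J")),
    o("missing_motif", "J"),
    o("missing_conserved_residue", "V")
  )
}

# Shared by the classifier and the synthetic generator: the call implied by a
# set of defect codes for a segment type.
severity_call <- function(type, codes, severity = default_severity_table()) {
  codes <- unique(codes[!is.na(codes)])
  if (length(codes) == 0L) return(list(call = "F", reasons = character(0)))
  forces <- vapply(codes, function(code) {
    row <- severity[severity$code == code & severity$segment_type == type, ]
    if (nrow(row) == 0L) "ORF" else row$forces[1]
  }, "")
  list(
    call = if (any(forces == "P")) "P" else "ORF",
    reasons = codes
  )
}

#' Classify a described segment as functional, ORF or pseudogene
#'
#' Pure function of the recorded structural evidence: the defect codes present
#' in a segment description are mapped through the severity table; any
#' pseudogene-forcing defect yields `P`, any remaining defect `ORF`, and a
#' defect-free description `F`. `P` calls carry `in_frame_pseudo = TRUE` when
#' the reading frame itself is intact (stop codon present but no frameshift or
#' splice/init loss), the subset used for phylogenetic trees.
#'
#' @param segment a segment description from [describe_v()], [find_d()],
#'   [find_j()] or [find_c()] (class `tr_segment`), or a bare list with
#'   `type` and `defects` fields.
#' @param severity severity table, see [default_severity_table()].
#' @return one-row tibble: `call` (`F`/`ORF`/`P`), `reasons` (comma-joined
#'   defect codes), `in_frame_pseudo`.
#' @export
classify_segment <- function(segment, severity = default_severity_table()) {
  if (is.null(segment$type) || is.null(segment$defects)) {
    stop("incomplete description: segment needs 'type' and 'defects' fields")
  }
  type <- segment$type
  stopifnot(type %in% c("V", "D", "J", "C"))
  codes <- segment$defects
  if (length(codes) == 1L && (is.na(codes) || codes == "")) codes <- character(0)
  if (length(codes) == 1L && grepl(",", codes)) {
    codes <- strsplit(codes, ",", fixed = TRUE)[[1]]
  }
  bad <- setdiff(codes, DEFECT_CODES)
  if (length(bad)) stop("unknown defect code(s): ", paste(bad, collapse = ", "))
  sv <- severity_call(type, codes, severity)
  frame_killers <- c("frameshift", "missing_init", "broken_acceptor", "broken_donor")
  tibble(
    call = sv$call,
    reasons = if (length(sv$reasons)) paste(sort(sv$reasons), collapse = ",") else "",
    in_frame_pseudo = sv$call == "P" &&
      "stop_codon" %in% codes && !any(frame_killers %in% codes)
  )
}

#' Exhaustive single-defect truth table
#'
#' Enumerates every applicable (segment type, defect code) pair, injects the
#' defect alone into an otherwise perfect description, and records the
#' resulting functionality call. Used as a regression fixture for the
#' classifier contract.
#'
#' @param severity severity table.
#' @return tibble: `segment_type`, `code`, `call`.
#' @export
defect_truth_table <- function(severity = default_severity_table()) {
  severity |>
    rowwise() |>
    mutate(call = classify_segment(
      list(type = .data$segment_type, defects = .data$code), severity
    )$call) |>
    ungroup() |>
    select(segment_type = "segment_type", code = "code", call = "call") |>
    arrange(.data$segment_type, .data$code)
}
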