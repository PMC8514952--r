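#' Pairwise percent nucleotide identity
#'
#' Global (Needleman-Wunsch) alignment of every sequence pair; identity is
#' matched positions over aligned columns, terminal gap columns excluded,
#' times 100.
#'
#' @param seqs named character vector of DNA sequences (>= 2, non-empty).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return symmetric numeric matrix of percent identities, 100 on the diagonal.
#' @export
pairwise_identity <- function(seqs, gap_opening = 10, gap_extension = 0.5) {
  if (length(seqs) < 2L) stop("need at least two sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) stop("sequences must be named")
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence(s): ",
         paste(names(seqs)[nchar(seqs) == 0L], collapse = ", "))
  }
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  submat <- nt_submat()
  for (i in seq_len(n - 1L)) {
    # one vectorized call: sequence i against all later sequences
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(seqs[seq.int(i + 1L, n)]),
      subject = Biostrings::DNAString(seqs[[i]]),
      type = "global", substitutionMatrix = submat,
      gapOpening = gap_opening, gapExtension = gap_extension
    )
    # terminal gaps are clipped from the aligned ranges in this representation,
    # so match/mismatch/indel counts already cover exactly the non-terminal
    # alignment columns
    nm <- Biostrings::nmatch(pa)
    nmm <- Biostrings::nmismatch(pa)
    ni <- Biostrings::nindel(pa)
    gaps <- ni@insertion[, "WidthSum"] + ni@deletion[, "WidthSum"]
    ident <- 100 * nm / (nm + nmm + gaps)
    js <- seq.int(i + 1L, n)
    m[i, js] <- m[js, i] <- ident
  }
  m
}

#' Tidy an identity matrix into pair rows
#'
#' @param m matrix from [pairwise_identity()].
#' @return tibble `id1`, `id2`, `identity` over unordered pairs.
#' @export
identity_pairs <- function(m) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  tibble(
    id1 = rownames(m)[ut[, 1]], id2 = colnames(m)[ut[, 2]],
    identity = m[ut]
  )
}

# union-find -------------------------------------------------------------

uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

#' Assign V subgroups at an identity threshold, with a tree override
#'
#' Base assignment is single-linkage: connected components of the graph whose
#' edges join pairs at or above `threshold` percent identity. A segment below
#' threshold to every member of a group is still merged into that group when
#' its nearest tree neighbor (smallest patristic distance) belongs to the
#' group and the supporting node has bootstrap at or above `boot_floor` — the
#' adjacency-over-threshold exception observed for divergent in-group
#' pseudogenes. Otherwise it founds a singleton subgroup.
#'
#' @param m identity matrix from [pairwise_identity()].
#' @param tree optional `phylo` over the same labels (node labels carry
#'   bootstrap supports; trees without node labels are treated as confident).
#' @param threshold percent identity threshold.
#' @param boot_floor minimum bootstrap support for the override.
#' @return tibble: `id`, `subgroup` (integer, numbered by first appearance),
#'   `provenance` (`threshold` or `tree_override`).
#' @export
assign_subgroups <- function(m, tree = NULL, threshold = 75, boot_floor = 70) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    stop("identity matrix must be symmetric")
  }
  ids <- rownames(m)
  n <- length(ids)
  parent <- uf_new(n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (m[i, j] >= threshold) parent <- uf_union(parent, i, j)
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), 1L)
  provenance <- rep("threshold", n)

  if (!is.null(tree)) {
    if (!setequal(tree$tip.label, ids) && !all(ids %in% tree$tip.label)) {
      stop("tree leaf set does not cover the identity matrix labels")
    }
    pat <- stats::cophenetic(tree)[ids, ids, drop = FALSE]
    support <- node_support_of_tips(tree)
    singletons <- which(tabulate(comp, nbins = n)[comp] == 1L)
    for (i in sort(singletons)) {
      d <- pat[i, ]; d[i] <- Inf
      nn <- which.min(d)
      sup <- support[[ids[i]]]
      if (is.na(sup)) sup <- 100
      if (sup >= boot_floor && comp[nn] != comp[i]) {
        comp[i] <- comp[nn]
        provenance[i] <- "tree_override"
      }
    }
  }
  tibble(
    id = ids,
    subgroup = as.integer(factor(comp, levels = unique(comp))),
    provenance = provenance
  )
}

# bootstrap support of the internal node each tip attaches to (NA if absent)
node_support_of_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  out <- stats::setNames(rep(NA_real_, n_tip), tree$tip.label)
  if (is.null(tree$node.label)) return(out)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  for (i in seq_len(n_tip)) {
    parent <- tree$edge[tree$edge[, 2] == i, 1]
    if (length(parent) == 1L) out[i] <- sup[parent - n_tip]
  }
  out
}

#' Neighbor-joining tree
#'
#' Classic neighbor-joining agglomeration on a distance matrix: at each step
#' the pair minimizing the Q criterion is joined (ties broken by the
#' alphabetically lowest label pair), branch lengths follow the standard
#' rate-corrected formulas, and negative branch lengths are clamped to zero
#' with the deficit moved to the sister branch. Returns an unrooted `phylo`.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 3 taxa.
#' @return an [ape] `phylo` object.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  fmt <- function(x) format(max(0, x), digits = 12, scientific = FALSE, trim = TRUE)
  nodes <- labels            # newick fragment per active node
  active <- seq_len(n)
  D <- d
  while (length(active) > 3L) {
    k <- length(active)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    # deterministic tie-break: lowest label pair
    pair_lab <- apply(best, 1L, function(ij) {
      paste(sort(c(nodes[ij[1]], nodes[ij[2]])), collapse = "\r")
    })
    sel <- best[order(pair_lab)[1], ]
    i <- sel[1]; j <- sel[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- D[i, j]; bi <- 0 }
    if (bj < 0) { bi <- D[i, j]; bj <- 0 }
    new_frag <- paste0("(", nodes[i], ":", fmt(bi), ",", nodes[j], ":", fmt(bj), ")")
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nodes <- c(nodes[keep], new_frag)
    active <- seq_len(k - 1L)
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  b1 <- max(0, (d12 + d13 - d23) / 2)
  b2 <- max(0, (d12 + d23 - d13) / 2)
  b3 <- max(0, (d13 + d23 - d12) / 2)
  nwk <- paste0("(", nodes[1], ":", fmt(b1), ",", nodes[2], ":", fmt(b2), ",",
                nodes[3], ":", fmt(b3), ");")
  ape::read.tree(text = nwk)
}

# p-distance with pairwise deletion of gap/ambiguous columns, on an
# integer-encoded alignment matrix (NA = gap)
encode_alignment <- function(alignment) {
  stopifnot(!is.null(names(alignment)))
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) stop("alignment sequences differ in length")
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  code <- match(mat, DNA_BASES)  # gaps / N -> NA
  matrix(code, nrow = length(alignment), dimnames = list(names(alignment), NULL))
}

pdist_from_encoded <- function(enc) {
  n <- nrow(enc)
  d <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      valid <- !is.na(enc[i, ]) & !is.na(enc[j, ])
      nv <- sum(valid)
      d[i, j] <- d[j, i] <- if (nv == 0L) 0 else sum(enc[i, valid] != enc[j, valid]) / nv
    }
  }
  d
}

#' P-distance matrix from a gapped alignment
#'
#' Proportion of differing sites per pair, gap/ambiguous columns deleted
#' pairwise.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @return symmetric numeric distance matrix.
#' @export
p_distance <- function(alignment) {
  pdist_from_encoded(encode_alignment(alignment))
}

#' Bootstrap support for neighbor-joining tree edges
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree on the
#' p-distance of each replicate, and reports for each internal node of the
#' reference tree the percentage of replicates containing the same
#' bipartition. Supports are written into `tree$node.label`.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @param replicates number of bootstrap replicates.
#' @param tree reference tree; rebuilt from the full alignment when NULL.
#' @param seed optional seed for the resampling.
#' @return the reference `phylo` with `node.label` set to percent support
#'   (root node label NA).
#' @export
bootstrap_support <- function(alignment, replicates = 1000L, tree = NULL,
                              seed = NULL) {
  enc <- encode_alignment(alignment)
  if (is.null(tree)) tree <- nj_tree(pdist_from_encoded(enc))
  run <- function() {
    reps <- vector("list", replicates)
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol(enc), ncol(enc), replace = TRUE)
      reps[[b]] <- nj_tree(pdist_from_encoded(enc[, cols, drop = FALSE]))
    }
    reps
  }
  reps <- if (is.null(seed)) run() else with_local_seed(seed, run())
  part <- ape::prop.part(reps)
  counts <- ape::prop.clades(tree, part = part, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / replicates)
  support[1] <- NA  # root of the unrooted representation, not a bipartition
  tree$node.label <- as.character(support)
  tree
}

#' Name segments in IMGT style
#'
#' V genes: each subgroup inherits the subgroup designation of its nearest
#' named reference clade (smallest mean patristic distance to a reference
#' leaf) when a tree with named reference leaves is supplied; subgroups
#' without a homologous reference are numbered by position of their first
#' member along the locus. Multi-member subgroups get `-1`, `-2`, ... by 5'
#' to 3' locus order. D, J and C genes are named by D-J-C cluster index and
#' position within the cluster (the hyphenated form only when the locus has
#' several clusters).
#'
#' @param assignment tibble from [assign_subgroups()] (V genes), or NULL.
#' @param tree optional `phylo` containing both the segment ids and named
#'   reference leaves.
#' @param reference_names named character: reference leaf id -> subgroup
#'   designation (e.g. `"TRAV8"`).
#' @param locus_order tibble with `id`, `type`, `position` (locus coordinate)
#'   and `cluster` (D-J-C cluster index for D/J/C rows).
#' @param locus_prefix e.g. `"TRA"`, `"TRB"`.
#' @return tibble: `id`, `name`, `provenance`.
#' @export
name_segments <- function(assignment, tree = NULL, reference_names = NULL,
                          locus_order, locus_prefix = "TR") {
  out <- list()

  v_rows <- locus_order |> filter(.data$type == "V") |> arrange(.data$position)
  if (nrow(v_rows) > 0L) {
    if (is.null(assignment)) {
      assignment <- tibble(id = v_rows$id, subgroup = seq_len(nrow(v_rows)),
                           provenance = "position_fallback")
    }
    av <- v_rows |> left_join(assignment, by = "id")
    sg_first <- av |>
      group_by(.data$subgroup) |>
      summarize(first_pos = min(.data$position), .groups = "drop") |>
      arrange(.data$first_pos) |>
      mutate(order = row_number())
    base_names <- character(nrow(sg_first))
    prov <- character(nrow(sg_first))
    used <- character(0)
    for (k in seq_len(nrow(sg_first))) {
      sg <- sg_first$subgroup[k]
      base <- NA_character_
      if (!is.null(tree) && !is.null(reference_names)) {
        members <- av$id[av$subgroup == sg]
        refs_in_tree <- intersect(names(reference_names), tree$tip.label)
        members <- intersect(members, tree$tip.label)
        if (length(refs_in_tree) > 0L && length(members) > 0L) {
          pat <- stats::cophenetic(tree)
          dm <- pat[members, refs_in_tree, drop = FALSE]
          nearest <- refs_in_tree[which.min(colMeans(dm))]
          base <- unname(reference_names[[nearest]])
        }
      }
      if (!is.na(base) && !base %in% used) {
        base_names[k] <- base
        prov[k] <- "reference"
      } else {
        base_names[k] <- paste0(locus_prefix, "V", sg_first$order[k])
        prov[k] <- "position_fallback"
      }
      used <- c(used, base_names[k])
    }
    sg_first$base <- base_names
    sg_first$prov <- prov
    av <- av |>
      left_join(sg_first |> select("subgroup", "base", "prov"), by = "subgroup") |>
      group_by(.data$subgroup) |>
      arrange(.data$position, .by_group = TRUE) |>
      mutate(
        n_members = n(),
        name = if (n() > 1L) paste0(.data$base, "-", row_number()) else .data$base
      ) |>
      ungroup()
    out$v <- av |> select(id = "id", name = "name", provenance = "prov")
  }

  for (tp in c("D", "J", "C")) {
    rows <- locus_order |> filter(.data$type == tp) |> arrange(.data$position)
    if (nrow(rows) == 0L) next
    n_clusters <- length(unique(rows$cluster[!is.na(rows$cluster)]))
    rows <- rows |>
      group_by(.data$cluster) |>
      arrange(.data$position, .by_group = TRUE) |>
      mutate(pos_in_cluster = row_number()) |>
      ungroup()
    nm <- if (tp == "C") {
      paste0(locus_prefix, "C", rows$cluster)
    } else if (n_clusters > 1L) {
      paste0(locus_prefix, tp, rows$cluster, "-", rows$pos_in_cluster)
    } else {
      paste0(locus_prefix, tp, rows$pos_in_cluster)
    }
    out[[tp]] <- tibble(id = rows$id, name = nm, provenance = "cluster_position")
  }
  list_rbind(unname(out))
}
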