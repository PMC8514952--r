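test_that("pairwise identity matches hand-computed examples", {
  m <- pairwise_identity(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(m["a", "b"], 100)
  m2 <- pairwise_identity(c(a = "ACGT", b = "ACGA"))
  expect_equal(m2["a", "b"], 75)
  expect_equal(diag(m2), c(a = 100, b = 100))
  expect_true(isSymmetric(m2))
  expect_error(pairwise_identity(c(a = "ACGT", b = "")), "empty sequence")
  expect_error(pairwise_identity(c(a = "ACGT")), "at least two")
})

test_that("subgroups are single-linkage components at the threshold", {
  m <- matrix(c(100, 80, 60, 80, 100, 76, 60, 76, 100), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  sg <- assign_subgroups(m, threshold = 75)
  expect_equal(length(unique(sg$subgroup)), 1L)   # chained via B

  m2 <- m; m2["B", "C"] <- m2["C", "B"] <- 60
  sg2 <- assign_subgroups(m2, threshold = 75)
  expect_equal(sg2$subgroup[sg2$id == "A"], sg2$subgroup[sg2$id == "B"])
  expect_false(sg2$subgroup[sg2$id == "C"] == sg2$subgroup[sg2$id == "A"])
})

test_that("subgroup assignment equals graph components and ignores ordering", {
  set.seed(7)
  for (trial in 1:10) {
    n <- sample(5:12, 1)
    ids <- paste0("g", seq_len(n))
    m <- matrix(runif(n * n, 40, 100), n, n, dimnames = list(ids, ids))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 100
    sg <- assign_subgroups(m, threshold = 75)
    adj <- (m >= 75); diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    # same partition
    expect_equal(
      outer(sg$subgroup, sg$subgroup, "=="),
      outer(comp[sg$id], comp[sg$id], "=="),
      ignore_attr = TRUE
    )
    # invariant to relabeling / permutation
    perm <- sample(n)
    sg_p <- assign_subgroups(m[perm, perm], threshold = 75)
    key <- function(s) {
      split(s$id, s$subgroup) |> lapply(sort) |> unname() |>
        (\(x) x[order(vapply(x, `[`, "", 1))])()
    }
    expect_equal(key(sg_p), key(sg))
  }
})

test_that("the tree override merges a divergent member into its clade's group", {
  ids <- c("g1", "g2", "g3", "X")
  m <- matrix(65, 4, 4, dimnames = list(ids, ids))
  m[1:3, 1:3] <- 80
  diag(m) <- 100
  tree <- ape::read.tree(
    text = "((X:0.10,g1:0.08)95:0.05,g2:0.09,g3:0.10);"
  )
  sg <- assign_subgroups(m, tree = tree, threshold = 75, boot_floor = 70)
  expect_equal(sg$subgroup[sg$id == "X"], sg$subgroup[sg$id == "g1"])
  expect_equal(sg$provenance[sg$id == "X"], "tree_override")
  # low support blocks the merge
  low <- ape::read.tree(text = "((X:0.10,g1:0.08)40:0.05,g2:0.09,g3:0.10);")
  sg2 <- assign_subgroups(m, tree = low, threshold = 75, boot_floor = 70)
  expect_false(sg2$subgroup[sg2$id == "X"] == sg2$subgroup[sg2$id == "g1"])
  # and without a tree X stays a singleton
  sg3 <- assign_subgroups(m, threshold = 75)
  expect_equal(sum(sg3$subgroup == sg3$subgroup[sg3$id == "X"]), 1L)
})

test_that("three-taxon neighbor joining solves the branch equations", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), 0.5)
  expect_equal(unname(bl["b"]), 1.5)
  expect_equal(unname(bl["c"]), 2.5)
})

test_that("neighbor joining recovers additive trees exactly", {
  # four-point construction: ((a,b),(c,d)) with known branch lengths
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  bl <- c(a = 1, b = 2, c = 1.5, d = 2.5); mid <- 1
  d["a", "b"] <- d["b", "a"] <- bl["a"] + bl["b"]
  d["c", "d"] <- d["d", "c"] <- bl["c"] + bl["d"]
  for (x in c("a", "b")) for (y in c("c", "d")) {
    d[x, y] <- d[y, x] <- bl[x] + mid + bl[y]
  }
  tr <- nj_tree(d)
  want <- ape::read.tree(text = "((a:1,b:2):1,(c:1.5,d:2.5):0);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(want)), 0,
               ignore_attr = TRUE)
  # total tree length is preserved for additive input
  expect_equal(sum(tr$edge.length), sum(bl) + mid)

  # random additive instances, checked against the generating topology and
  # cross-checked against the reference implementation
  set.seed(11)
  for (trial in 1:15) {
    n <- sample(5:8, 1)
    gen <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    dm <- stats::cophenetic(gen)
    mine <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(mine)), 0,
                 ignore_attr = TRUE)
    ref <- ape::nj(dm)
    expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(mine)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("identical sequences join first as a zero-length cherry", {
  seqs <- c(x1 = "ACGTACGTAA", x2 = "ACGTACGTAA", y = "TTTTTTTTTT", z = "ACGTAAAATT")
  d <- p_distance(seqs)
  tr <- nj_tree(d)
  # x1 and x2 are sisters with zero terminal branches
  pair <- tr$edge[tr$edge[, 2] %in% match(c("x1", "x2"), tr$tip.label), 1]
  expect_equal(pair[1], pair[2])
  expect_equal(tr$edge.length[tr$edge[, 2] %in% match(c("x1", "x2"), tr$tip.label)],
               c(0, 0))
})

test_that("nj_tree validates its input", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(matrix(runif(9), 3, 3)), "symmetric")
  expect_error(nj_tree(matrix(0, 2, 2)), "at least 3")
})

test_that("bootstrap supports behave at the extremes and under permutation", {
  set.seed(19)
  # two well-separated clades with many invariant diagnostic sites
  blockA <- paste(rep("A", 250), collapse = "")
  blockC <- paste(rep("C", 250), collapse = "")
  noise <- function() rand_dna(30)
  aln <- c(
    a1 = paste0(blockA, noise()), a2 = paste0(blockA, noise()),
    a3 = paste0(blockA, noise()),
    b1 = paste0(blockC, noise()), b2 = paste0(blockC, noise()),
    b3 = paste0(blockC, noise())
  )
  tr <- bootstrap_support(aln, replicates = 50, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_gte(max(sup, na.rm = TRUE), 99)

  one <- bootstrap_support(aln, replicates = 1, seed = 9)
  s1 <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))

  # permuting taxon order leaves the central-split support unchanged
  perm <- aln[c(4, 1, 5, 2, 6, 3)]
  tr2 <- bootstrap_support(perm, replicates = 50, seed = 5)
  central <- function(t) {
    s <- suppressWarnings(as.numeric(t$node.label))
    max(s, na.rm = TRUE)
  }
  expect_equal(central(tr2), central(tr))
})

test_that("segment naming follows subgroup, cluster and position rules", {
  # V genes without references: positional subgroup names, members suffixed
  lo <- tibble::tibble(
    id = c("V001", "V002", "V003", "J001", "J002", "J003", "C001"),
    type = c("V", "V", "V", "J", "J", "J", "C"),
    position = c(100, 500, 900, 2000, 2400, 2800, 3500),
    cluster = c(NA, NA, NA, 1L, 1L, 1L, 1L)
  )
  asg <- tibble::tibble(id = c("V001", "V002", "V003"),
                        subgroup = c(1L, 1L, 2L),
                        provenance = "threshold")
  nm <- name_segments(asg, locus_order = lo, locus_prefix = "TRA")
  expect_equal(nm$name[nm$id == "V001"], "TRAV1-1")
  expect_equal(nm$name[nm$id == "V002"], "TRAV1-2")
  expect_equal(nm$name[nm$id == "V003"], "TRAV2")
  # single cluster: unhyphenated J names by position
  expect_equal(nm$name[nm$id == "J002"], "TRAJ2")
  expect_equal(nm$name[nm$id == "C001"], "TRAC1")

  # two clusters: hyphenated J names, numbered C genes
  lo2 <- tibble::tibble(
    id = c("J001", "J002", "J003", "C001", "C002"),
    type = c("J", "J", "J", "C", "C"),
    position = c(100, 200, 900, 400, 1200),
    cluster = c(1L, 1L, 2L, 1L, 2L)
  )
  nm2 <- name_segments(NULL, locus_order = lo2, locus_prefix = "TRB")
  expect_equal(nm2$name[nm2$id == "J001"], "TRBJ1-1")
  expect_equal(nm2$name[nm2$id == "J002"], "TRBJ1-2")
  expect_equal(nm2$name[nm2$id == "J003"], "TRBJ2-1")
  expect_equal(sort(nm2$name[nm2$id %in% c("C001", "C002")]), c("TRBC1", "TRBC2"))

  # nearest named reference clade donates the subgroup designation
  tree <- ape::read.tree(
    text = "((V001:0.05,RefTRAV8:0.05):0.3,(V002:0.05,RefTRAV19:0.06):0.3,V003:0.5);"
  )
  lo3 <- tibble::tibble(id = c("V001", "V002", "V003"), type = "V",
                        position = c(100, 500, 900), cluster = NA_integer_)
  asg3 <- tibble::tibble(id = lo3$id, subgroup = 1:3, provenance = "threshold")
  nm3 <- name_segments(asg3, tree = tree,
                       reference_names = c(RefTRAV8 = "TRAV8", RefTRAV19 = "TRAV19"),
                       locus_order = lo3, locus_prefix = "TRA")
  expect_equal(nm3$name[nm3$id == "V001"], "TRAV8")
  expect_equal(nm3$name[nm3$id == "V002"], "TRAV19")
  expect_equal(nm3$provenance[nm3$id == "V003"], "position_fallback")
})
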