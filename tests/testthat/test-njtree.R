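test_that("three-taxon NJ branch lengths follow the closed form", {
  d <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(bl["B"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(bl["C"]), (0.4 + 0.5 - 0.3) / 2)
})

test_that("NJ exactly recovers additive four-taxon trees", {
  # ((A:1,B:2):1,(C:3,D:1)) -> pairwise path lengths
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 3
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 4
  d["C", "D"] <- d["D", "C"] <- 4
  tr <- nj_tree(d)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
               d, tolerance = 1e-12)
  # AB | CD is the split
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("NJ recovers random additive matrices (path-length oracle)", {
  set.seed(606)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    src <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- as.matrix(ape::cophenetic.phylo(src))
    tr <- nj_tree(d)
    expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
                 d, tolerance = 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(src)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("row/column permutation yields an isomorphic tree", {
  recs <- tiny_library(n_species = 4, n_per = 2, len = 250, seed = 9)
  dm <- distance_matrix(recs)
  tr1 <- nj_tree(dm, "p")
  perm <- sample(length(dm$labels))
  m <- dm$p[perm, perm]
  tr2 <- nj_tree(m)
  expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
})

test_that("negative branch lengths are clamped with sibling compensation", {
  # a matrix known to produce a negative NJ branch estimate
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0) * 1.0, 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 5.9  # near-degenerate cherry
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  # undefined entries are rejected with the pair named
  dna <- d; dna["A", "C"] <- dna["C", "A"] <- NA
  expect_error(nj_tree(dna), "non-finite distance")
})

test_that("newick round-trip preserves topology, lengths and supports", {
  set.seed(707)
  for (rep in 1:20) {
    tr <- ape::rtree(sample(4:12, 1))
    txt <- write_newick(tr)
    back <- read_newick(text = txt)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
                 ignore_attr = TRUE)
    o <- match(back$tip.label, tr$tip.label)
    coph1 <- as.matrix(ape::cophenetic.phylo(tr))
    coph2 <- as.matrix(ape::cophenetic.phylo(back))
    expect_equal(coph2[tr$tip.label, tr$tip.label],
                 coph1, tolerance = 1e-5)
  }
  tr3 <- read_newick(text = "(A:1.0,B:2.0,C:1.5);")
  expect_equal(sort(tr3$tip.label), c("A", "B", "C"))
  # supports serialize as internal node labels
  tr4 <- read_newick(text = "((A:1,B:1)95:1,(C:1,D:1)80:1);")
  expect_true("95" %in% tr4$node.label)
  expect_error(read_newick(text = "((A,B,C"), "malformed")
})

test_that("bootstrap gives full support on clean separated data, deterministically", {
  # two cherries, each pair sharing 30 scattered diagnostic sites: the single
  # internal split is supported by every informative column
  set.seed(131)
  anc <- rand_seq(300)
  posA <- seq(1, 118, by = 4); posB <- seq(2, 119, by = 4)
  gA <- mutate_at(anc, posA, rep("C", 30))
  gB <- mutate_at(anc, posB, rep("G", 30))
  recs <- make_records(
    c(A1 = mutate_at(gA, 201, "T"), A2 = mutate_at(gA, 202, "T"),
      B1 = mutate_at(gB, 203, "T"), B2 = mutate_at(gB, 204, "T")),
    c("Aa a", "Aa a", "Bb b", "Bb b"))
  msa <- progressive_msa(recs)
  b1 <- bootstrap_support(msa, n_replicates = 100, seed = 99)
  expect_true(all(b1$supports == 100))
  expect_equal(b1$n_dropped, 0L)
  b2 <- bootstrap_support(msa, n_replicates = 100, seed = 99)
  expect_identical(b1$supports, b2$supports)
  expect_identical(write_newick(b1$tree), write_newick(b2$tree))
  # supports land on the reference tree's internal nodes
  expect_true(any(nzchar(b1$tree$node.label)))
  expect_true(all(b1$supports >= 0 & b1$supports <= 100))
})

test_that("a short internal edge gets the lowest bootstrap support", {
  set.seed(808)
  # backbone with two well-separated cherries and one barely supported split
  anc <- rand_seq(400)
  posA <- seq(1, 120, by = 4)   # 30 scattered diagnostic sites per group
  posB <- seq(2, 121, by = 4)
  posC <- seq(203, 263, by = 2)
  gA <- mutate_at(anc, posA, rep("C", 30))
  gB <- mutate_at(anc, posB, rep("G", 30))
  a1 <- mutate_at(gA, 301, "T"); a2 <- mutate_at(gA, 302, "T")
  b1 <- mutate_at(gB, 303, "T"); b2 <- mutate_at(gB, 304, "T")
  # fifth taxon sharing the A-side diagnostics plus private sites
  c1 <- mutate_at(mutate_at(anc, posA, rep("C", 30)), posC, rep("T", 31))
  recs <- make_records(c(A1 = a1, A2 = a2, B1 = b1, B2 = b2, C1 = c1),
                       c("Aa a", "Aa a", "Bb b", "Bb b", "Cc c"))
  msa <- progressive_msa(recs)
  b <- bootstrap_support(msa, n_replicates = 200, seed = 3, metric = "p")
  expect_true(length(b$supports) >= 2)
  expect_true(min(b$supports) < 100)
})
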