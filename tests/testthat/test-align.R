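test_that("global alignment matches simple expectations", {
  al <- nw_align("ACGT", "ACGT")
  expect_equal(al$a, "ACGT")
  expect_equal(al$b, "ACGT")
  expect_equal(al$score, 4 * 2)

  al2 <- nw_align("ACGT", "ACGGT")
  expect_equal(nchar(al2$a), nchar(al2$b))
  expect_equal(gsub("-", "", al2$a), "ACGT")
  expect_equal(gsub("-", "", al2$b), "ACGGT")
  expect_equal(sum(strsplit(al2$a, "")[[1]] == "-"), 1L)
})

test_that("alignment score equals the exhaustive-search optimum", {
  set.seed(101)
  params <- align_params()
  for (rep in 1:40) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    a <- rand_seq(n); b <- rand_seq(m)
    got <- nw_align(a, b, params)$score
    want <- brute_align_score(a, b, params$match, params$mismatch,
                              params$gap_open, params$gap_ext)
    expect_equal(got, want, info = paste(a, b))
    # degapping recovers the inputs
    al <- nw_align(a, b, params)
    expect_equal(gsub("-", "", al$a), a)
    expect_equal(gsub("-", "", al$b), b)
  }
  # and under a different scoring scheme
  p2 <- align_params(match = 3, mismatch = -2, gap_open = 4, gap_ext = 2)
  for (rep in 1:10) {
    a <- rand_seq(6); b <- rand_seq(7)
    expect_equal(nw_align(a, b, p2)$score,
                 brute_align_score(a, b, 3, -2, 4, 2))
  }
})

test_that("site-pattern counting applies pairwise deletion", {
  sc <- count_site_patterns("ACGT", "GCGT")
  expect_equal(sc$L, 4L)
  expect_equal(sc$P1, 0.25)  # A<->G purine transition
  expect_equal(sc$P2, 0)
  expect_equal(sc$Q, 0)
  expect_equal(sc$n_subst, 1L)

  expect_equal(count_site_patterns("AC-T", "ACGT")$L, 3L)
  expect_equal(count_site_patterns("ANGT", "ACGT")$L, 3L)
  expect_equal(count_site_patterns("ACGT", "ACGA")$Q, 0.25)  # T<->A
  expect_equal(count_site_patterns("ACGT", "ACGC")$P2, 0.25) # T<->C
  expect_error(count_site_patterns("NNNN", "ACGT"), "no comparable")

  # pooled frequencies over both sequences
  expect_equal(count_site_patterns("AAAA", "AAAC")$freq,
               c(A = 7 / 8, C = 1 / 8, G = 0, T = 0))
})

test_that("p-distance equals brute-force mismatch proportion", {
  expect_equal(p_distance(count_site_patterns("ACGT", "ACGT")), 0)
  sc <- count_site_patterns(strrep("ACGTT", 150),
                            mutate_at(strrep("ACGTT", 150), c(1, 2, 3),
                                      c("C", "G", "T")))  # A->C, C->G, G->T
  expect_equal(p_distance(sc), 3 / 750)
  set.seed(202)
  for (rep in 1:50) {
    a <- rand_seq(60); b <- rand_seq(60)
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    expect_equal(p_distance(count_site_patterns(a, b)),
                 sum(av != bv) / 60)
  }
})

test_that("TN93 distance: zero limit, K2P limit, and tn93 >= p", {
  # identical pair
  expect_equal(tn93_distance(count_site_patterns("ACGTACGT", "ACGTACGT")), 0)

  # equal base frequencies and P1 = P2 reduce TN93 to Kimura 2-parameter
  k2p <- function(P, Q) -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  for (v in list(c(0.02, 0.01), c(0.06, 0.03), c(0.10, 0.08))) {
    P <- v[1]; Q <- v[2]
    sc <- list(L = 1000L, P1 = P / 2, P2 = P / 2, Q = Q,
               freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
    expect_equal(tn93_distance(sc), k2p(P, Q), tolerance = 1e-12)
  }

  # correction never shrinks the distance where defined
  set.seed(303)
  for (rep in 1:30) {
    a <- rand_seq(400)
    npos <- sample(1:60, 1)
    pos <- sample(400, npos)
    b <- mutate_at(a, pos, sample(c("A", "C", "G", "T"), npos, TRUE))
    sc <- count_site_patterns(a, b)
    d <- tn93_distance(sc)
    if (!is.na(d)) expect_gte(d, p_distance(sc) - 1e-12)
  }

  # saturation flags undefined rather than erroring
  sat <- list(L = 100L, P1 = 0.3, P2 = 0.3, Q = 0.39,
              freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_true(is.na(tn93_distance(sat)))
  # zero frequency is an error
  z <- list(L = 10L, P1 = 0, P2 = 0, Q = 0,
            freq = c(A = 0.5, C = 0.5, G = 0, T = 0))
  expect_error(tn93_distance(z), "frequencies")
})

test_that("distance matrices are symmetric, zero-diagonal, order-invariant", {
  recs <- tiny_library(n_species = 4, n_per = 2, len = 240, seed = 7)
  dm <- distance_matrix(recs)
  expect_true(all(dm$p == t(dm$p)))
  expect_true(all(diag(dm$p) == 0))
  expect_true(all(diag(dm$tn93) == 0))
  expect_true(all(dm$p >= 0 & dm$p <= 1))

  # permutation invariance
  perm <- sample(nrow(recs))
  dm2 <- distance_matrix(recs[perm, ])
  expect_equal(dm2$p[dm$labels, dm$labels], dm$p)
  expect_equal(dm2$subst[dm$labels, dm$labels], dm$subst)

  # identical records give the zero matrix
  same <- make_records(setNames(rep(strrep("ACGT", 50), 3), paste0("I", 1:3)),
                       rep("Aa bb", 3))
  expect_true(all(distance_matrix(same)$p == 0))
})

test_that("distances agree with ape::dist.dna on an ungapped alignment", {
  set.seed(404)
  recs <- tiny_library(n_species = 5, n_per = 2, len = 400, seed = 99)
  dm <- distance_matrix(recs)
  chmat <- do.call(rbind, strsplit(tolower(recs$seq), ""))
  rownames(chmat) <- recs$accession
  dnab <- ape::as.DNAbin(chmat)
  p_ape <- as.matrix(ape::dist.dna(dnab, model = "raw",
                                   pairwise.deletion = TRUE))
  tn_ape <- as.matrix(ape::dist.dna(dnab, model = "TN93",
                                    pairwise.deletion = TRUE))
  expect_equal(dm$p[recs$accession, recs$accession], p_ape,
               tolerance = 1e-12, ignore_attr = TRUE)
  # ape pools base frequencies across the whole alignment; we pool per pair,
  # so TN93 values agree closely but not to machine precision
  expect_equal(dm$tn93[recs$accession, recs$accession], tn_ape,
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("intra/interspecific summaries match direct computation", {
  recs <- tiny_library(n_species = 4, n_per = 3, len = 300, seed = 17)
  dm <- distance_matrix(recs)
  intra <- intraspecific_summary(dm)
  sp1 <- intra$per_species[1, ]
  idx <- which(dm$species == sp1$species)
  ut <- upper.tri(dm$p[idx, idx])
  expect_equal(sp1$max_dist, max(dm$p[idx, idx][ut]))
  expect_equal(sp1$mean_dist, mean(dm$p[idx, idx][ut]))
  expect_equal(sp1$max_subst, max(dm$subst[idx, idx][ut]))

  inter <- interspecific_summary(dm)
  # brute-force recomputation over all qualifying pairs
  for (r in seq_len(nrow(inter))) {
    g <- inter$genus[r]
    vals <- c()
    for (i in seq_along(dm$labels)) for (j in seq_along(dm$labels)) {
      if (i < j && dm$genus[i] == g && dm$genus[j] == g &&
          dm$species[i] != dm$species[j]) {
        vals <- c(vals, dm$p[i, j])
      }
    }
    expect_equal(inter$mean_dist[r], mean(vals))
    expect_equal(inter$min_dist[r], min(vals))
    expect_equal(inter$max_dist[r], max(vals))
  }

  # single-sequence species report NA distances
  solo <- rbind(recs, make_records(c(Z1 = recs$seq[1]), "Zz solo"))
  dms <- distance_matrix(solo)
  per <- intraspecific_summary(dms)$per_species
  expect_true(is.na(per$max_dist[per$species == "Zz solo"]))
})

test_that("nearest heterospecific distance equals brute-force minimum", {
  recs <- tiny_library(n_species = 5, n_per = 2, len = 300, seed = 23)
  dm <- distance_matrix(recs)
  for (s in unique(dm$species)) {
    nn <- nearest_heterospecific(dm, s)
    foc <- which(dm$species == s); het <- which(dm$species != s)
    expect_equal(nn$distance, min(dm$p[foc, het]))
  }
  # identical cross-species pair reports distance 0
  recs2 <- recs
  recs2$seq[recs2$species == unique(recs2$species)[2]][1] <- recs2$seq[1]
  dm2 <- distance_matrix(recs2)
  expect_equal(nearest_heterospecific(dm2, recs2$species[1])$distance, 0)
  # lone species errors
  one <- make_records(c(A = "ACGT", B = "ACGA"), rep("Aa bb", 2))
  expect_error(nearest_heterospecific(distance_matrix(one), "Aa bb"),
               "heterospecific")
})

test_that("progressive MSA stacks equal-length substitution-only records", {
  recs <- tiny_library(n_species = 3, n_per = 2, len = 200, seed = 31)
  msa <- progressive_msa(recs)
  expect_equal(length(unique(nchar(msa$rows))), 1L)
  expect_equal(unname(nchar(msa$rows[1])), 200L)  # no gap columns needed
  for (i in seq_len(nrow(recs))) {
    expect_equal(gsub("-", "", msa$rows[[recs$accession[i]]]), recs$seq[i])
  }
  # identical records: trivial stacking
  same <- make_records(setNames(rep(strrep("ACGT", 30), 3), paste0("I", 1:3)),
                       paste("Aa", c("bb", "cc", "dd")))
  expect_true(all(nchar(progressive_msa(same)$rows) == 120))
})

test_that("progressive MSA places a planted deletion as one gap run", {
  set.seed(505)
  anc <- rand_seq(160)
  # two carriers of a 3-nt deletion at position 80, two non-carriers
  del <- paste0(substr(anc, 1, 79), substr(anc, 83, 160))
  v1 <- mutate_at(anc, 10, "A"); v2 <- mutate_at(anc, 20, "C")
  c1 <- mutate_at(del, 30, "G"); c2 <- mutate_at(del, 40, "T")
  recs <- make_records(c(N1 = v1, N2 = v2, D1 = c1, D2 = c2),
                       c("Aa bb", "Aa bb", "Aa cc", "Aa cc"))
  msa <- progressive_msa(recs)
  expect_equal(length(unique(nchar(msa$rows))), 1L)
  for (carrier in c("D1", "D2")) {
    gaps <- gregexpr("-+", msa$rows[[carrier]])[[1]]
    expect_equal(length(gaps), 1L)
    expect_equal(attr(gaps, "match.length"), 3L)
  }
  for (nc in c("N1", "N2")) expect_false(grepl("-", msa$rows[[nc]]))
})
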