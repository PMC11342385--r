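test_that("pure clusters: monophyletic species and hand-built splits", {
  tr <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1,(C1:1,C2:1):1);")
  labels <- setNames(c("Aa a", "Aa a", "Bb b", "Bb b", "Cc c", "Cc c"),
                     c("A1", "A2", "B1", "B2", "C1", "C2"))
  expect_equal(pure_clusters(tr, labels, "Aa a")$k, 1L)
  expect_equal(pure_clusters(tr, labels, "Bb b")$k, 1L)

  # ((A1,(B1,A2)),B2): species A broken into two pure clades
  tr2 <- ape::read.tree(text = "((A1:1,(B1:1,A2:1):1):1,B2:1);")
  lab2 <- setNames(c("Aa a", "Bb b", "Aa a", "Bb b"),
                   c("A1", "B1", "A2", "B2"))
  pc <- pure_clusters(tr2, lab2, "Aa a")
  expect_equal(pc$k, 2L)
  expect_setequal(unlist(pc$clusters), c("A1", "A2"))
  expect_equal(pure_clusters(tr2, lab2, "Bb b")$k, 2L)

  expect_error(pure_clusters(tr, labels, "Zz z"), "absent")
})

test_that("pure clusters equal exhaustive clade enumeration on random trees", {
  set.seed(909)
  for (rep in 1:60) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("T", seq_len(n))
    nsp <- sample(2:4, 1)
    sp <- paste0("Sp", sample(nsp, n, replace = TRUE))
    # ensure at least 2 species present
    sp[1] <- "Sp1"; sp[2] <- "Sp2"
    labels <- setNames(paste("Genus", sp), tr$tip.label)
    for (s in unique(labels)) {
      got <- pure_clusters(tr, labels, s)$k
      want <- brute_pure_clusters(tr, labels, s)
      expect_equal(got, want, info = paste("rep", rep, s))
    }
  }
})

test_that("identity sharing is detected with witnesses", {
  recs <- tiny_library(n_species = 3, n_per = 2, len = 200, seed = 15)
  dm <- distance_matrix(recs)
  s1 <- unique(recs$species)[1]
  expect_false(shares_identity(dm, s1)$shared)

  recs2 <- recs
  recs2$seq[3] <- recs2$seq[1]  # species 2 sequence copies species 1 haplotype
  dm2 <- distance_matrix(recs2)
  sh <- shares_identity(dm2, s1)
  expect_true(sh$shared)
  expect_true(all(sh$witnesses$other_species != s1))
  # epsilon 0 means close-but-distinct does not count
  expect_false(shares_identity(dm2, unique(recs$species)[3])$shared)
})

test_that("classification assigns the four categories and judgements", {
  # two clean species: both Match/success
  recs <- tiny_library(n_species = 2, n_per = 2, len = 300, div = 20, seed = 3)
  ev <- barcode_eval(recs)
  a <- ev$assessments
  expect_equal(a$category, rep("Match", 2))
  expect_equal(a$judgement, rep("success", 2))
  expect_true(all(a$k == 1L))

  # Mixture: species B's sequences both identical to A haplotypes and split
  set.seed(77)
  base <- rand_seq(300)
  far <- mutate_at(base, 1:40, rep("A", 40))
  a1 <- base
  a2 <- mutate_at(base, 50, "T")
  recs2 <- make_records(
    c(A1 = a1, A2 = a2, B1 = a1, B2 = a2, C1 = far, C2 = mutate_at(far, 60, "G")),
    c("Gg aa", "Gg aa", "Gg bb", "Gg bb", "Gg cc", "Gg cc"))
  ev2 <- barcode_eval(recs2)
  a2df <- ev2$assessments
  expect_equal(a2df$category[a2df$species == "Gg bb"], "Mixture")
  expect_equal(a2df$judgement[a2df$species == "Gg bb"], "failure")
  expect_equal(a2df$category[a2df$species == "Gg cc"], "Match")

  # Merge: single cluster whose haplotype is shared
  recs3 <- make_records(
    c(A1 = a1, A2 = a1, B1 = a1, B2 = a1, C1 = far, C2 = far),
    c("Gg aa", "Gg aa", "Gg bb", "Gg bb", "Gg cc", "Gg cc"))
  ev3 <- barcode_eval(recs3)
  a3 <- ev3$assessments
  expect_equal(a3$category[a3$species == "Gg aa"], "Merge")
  expect_equal(a3$category[a3$species == "Gg bb"], "Merge")
  expect_equal(a3$category[a3$species == "Gg cc"], "Match")

  # single-specimen rule: shared haplotype is a failure, else judged by nn
  recs4 <- make_records(
    c(A1 = a1, A2 = a2, S1 = a1, T1 = far),
    c("Gg aa", "Gg aa", "Gg ss", "Gg tt"))
  ev4 <- barcode_eval(recs4)
  a4 <- ev4$assessments
  expect_equal(a4$category[a4$species == "Gg ss"], "NA_single")
  expect_true(a4$single_specimen_merge[a4$species == "Gg ss"])
  expect_equal(a4$judgement[a4$species == "Gg ss"], "failure")
  expect_equal(a4$judgement[a4$species == "Gg tt"], "success")

  # every multi-sequence species gets exactly one category
  for (ev_i in list(ev, ev2, ev3)) {
    multi <- ev_i$assessments$n_seqs >= 2
    expect_true(all(ev_i$assessments$category[multi] %in%
                      c("Match", "Split", "Merge", "Mixture")))
  }
})

test_that("caution threshold boundary: exactly 0.01 is caution, above is success", {
  set.seed(88)
  base <- rand_seq(300)
  # neighbour at exactly 3/300 = 0.01
  nb <- mutate_at(base, c(10, 20, 30), c("A", "A", "A"))
  # ensure the 3 positions actually differ
  ch <- strsplit(base, "")[[1]]
  ch[c(10, 20, 30)] <- ifelse(ch[c(10, 20, 30)] == "A", "C", "A")
  nb <- paste(ch, collapse = "")
  far <- mutate_at(base, 101:140, rep("G", 40))
  recs <- make_records(c(X1 = base, Y1 = nb, Z1 = far),
                       c("Gg xx", "Gg yy", "Gg zz"))
  ev <- barcode_eval(recs)
  a <- ev$assessments
  expect_equal(a$nn_hetero[a$species == "Gg xx"], 0.01)
  expect_equal(a$judgement[a$species == "Gg xx"], "caution")
  expect_equal(a$judgement[a$species == "Gg zz"], "success")

  # monotonicity: raising the threshold never turns caution into success
  for (thr in c(0.005, 0.01, 0.02, 0.05)) {
    evt <- barcode_eval(recs, classifier_config(caution_threshold = thr))
    at <- evt$assessments
    jx <- at$judgement[at$species == "Gg xx"]
    if (thr < 0.01) expect_equal(jx, "success") else expect_equal(jx, "caution")
  }
})

test_that("caution report mirrors the grouped table layout", {
  set.seed(99)
  base <- rand_seq(300)
  nb <- mutate_at(base, 5, if (substr(base, 5, 5) == "A") "C" else "A")
  far <- mutate_at(base, 101:140, rep("G", 40))
  recs <- make_records(c(X1 = base, Y1 = nb, Z1 = far),
                       c("Gg xx", "Gg yy", "Hh zz"))
  ev <- barcode_eval(recs)
  rep_tab <- caution_report(ev$assessments, ev$config)
  expect_true(all(grepl("Cautions", rep_tab$label)))
  expect_false("Hh zz" %in% rep_tab$species)
  # success-only input gives an empty report
  clean <- tiny_library(n_species = 2, n_per = 2, len = 300, div = 20, seed = 3)
  evc <- barcode_eval(clean)
  expect_equal(nrow(caution_report(evc$assessments)), 0L)
})

test_that("discriminability arithmetic", {
  mk <- function(n, nf) {
    data.frame(species = paste0("s", seq_len(n)),
               judgement = c(rep("failure", nf),
                             rep("success", n - nf)))
  }
  d <- discriminability(mk(150, 6))
  expect_equal(d$n_unique, 144L)
  expect_equal(d$pct_unique, 96.0)
  expect_equal(discriminability(mk(30, 0))$pct_unique, 100.0)
  expect_equal(discriminability(mk(30, 2))$pct_unique, 93.3)
})

test_that("curation screen flags planted label errors only", {
  recs <- tiny_library(n_species = 4, n_per = 2, len = 300, div = 20, seed = 19)
  dm <- distance_matrix(recs)
  expect_equal(nrow(curation_screen(dm)), 0L)

  # swap one sequence's label into a different genus
  recs2 <- recs
  recs2$species[1] <- recs2$species[7]
  recs2$genus[1] <- recs2$genus[7]
  dm2 <- distance_matrix(recs2)
  flagged <- curation_screen(dm2)
  expect_true(recs2$accession[1] %in% flagged$accession)

  # deep intraspecific split: flagged at default, passes at looser threshold
  set.seed(7)
  base <- rand_seq(300)
  deep <- mutate_at(base, 1:18, rep("A", 18))  # ~0.06 away
  ch <- strsplit(base, "")[[1]]
  ch[1:18] <- ifelse(ch[1:18] == "A", "C", "A")
  deep <- paste(ch, collapse = "")
  other <- mutate_at(base, 250:280, rep("G", 31))
  recs3 <- make_records(c(P1 = base, P2 = deep, Q1 = other),
                        c("Gg pp", "Gg pp", "Gg qq"))
  dm3 <- distance_matrix(recs3)
  expect_true(nrow(curation_screen(dm3, max_conspecific_dist = 0.05)) > 0)
  expect_equal(nrow(curation_screen(dm3, max_conspecific_dist = 0.08,
                                    require_genus_neighbor = FALSE)), 0L)
})
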