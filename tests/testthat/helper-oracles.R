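# Independent oracles and fixture builders used across the suite.

# Build a record data.frame from named sequences ("accession" = seq) and a
# parallel species vector.
make_records <- function(seqs, species, region = "longer12S") {
  data.frame(
    accession = names(seqs),
    species = species,
    genus = vapply(strsplit(species, " ", fixed = TRUE), `[`, character(1), 1L),
    voucher = NA_character_,
    source = "determined",
    region = region,
    seq = unname(seqs),
    stringsAsFactors = FALSE
  )
}

# Exhaustive-search optimal global alignment score. Enumerates every monotone
# alignment path recursively, scoring columns directly and charging
# gap_open + gap_ext at each gap opening and gap_ext per extension. Completely
# independent of the DP implementation; only practical for short strings.
brute_align_score <- function(a, b, match = 2, mismatch = -1,
                              gap_open = 12, gap_ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  gi <- gap_open + gap_ext
  best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i > n && j > m) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) match else mismatch
      rec(i + 1L, j + 1L, "M", acc + s)
    }
    if (i <= n) {
      rec(i + 1L, j, "X", acc - if (prev == "X") gap_ext else gi)
    }
    if (j <= m) {
      rec(i, j + 1L, "Y", acc - if (prev == "Y") gap_ext else gi)
    }
  }
  rec(1L, 1L, "M", 0)
  best
}

# Brute-force count of maximal species-pure bipartition sides of an unrooted
# tree. Enumerates every edge's two sides from the edge matrix alone (no reuse
# of package internals), keeps the sides whose tips are all conspecific with
# `species`, and counts the inclusion-maximal ones.
brute_pure_clusters <- function(tree, species_labels, species) {
  tips <- tree$tip.label
  nt <- length(tips)
  edges <- tree$edge
  nn <- max(edges)
  adj <- vector("list", nn)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  side_tips <- function(start, avoid) {
    seen <- logical(nn); seen[avoid] <- TRUE
    stack <- start; out <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      if (v <= nt) out <- c(out, v)
      stack <- c(stack, adj[[v]])
    }
    sort(out)
  }
  focal <- which(species_labels[tips] == species)
  sides <- list()
  for (e in seq_len(nrow(edges))) {
    s1 <- side_tips(edges[e, 2], edges[e, 1])
    s2 <- setdiff(seq_len(nt), s1)
    for (s in list(s1, s2)) {
      if (length(s) && all(s %in% focal)) sides[[length(sides) + 1L]] <- s
    }
  }
  if (!length(sides)) return(length(focal))  # no pure side: singletons only
  sides <- unique(sides)
  maximal <- Filter(function(s) {
    !any(vapply(sides, function(o)
      length(o) > length(s) && all(s %in% o), logical(1)))
  }, sides)
  covered <- sort(unique(unlist(maximal)))
  # focal tips not inside any pure side stand alone
  length(maximal) + sum(!(focal %in% covered))
}

# Random nucleotide string.
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Mutate a sequence at fixed positions (deterministic substitutions).
mutate_at <- function(seq, pos, to) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- to
  paste(ch, collapse = "")
}

# Tiny library of diverged species for classifier tests: each species gets a
# private set of scattered diagnostic substitutions on a shared backbone.
tiny_library <- function(n_species = 4, n_per = 2, len = 300, div = 12,
                         intra = 1, seed = 42) {
  set.seed(seed)
  backbone <- rand_seq(len)
  all_pos <- sample(len)  # disjoint scattered positions per species
  seqs <- character(0); species <- character(0)
  acc <- 0L
  bases <- c("A", "C", "G", "T")
  for (s in seq_len(n_species)) {
    pos <- all_pos[((s - 1) * div + 1):(s * div)]
    ch <- strsplit(backbone, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(x) sample(setdiff(bases, x), 1),
                      character(1))
    spseq <- paste(ch, collapse = "")
    for (k in seq_len(n_per)) {
      acc <- acc + 1L
      sq <- spseq
      if (k > 1 && intra > 0) {
        p <- len - s * 2 - k  # deterministic-ish distinct positions
        sq <- mutate_at(sq, p, sample(setdiff(bases, substr(sq, p, p)), 1))
      }
      seqs <- c(seqs, setNames(sq, sprintf("ACC%03d", acc)))
      species <- c(species, sprintf("Genus%02d species%02d", (s + 1) %/% 2, s))
    }
  }
  make_records(seqs, species)
}
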