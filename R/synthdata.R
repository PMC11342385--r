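# Synthetic barcode reference libraries with known ground truth. Sequences
# evolve under the TN93 substitution model along a pure-birth species tree,
# with a planted hypervariable core flanked by conserved primer sites, then
# optional introgression / shared-haplotype events. The regime the defaults
# emulate: ~150 species with ~2 sequences each (about two thirds singletons),
# 750 nt fragments holding a 166-199 nt core, intraspecific p-distances
# mostly < 0.01 and congeneric interspecific p-distances up to ~0.2.

# Synthetic primer pair planted at the core flanks (arbitrary fixed 20/24-mers;
# not the sequences of any published primer set).
.SIM_FWD_PRIMER <- "GCCTAAGCATTCGACTGGTA"
.SIM_REV_PRIMER <- "TCAGGATCGAACGTTACCGATGCA"  # antisense 5'->3'

#' Simulator configuration
#'
#' Defaults describe the reference regime the package targets (see the
#' methods vignette): 150 species, singleton probability 0.647 with
#' multi-sequence counts 2 + Poisson(1.85) capped at 20, 750 nt sequences,
#' one hypervariable core of 166-199 nt evolving 1.5x faster, conserved
#' (invariant) primer sites, mean interspecific depth 0.05
#' substitutions/site, intraspecific depth 0.002, and the default event set
#' `"auto"`: two partial congeneric introgressions plus one identical-
#' haplotype injection between congeneric singletons.
#'
#' @param n_species number of species.
#' @param p_single probability a species has exactly one sequence.
#' @param extra_mean Poisson mean for extra sequences of multi-sequence
#'   species (counts are `2 + Poisson(extra_mean)`, capped at `max_seqs`).
#' @param max_seqs cap on sequences per species.
#' @param seq_length sequence length (nt), substitution-only runs keep it.
#' @param core_length_range the planted hypervariable window length is drawn
#'   uniformly from this range (one draw per run).
#' @param fwd_primer,rev_primer planted primer site sequences (sense /
#'   antisense 5'->3'); synthetic defaults.
#' @param freq TN93 equilibrium base frequencies (A, C, G, T; sum to 1).
#' @param alpha1,alpha2,beta relative rates of purine transitions, pyrimidine
#'   transitions and transversions (the matrix is normalized to one expected
#'   substitution per site per unit branch length).
#' @param interspecific_depth target mean tip-pair path length of the species
#'   tree divided by 2 (substitutions/site).
#' @param intraspecific_depth length of the extra branch each individual
#'   evolves from its species tip.
#' @param hypervariable_rate_multiplier rate factor inside the core (>= 1).
#' @param primer_rate_multiplier rate factor in the primer sites (0 =
#'   perfectly conserved, the default).
#' @param indel_rate expected indel events per flank site per individual
#'   (0 disables; indels never touch primer sites or the core).
#' @param introgression_events `"auto"`, `NULL`, or a list of
#'   `list(donor=, recipient=, n_recipients=)`.
#' @param identical_injections `"auto"`, `NULL`, or a list of 2-vectors of
#'   species names.
#' @param seed RNG seed; the whole simulation is a deterministic function of
#'   the config including the seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_species = 150L,
                       p_single = 0.647,
                       extra_mean = 1.85,
                       max_seqs = 20L,
                       seq_length = 750L,
                       core_length_range = c(166L, 199L),
                       fwd_primer = .SIM_FWD_PRIMER,
                       rev_primer = .SIM_REV_PRIMER,
                       freq = c(A = 0.32, C = 0.26, G = 0.19, T = 0.23),
                       alpha1 = 4, alpha2 = 4, beta = 1,
                       interspecific_depth = 0.05,
                       intraspecific_depth = 0.002,
                       hypervariable_rate_multiplier = 1.5,
                       primer_rate_multiplier = 0,
                       indel_rate = 0,
                       introgression_events = "auto",
                       identical_injections = "auto",
                       seed = 1L) {
  stopifnot(n_species >= 2L, abs(sum(freq) - 1) < 1e-9,
            interspecific_depth >= 0, intraspecific_depth >= 0,
            hypervariable_rate_multiplier >= 1, primer_rate_multiplier >= 0,
            indel_rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' TN93 rate matrix
#'
#' Builds the 4x4 instantaneous rate matrix with rows/columns A, C, G, T,
#' normalized (by default) so the expected substitution rate at equilibrium
#' is 1 per site per unit time, making branch lengths substitutions/site.
#'
#' @param freq equilibrium frequencies (A, C, G, T).
#' @param alpha1 purine transition rate factor (A<->G).
#' @param alpha2 pyrimidine transition rate factor (C<->T).
#' @param beta transversion rate factor.
#' @param normalize rescale to unit expected rate.
#' @return 4x4 numeric matrix.
#' @export
tn93_rate_matrix <- function(freq = c(A = 0.32, C = 0.26, G = 0.19, T = 0.23),
                             alpha1 = 4, alpha2 = 4, beta = 1,
                             normalize = TRUE) {
  stopifnot(length(freq) == 4L, all(freq > 0))
  nm <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(nm, nm))
  rate <- function(i, j) {
    ts1 <- (nm[i] == "A" && nm[j] == "G") || (nm[i] == "G" && nm[j] == "A")
    ts2 <- (nm[i] == "C" && nm[j] == "T") || (nm[i] == "T" && nm[j] == "C")
    f <- if (ts1) alpha1 else if (ts2) alpha2 else beta
    f * freq[[j]]
  }
  for (i in 1:4) for (j in 1:4) if (i != j) Q[i, j] <- rate(i, j)
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    mu <- -sum(freq * diag(Q))
    Q <- Q / mu
  }
  Q
}

#' Expected p-distance between two sequences at a given TN93 divergence
#'
#' For a pair separated by total branch length `t` under rate matrix `Q`
#' (stationary start), the probability a site differs is
#' \eqn{1 - \sum_i \pi_i P_{ii}(t)}.
#'
#' @param t total divergence (substitutions/site).
#' @param Q rate matrix from [tn93_rate_matrix()].
#' @param freq equilibrium frequencies.
#' @return expected proportion of differing sites.
#' @export
tn93_expected_p <- function(t, Q = tn93_rate_matrix(),
                            freq = c(A = 0.32, C = 0.26, G = 0.19, T = 0.23)) {
  P <- ape::matexpo(Q * t)
  1 - sum(freq * diag(P))
}

#' Simulate an ultrametric pure-birth species tree
#'
#' A Yule tree rescaled so the mean tip-pair path length is twice
#' `depth`; tips are named as generated binomials with genus blocks carved
#' from the tree's own clade structure so per-genus summaries are exercised.
#'
#' @param n_species number of tips.
#' @param depth target half mean tip-pair path (substitutions/site).
#' @param seed RNG seed.
#' @return `phylo` with binomial tip labels (`"GenusNN speciesNNN"`).
#' @export
simulate_species_tree <- function(n_species, depth = 0.05, seed = 1L) {
  stopifnot(n_species >= 2L)
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  coph <- ape::cophenetic.phylo(tr)
  mean_path <- mean(coph[upper.tri(coph)])
  tr$edge.length <- tr$edge.length * (2 * depth) / mean_path
  # genus blocks: average-linkage clusters at half the mean rescaled path
  coph <- coph * (2 * depth) / mean_path
  hc <- hclust(as.dist(coph), method = "average")
  gidx <- cutree(hc, h = depth)
  labs <- character(n_species)
  for (tip in seq_len(n_species)) {
    labs[tip] <- sprintf("Genus%02d species%03d", gidx[tip], tip)
  }
  tr$tip.label <- labs
  tr
}

# Sample a child state vector from parent states along branch length t,
# site-specific rate factors in `fac` (categories precomputed outside).
.evolve_branch <- function(parent, t, fac_levels, fac_index, Q) {
  child <- parent
  for (ci in seq_along(fac_levels)) {
    f <- fac_levels[ci]
    pos <- which(fac_index == ci)
    if (!length(pos) || f * t == 0) next
    P <- ape::matexpo(Q * (f * t))
    P[P < 0] <- 0  # numerical guard
    for (s in 1:4) {
      idx <- pos[parent[pos] == s]
      if (length(idx)) {
        child[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                 prob = P[s, ])
      }
    }
  }
  child
}

#' Evolve sequences along a species tree
#'
#' The root sequence is drawn from the equilibrium frequencies with the
#' forward primer site and the reverse-complemented reverse primer site
#' planted verbatim around the hypervariable core. Each branch substitutes
#' sites via the TN93 transition probabilities, with the core evolving
#' `hypervariable_rate_multiplier` times faster and primer sites at
#' `primer_rate_multiplier` times the base rate. Each individual then evolves
#' an extra branch of `intraspecific_depth` from its species tip, and
#' (optionally) receives indels restricted to the flanks.
#'
#' @param tree species tree from [simulate_species_tree()].
#' @param config a [sim_config()].
#' @return list with `records` (record data.frame, region `"longer12S"`),
#'   `truth` (list with `per_species` and `per_seq` data.frames), and
#'   `layout` (core/primer coordinates, 1-based inclusive).
#' @export
evolve_sequences <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  freq <- config$freq
  Q <- tn93_rate_matrix(freq, config$alpha1, config$alpha2, config$beta)
  nm <- c("A", "C", "G", "T")

  fwd <- seq_to_mask(normalize_seq(config$fwd_primer))
  rvc <- seq_to_mask(revcomp(config$rev_primer))
  core_len <- sample(config$core_length_range[1]:config$core_length_range[2], 1L)
  lp <- length(fwd); lr <- length(rvc)
  flank_total <- config$seq_length - lp - lr - core_len
  stopifnot(flank_total >= 2L)
  flankL <- floor(flank_total / 2); flankR <- flank_total - flankL
  L <- config$seq_length

  # site categories: 1 = flank, 2 = primer, 3 = core
  cat_idx <- integer(L)
  cat_idx[] <- 1L
  fwd_at <- (flankL + 1L):(flankL + lp)
  core_at <- (flankL + lp + 1L):(flankL + lp + core_len)
  rev_at <- (flankL + lp + core_len + 1L):(flankL + lp + core_len + lr)
  cat_idx[fwd_at] <- 2L
  cat_idx[core_at] <- 3L
  cat_idx[rev_at] <- 2L
  fac_levels <- c(1, config$primer_rate_multiplier,
                  config$hypervariable_rate_multiplier)

  mask_to_state <- c(`1` = 1L, `2` = 2L, `4` = 3L, `8` = 4L)
  root <- sample.int(4L, L, replace = TRUE, prob = freq)
  root[fwd_at] <- mask_to_state[as.character(fwd)]
  root[rev_at] <- mask_to_state[as.character(rvc)]

  # preorder traversal of the species tree
  tr <- stats::reorder(tree, "cladewise")
  nt <- length(tr$tip.label)
  states <- vector("list", nt + tr$Nnode)
  states[[nt + 1L]] <- root
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    states[[ch]] <- .evolve_branch(states[[par]], tr$edge.length[e],
                                   fac_levels, cat_idx, Q)
  }

  # sequences per species
  n_per <- ifelse(runif(nt) < config$p_single, 1L,
                  pmin(config$max_seqs, 2L + rpois(nt, config$extra_mean)))

  recs <- list(); per_seq <- list()
  acc_counter <- 0L
  for (tip in seq_len(nt)) {
    spname <- tr$tip.label[tip]
    for (k in seq_len(n_per[tip])) {
      acc_counter <- acc_counter + 1L
      ind <- if (config$intraspecific_depth > 0) {
        .evolve_branch(states[[tip]], config$intraspecific_depth,
                       fac_levels, cat_idx, Q)
      } else states[[tip]]
      seqchr <- paste(nm[ind], collapse = "")
      core_start <- core_at[1]; core_end <- core_at[length(core_at)]
      if (config$indel_rate > 0) {
        res <- .apply_flank_indels(seqchr, flankL, rev_at[length(rev_at)],
                                   config$indel_rate, freq)
        seqchr <- res$seq
        core_start <- core_start + res$shift
        core_end <- core_end + res$shift
      }
      acc <- sprintf("SYN%05d", acc_counter)
      recs[[acc_counter]] <- new_record(
        accession = acc, species = spname, source = "determined",
        region = "longer12S", seq = seqchr)
      per_seq[[acc_counter]] <- data.frame(
        accession = acc, species = spname,
        core_start = core_start, core_end = core_end,
        introgressed = FALSE, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  per_seq <- do.call(rbind, per_seq)

  tab <- table(records$species)
  per_species <- data.frame(
    species = names(tab),
    genus = vapply(strsplit(names(tab), " ", fixed = TRUE), `[`,
                   character(1), 1L),
    n_seqs = as.integer(tab),
    expected_category = ifelse(as.integer(tab) >= 2L, "Match", "NA_single"),
    expected_judgement = "success",
    stringsAsFactors = FALSE)
  rownames(per_species) <- NULL

  list(records = records,
       truth = list(per_species = per_species, per_seq = per_seq),
       layout = list(flankL = flankL, fwd = range(fwd_at),
                     core = range(core_at), rev = range(rev_at),
                     core_length = core_len))
}

# Poisson-count indels of length 1-3 confined to the flanks (before the
# forward primer / after the reverse primer site).
.apply_flank_indels <- function(seqchr, flankL, last_primer_pos, rate, freq) {
  nm <- c("A", "C", "G", "T")
  ch <- strsplit(seqchr, "")[[1]]
  n_flank <- flankL + (length(ch) - last_primer_pos)
  n_ev <- rpois(1L, rate * n_flank)
  shift <- 0L
  for (i in seq_len(n_ev)) {
    len <- sample.int(3L, 1L)
    left <- runif(1) < flankL / max(1, n_flank)
    if (left) {
      pos <- sample.int(max(1L, flankL - len), 1L)
    } else {
      pos <- last_primer_pos + shift +
        sample.int(max(1L, length(ch) - (last_primer_pos + shift) - len), 1L)
    }
    if (runif(1) < 0.5) {  # insertion
      ins <- nm[sample.int(4L, len, replace = TRUE, prob = freq)]
      ch <- append(ch, ins, after = pos)
      if (left) shift <- shift + len
    } else {               # deletion
      ch <- ch[-(pos:(pos + len - 1L))]
      if (left) shift <- shift - len
    }
  }
  list(seq = paste(ch, collapse = ""), shift = shift)
}

#' Inject introgression and shared-haplotype events
#'
#' Introgression: the chosen recipient individuals' sequences are replaced by
#' copies of one donor haplotype (a recent mitochondrial sweep, so the
#' introgressed sequences are identical to the donor's). Identical
#' injections copy one haplotype verbatim across a species pair. Ground truth
#' is updated: a partial-introgression recipient is expected `Mixture`, a
#' full-replacement recipient `Merge`; donors and injection partners are
#' expected failures whose tree-side category can be either `Merge` or
#' `Mixture` (recorded as `"Merge|Mixture"`).
#'
#' @param sim result of [evolve_sequences()].
#' @param introgression_events list of `list(donor=, recipient=,
#'   n_recipients=)`.
#' @param identical_injections list of `c(speciesA, speciesB)` pairs.
#' @return the modified `sim` object.
#' @export
inject_events <- function(sim, introgression_events = NULL,
                          identical_injections = NULL) {
  records <- sim$records
  ps <- sim$truth$per_species
  pq <- sim$truth$per_seq

  get_idx <- function(spname) {
    idx <- which(records$species == spname)
    if (!length(idx)) stop("event references unknown species: ", spname)
    idx
  }
  mark <- function(sp, category, judgement = "failure") {
    i <- ps$species == sp
    n <- ps$n_seqs[i]
    ps$expected_category[i] <<- if (n == 1L) "NA_single" else category
    ps$expected_judgement[i] <<- judgement
  }

  for (ev in introgression_events) {
    don <- get_idx(ev$donor); rec <- get_idx(ev$recipient)
    n_rec <- min(ev$n_recipients, length(rec))
    hap <- records$seq[don[1]]
    targets <- rec[seq_len(n_rec)]
    records$seq[targets] <- hap
    pq$introgressed[targets] <- TRUE
    full <- n_rec == length(rec)
    mark(ev$recipient, if (full) "Merge" else "Mixture")
    mark(ev$donor, "Merge|Mixture")
  }
  for (pair in identical_injections) {
    a <- get_idx(pair[1]); b <- get_idx(pair[2])
    records$seq[b[1]] <- records$seq[a[1]]
    pq$introgressed[b[1]] <- TRUE
    for (sp in pair) mark(sp, "Merge|Mixture")
  }
  sim$records <- records
  sim$truth$per_species <- ps
  sim$truth$per_seq <- pq
  sim
}

# Default event choices: deterministic functions of the species table.
.auto_events <- function(truth) {
  ps <- truth$per_species
  multi <- ps[ps$n_seqs >= 2L, ]
  singles <- ps[ps$n_seqs == 1L, ]
  intro <- list()
  gtab <- table(multi$genus)
  cand_gen <- names(gtab)[gtab >= 2L]
  for (g in cand_gen[seq_len(min(2L, length(cand_gen)))]) {
    spg <- sort(multi$species[multi$genus == g])
    intro[[length(intro) + 1L]] <-
      list(donor = spg[1], recipient = spg[2], n_recipients = 1L)
  }
  inj <- list()
  stab <- table(singles$genus)
  sg <- names(stab)[stab >= 2L]
  if (length(sg)) {
    spg <- sort(singles$species[singles$genus == sg[1]])
    inj[[1]] <- c(spg[1], spg[2])
  }
  list(introgression = intro, injections = inj)
}

#' Generate a complete synthetic reference library
#'
#' One call: species tree, sequence evolution, and event injection, all
#' driven by the seed in the config. With `"auto"` events the generator
#' plants two partial congeneric introgressions and one identical-haplotype
#' injection between congeneric singletons (skipping whatever the realized
#' species table cannot support).
#'
#' @param config a [sim_config()].
#' @return list with `records`, `truth`, `tree` (species tree), `layout`,
#'   and `config`.
#' @export
sim_barcode_library <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_species_tree(config$n_species, config$interspecific_depth,
                                seed = config$seed)
  set.seed(config$seed + 1L)
  sim <- evolve_sequences(tree, config)

  intro <- config$introgression_events
  inj <- config$identical_injections
  if (identical(intro, "auto") || identical(inj, "auto")) {
    auto <- .auto_events(sim$truth)
    if (identical(intro, "auto")) intro <- auto$introgression
    if (identical(inj, "auto")) inj <- auto$injections
  }
  sim <- inject_events(sim, intro, inj)
  sim$tree <- tree
  sim$config <- config
  sim
}
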