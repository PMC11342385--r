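# Pairwise global alignment, site-pattern counting, p / TN93 distances,
# distance matrices, the intra/interspecific summaries, and a progressive MSA
# used where a shared column structure is needed (bootstrap resampling).

#' Alignment scoring parameters
#'
#' Scores for the affine-gap global aligner. A gap run of length L costs
#' `gap_open + L * gap_ext`. Defaults suit closely related rRNA fragments
#' with rare short indels; the heavy gap opening keeps runs of substitutions
#' from being spuriously absorbed into compensating gaps (with these values,
#' gapping around a divergent block only pays off beyond 24 consecutive
#' mismatches).
#'
#' @param match match score (> -mismatch).
#' @param mismatch mismatch score (typically negative).
#' @param gap_open gap opening penalty (>= 0, applied once per gap run).
#' @param gap_ext gap extension penalty (>= 0, applied per gapped position).
#' @return object of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -1, gap_open = 12, gap_ext = 1) {
  stopifnot(gap_open >= 0, gap_ext >= 0, match > -mismatch)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_ext = gap_ext),
            class = "align_params")
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch-Gotoh alignment. Two symbols score as a match when their
#' IUPAC sets intersect. Traceback ties prefer the diagonal move, then the gap
#' consuming `a`, then the gap consuming `b`, so results are deterministic.
#'
#' @param a,b nucleotide strings (non-empty).
#' @param params an [align_params()].
#' @return list with gapped strings `a` and `b` (equal length; removing gaps
#'   recovers the inputs) and the optimal `score`.
#' @export
#' @examples
#' nw_align("ACGT", "ACGGT")
nw_align <- function(a, b, params = align_params()) {
  stopifnot(nzchar(a), nzchar(b))
  am <- seq_to_mask(normalize_seq(a))
  bm <- seq_to_mask(normalize_seq(b))
  r <- .nw_pair_cpp(am, bm, params$match, params$mismatch,
                    params$gap_open, params$gap_ext)
  list(a = mask_to_seq(r$a), b = mask_to_seq(r$b), score = r$score,
       a_mask = r$a, b_mask = r$b)
}

#' Count site patterns between two aligned sequences
#'
#' Pairwise deletion: any column where either symbol is a gap or an ambiguity
#' code (non-ACGT) is excluded from the compared sites L. The proportions of
#' purine transitions (P1, A<->G), pyrimidine transitions (P2, C<->T) and
#' transversions (Q) are taken over L, and base frequencies are pooled over
#' the included sites of both sequences.
#'
#' @param a,b equal-length gapped strings, or integer mask vectors as
#'   returned in `a_mask`/`b_mask` of [nw_align()].
#' @return list with `L`, `P1`, `P2`, `Q`, `n_subst` (raw integer mismatch
#'   count, the authoritative substitution count), and `freq` (named
#'   A/C/G/T vector summing to 1).
#' @export
count_site_patterns <- function(a, b) {
  am <- if (is.character(a)) seq_to_mask(a) else as.integer(a)
  bm <- if (is.character(b)) seq_to_mask(b) else as.integer(b)
  if (length(am) != length(bm)) stop("aligned sequences differ in length")
  keep <- is_acgt_mask(am) & is_acgt_mask(bm)
  L <- sum(keep)
  if (L == 0L) stop("no comparable sites (L == 0)")
  x <- am[keep]; y <- bm[keep]
  diff <- x != y
  purine <- function(m) m == 1L | m == 4L   # A or G
  ts1 <- diff & purine(x) & purine(y)
  ts2 <- diff & !purine(x) & !purine(y)
  tv <- diff & (purine(x) != purine(y))
  counts <- tabulate(match(c(x, y), c(1L, 2L, 4L, 8L)), nbins = 4L)
  freq <- setNames(counts / (2 * L), c("A", "C", "G", "T"))
  list(L = L,
       P1 = sum(ts1) / L, P2 = sum(ts2) / L, Q = sum(tv) / L,
       n_subst = sum(diff),
       freq = freq)
}

#' Uncorrected p-distance from site patterns
#'
#' The proportion of differing sites among compared sites: `P1 + P2 + Q`.
#'
#' @param sc site comparison from [count_site_patterns()].
#' @return numeric in \[0, 1\].
#' @export
p_distance <- function(sc) {
  sc$P1 + sc$P2 + sc$Q
}

#' Tamura-Nei (TN93) distance from site patterns
#'
#' Model-corrected distance distinguishing the two transition classes and
#' transversions under unequal base frequencies:
#' \deqn{d = -\frac{2 g_A g_G}{g_R}\ln\!\Big(1-\frac{g_R P_1}{2 g_A g_G}-\frac{Q}{2 g_R}\Big)
#'      -\frac{2 g_T g_C}{g_Y}\ln\!\Big(1-\frac{g_Y P_2}{2 g_T g_C}-\frac{Q}{2 g_Y}\Big)
#'      -2\Big(g_R g_Y-\frac{g_A g_G g_Y}{g_R}-\frac{g_T g_C g_R}{g_Y}\Big)\ln\!\Big(1-\frac{Q}{2 g_R g_Y}\Big)}
#' where the frequencies are estimated from the compared sites. When any log
#' argument is non-positive the distance is undefined (saturation) and `NA`
#' is returned; downstream consumers must reject or fall back to p-distance.
#'
#' @param sc site comparison from [count_site_patterns()].
#' @return non-negative numeric, or `NA_real_` when undefined.
#' @export
tn93_distance <- function(sc) {
  g <- sc$freq
  if (any(g <= 0)) stop("all four base frequencies must be > 0 for TN93")
  gA <- g[["A"]]; gC <- g[["C"]]; gG <- g[["G"]]; gT <- g[["T"]]
  gR <- gA + gG; gY <- gC + gT
  a1 <- 1 - gR * sc$P1 / (2 * gA * gG) - sc$Q / (2 * gR)
  a2 <- 1 - gY * sc$P2 / (2 * gT * gC) - sc$Q / (2 * gY)
  a3 <- 1 - sc$Q / (2 * gR * gY)
  if (a1 <= 0 || a2 <= 0 || a3 <= 0) return(NA_real_)
  d <- -(2 * gA * gG / gR) * log(a1) -
    (2 * gT * gC / gY) * log(a2) -
    2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY) * log(a3)
  unname(d)
}

#' Pairwise distance matrices for a record set
#'
#' Every pair is globally aligned ([nw_align()]), site patterns are counted
#' under pairwise deletion, and both the uncorrected p-distance and the TN93
#' distance are derived in one pass (the conventional workflow uses TN93 for
#' tree building and p for thresholding). Identical sequences short-circuit to
#' distance zero. Undefined TN93 entries are stored as `NA` and must be
#' handled downstream.
#'
#' @param records record data.frame (>= 2 rows).
#' @param params an [align_params()].
#' @return object of class `barcode_dist`: list with `labels` (accessions),
#'   symmetric matrices `p`, `tn93`, integer matrices `subst` (raw mismatch
#'   counts) and `sites` (compared sites), plus `species` and `genus` label
#'   vectors aligned with `labels`.
#' @export
distance_matrix <- function(records, params = align_params()) {
  validate_records(records)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records")
  labs <- records$accession
  masks <- lapply(records$seq, seq_to_mask)
  p <- matrix(0, n, n, dimnames = list(labs, labs))
  tn <- matrix(0, n, n, dimnames = list(labs, labs))
  subst <- matrix(0L, n, n, dimnames = list(labs, labs))
  sites <- matrix(0L, n, n, dimnames = list(labs, labs))
  diag(sites) <- vapply(masks, length, integer(1))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (identical(records$seq[i], records$seq[j])) {
        L <- length(masks[[i]])
        sc <- NULL
        pij <- 0; tij <- 0; sij <- 0L; Lij <- L
      } else {
        r <- .nw_pair_cpp(masks[[i]], masks[[j]], params$match,
                          params$mismatch, params$gap_open, params$gap_ext)
        sc <- tryCatch(count_site_patterns(r$a, r$b), error = function(e)
          stop("pair ", labs[i], " / ", labs[j], ": ", conditionMessage(e)))
        pij <- p_distance(sc)
        tij <- tn93_distance(sc)
        sij <- sc$n_subst
        Lij <- sc$L
      }
      p[i, j] <- p[j, i] <- pij
      tn[i, j] <- tn[j, i] <- tij
      subst[i, j] <- subst[j, i] <- sij
      sites[i, j] <- sites[j, i] <- Lij
    }
  }
  structure(list(labels = labs, p = p, tn93 = tn, subst = subst,
                 sites = sites, species = records$species,
                 genus = records$genus),
            class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat(sprintf("barcode_dist: %d sequences, %d species\n",
              length(x$labels), length(unique(x$species))))
  cat(sprintf("  p-distance range %.4f-%.4f; TN93 undefined for %d pair(s)\n",
              min(x$p[upper.tri(x$p)]), max(x$p[upper.tri(x$p)]),
              sum(is.na(x$tn93[upper.tri(x$tn93)]))))
  invisible(x)
}

# Pick the metric matrix out of a barcode_dist.
dist_metric <- function(dm, metric = c("p", "tn93")) {
  metric <- match.arg(metric)
  dm[[metric]]
}

#' Per-species intraspecific distance summary
#'
#' For each species, the number of sequences and the maximum/mean pairwise
#' distance and maximum substitution count among its conspecific pairs
#' (`NA` for single-specimen species). Also returns the overall mean
#' substitution count and mean distance over all conspecific pairs.
#'
#' @param dm a [distance_matrix()].
#' @param metric `"p"` (default) or `"tn93"`.
#' @return list with `per_species` data.frame and scalars
#'   `mean_subst_overall`, `mean_dist_overall`.
#' @export
intraspecific_summary <- function(dm, metric = "p") {
  d <- dist_metric(dm, metric)
  sp <- dm$species
  species <- sort(unique(sp))
  rows <- lapply(species, function(s) {
    idx <- which(sp == s)
    if (length(idx) < 2L) {
      data.frame(species = s, n_seqs = length(idx), max_dist = NA_real_,
                 mean_dist = NA_real_, max_subst = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      sub <- d[idx, idx]; ss <- dm$subst[idx, idx]
      ut <- upper.tri(sub)
      data.frame(species = s, n_seqs = length(idx),
                 max_dist = max(sub[ut]), mean_dist = mean(sub[ut]),
                 max_subst = max(ss[ut]), stringsAsFactors = FALSE)
    }
  })
  per <- do.call(rbind, rows)
  multi <- per$n_seqs > 1L
  all_d <- c(); all_s <- c()
  for (s in species[multi]) {
    idx <- which(sp == s)
    ut <- upper.tri(d[idx, idx])
    all_d <- c(all_d, d[idx, idx][ut])
    all_s <- c(all_s, dm$subst[idx, idx][ut])
  }
  list(per_species = per,
       mean_subst_overall = if (length(all_s)) mean(all_s) else NA_real_,
       mean_dist_overall = if (length(all_d)) mean(all_d) else NA_real_)
}

#' Per-genus interspecific (congeneric) distance summary
#'
#' Summarizes distances between different species of the same genus; a genus
#' appears only if it holds >= 2 species.
#'
#' @param dm a [distance_matrix()].
#' @param metric `"p"` (default) or `"tn93"`.
#' @return data.frame with one row per qualifying genus: `genus`, `n_species`,
#'   `mean_dist`, `min_dist`, `max_dist`, `mean_subst`, `min_subst`,
#'   `max_subst`.
#' @export
interspecific_summary <- function(dm, metric = "p") {
  d <- dist_metric(dm, metric)
  rows <- list()
  for (g in sort(unique(dm$genus))) {
    idx <- which(dm$genus == g)
    spg <- dm$species[idx]
    if (length(unique(spg)) < 2L) next
    pairs <- which(outer(spg, spg, "!=") & upper.tri(d[idx, idx]),
                   arr.ind = TRUE)
    dd <- d[idx, idx][pairs]
    ss <- dm$subst[idx, idx][pairs]
    rows[[g]] <- data.frame(
      genus = g, n_species = length(unique(spg)),
      mean_dist = mean(dd), min_dist = min(dd), max_dist = max(dd),
      mean_subst = mean(ss), min_subst = min(ss), max_subst = max(ss),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nearest heterospecific distance for a species
#'
#' Minimum distance between any sequence of the focal species and any sequence
#' of a different species; ties report all tied species.
#'
#' @param dm a [distance_matrix()].
#' @param species focal species name.
#' @param metric `"p"` (default) or `"tn93"`.
#' @return list with `distance`, `other_species` (character vector, all tied),
#'   `other_accession` (witness accessions), `focal_accession`.
#' @export
nearest_heterospecific <- function(dm, species, metric = "p") {
  d <- dist_metric(dm, metric)
  foc <- which(dm$species == species)
  het <- which(dm$species != species)
  if (!length(foc)) stop("species not present: ", species)
  if (!length(het)) stop("no heterospecific sequences present")
  sub <- d[foc, het, drop = FALSE]
  if (anyNA(sub)) stop("undefined distances involving species ", species)
  mn <- min(sub)
  w <- which(sub <= mn + 1e-15, arr.ind = TRUE)
  list(distance = mn,
       other_species = unique(dm$species[het[w[, 2]]]),
       other_accession = unique(dm$labels[het[w[, 2]]]),
       focal_accession = unique(dm$labels[foc[w[, 1]]]))
}

# ---------------------------------------------------------------------------
# Progressive multiple alignment (guide tree from p-distance NJ;
# profile-profile merging). Used only where a column structure is required.

mask_profile <- function(rows) {
  # rows: list of integer mask vectors (equal length). 4 x L base fractions;
  # ambiguity mass split evenly over its bases, gaps contribute nothing.
  L <- length(rows[[1]])
  f <- matrix(0, 4L, L)
  bits <- c(1L, 2L, 4L, 8L)
  for (r in rows) {
    nb <- (bitwAnd(r, 1L) > 0) + (bitwAnd(r, 2L) > 0) +
      (bitwAnd(r, 4L) > 0) + (bitwAnd(r, 8L) > 0)
    for (k in 1:4) {
      has <- bitwAnd(r, bits[k]) > 0
      f[k, has] <- f[k, has] + 1 / nb[has]
    }
  }
  f / length(rows)
}

apply_merge_path <- function(rows, path, side) {
  # insert gap (0) into each row where the path consumes only the other side
  take <- if (side == "a") path != 2L else path != 1L
  lapply(rows, function(r) {
    out <- integer(length(path))
    out[take] <- r
    out
  })
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree by neighbour-joining on pairwise p-distances, then
#' merges sequences bottom-up by profile-profile global alignment with the
#' same affine gap model as [nw_align()]. Deterministic given the input order;
#' no randomness involved.
#'
#' @param records record data.frame (>= 2 rows).
#' @param params an [align_params()].
#' @return object of class `barcode_msa`: list with `labels` and `rows`
#'   (named character vector of equal-length gapped sequences).
#' @export
progressive_msa <- function(records, params = align_params()) {
  validate_records(records)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records")
  labs <- records$accession
  masks <- lapply(records$seq, seq_to_mask)
  names(masks) <- labs

  merge_pair <- function(ga, gb) {
    # ga/gb: list(rows = list of mask vectors, idx = record indices)
    fa <- mask_profile(ga$rows); fb <- mask_profile(gb$rows)
    path <- .nw_profile_cpp(fa, fb, params$match, params$mismatch,
                            params$gap_open, params$gap_ext)
    list(rows = c(apply_merge_path(ga$rows, path, "a"),
                  apply_merge_path(gb$rows, path, "b")),
         idx = c(ga$idx, gb$idx))
  }

  if (n == 2L) {
    final <- merge_pair(list(rows = masks[1], idx = 1L),
                        list(rows = masks[2], idx = 2L))
  } else {
    dm <- distance_matrix(records, params)
    tr <- ape::nj(as.dist(dm$p))
    tr <- stats::reorder(tr, "postorder")
    nt <- length(tr$tip.label)
    groups <- vector("list", nt + tr$Nnode)
    for (i in seq_len(nt)) {
      ri <- match(tr$tip.label[i], labs)
      groups[[i]] <- list(rows = masks[ri], idx = ri)
    }
    # postorder edge traversal: a child's subtree is complete before its edge
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      groups[[par]] <- if (is.null(groups[[par]])) groups[[ch]] else
        merge_pair(groups[[par]], groups[[ch]])
    }
    final <- groups[[nt + 1L]]  # root of the (unrooted) NJ tree
  }
  ord <- order(final$idx)
  rows <- vapply(final$rows[ord], mask_to_seq, character(1))
  names(rows) <- labs[final$idx[ord]]
  rows <- rows[labs]
  structure(list(labels = labs, rows = rows,
                 species = records$species, genus = records$genus),
            class = "barcode_msa")
}

#' Distance matrices from a fixed multiple alignment
#'
#' Computes the same pairwise quantities as [distance_matrix()] but from the
#' columns of an existing alignment (pairwise deletion per pair), without
#' re-aligning. Used by the bootstrap.
#'
#' @param rows named character vector of equal-length gapped sequences (or a
#'   `barcode_msa`).
#' @param species,genus optional label vectors (taken from the `barcode_msa`
#'   if present).
#' @return a `barcode_dist`.
#' @export
msa_distance_matrix <- function(rows, species = NULL, genus = NULL) {
  if (inherits(rows, "barcode_msa")) {
    species <- rows$species; genus <- rows$genus; rows <- rows$rows
  }
  n <- length(rows)
  stopifnot(n >= 2L)
  labs <- names(rows)
  masks <- lapply(rows, seq_to_mask)
  p <- matrix(0, n, n, dimnames = list(labs, labs))
  tn <- matrix(0, n, n, dimnames = list(labs, labs))
  subst <- matrix(0L, n, n, dimnames = list(labs, labs))
  sites <- matrix(0L, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sc <- count_site_patterns(masks[[i]], masks[[j]])
      p[i, j] <- p[j, i] <- p_distance(sc)
      tn[i, j] <- tn[j, i] <- tn93_distance(sc)
      subst[i, j] <- subst[j, i] <- sc$n_subst
      sites[i, j] <- sites[j, i] <- sc$L
    }
  }
  structure(list(labels = labs, p = p, tn93 = tn, subst = subst,
                 sites = sites,
                 species = if (is.null(species)) rep(NA_character_, n) else species,
                 genus = if (is.null(genus)) rep(NA_character_, n) else genus),
            class = "barcode_dist")
}
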