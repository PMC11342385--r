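# Neighbour-joining trees, nonparametric bootstrap supports, newick I/O.
# Trees are ape "phylo" objects; bootstrap supports (0-100 integers) live in
# node.label of the reference tree.

#' Build a neighbour-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration on the chosen metric. Negative branch
#' lengths (an artifact of the least-squares branch estimates) are clamped to
#' zero with the deficit added to the sibling branch so path lengths are
#' approximately preserved; the number of clamped edges is recorded in the
#' `"clamped"` attribute.
#'
#' @param dm a [distance_matrix()] result, or a plain symmetric numeric
#'   matrix with dimnames.
#' @param metric `"tn93"` (default, the usual tree-building metric) or `"p"`;
#'   ignored when `dm` is a plain matrix.
#' @return unrooted `phylo` object.
#' @export
nj_tree <- function(dm, metric = "tn93") {
  m <- if (inherits(dm, "barcode_dist")) dist_metric(dm, metric) else dm
  if (nrow(m) < 3L) stop("need at least 3 taxa")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("non-finite distance for pair ", rownames(m)[bad[1]], " / ",
         colnames(m)[bad[2]], "; reject or fall back to p-distance")
  }
  tr <- ape::nj(as.dist(m))
  clamp_negative_branches(tr)
}

# Clamp negative edge lengths to 0, adding each deficit to the sibling edge.
clamp_negative_branches <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    par <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == par)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      s <- sibs[1]
      tr$edge.length[s] <- tr$edge.length[s] + deficit
    }
  }
  attr(tr, "clamped") <- length(neg)
  tr
}

# Bipartitions of an unrooted tree as canonical strings. Each internal edge
# splits the leaves in two; the side not containing the alphabetically first
# leaf is the canonical representation. Trivial (leaf) edges excluded.
tree_bipartitions <- function(tr) {
  tips <- tr$tip.label
  anchor <- sort(tips)[1]
  nt <- length(tips)
  desc <- descendant_tips(tr)
  out <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= nt) next
    side <- tips[desc[[ch]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) <= 1L || length(side) >= nt - 1L) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# list: node id -> integer vector of descendant tip indices
descendant_tips <- function(tr) {
  nt <- length(tr$tip.label)
  nn <- nt + tr$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(nt)) desc[[i]] <- i
  tr <- stats::reorder(tr, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  desc
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, recomputes distances and the
#' NJ tree per pseudoreplicate, and annotates each internal edge of the
#' reference tree (NJ on the unresampled alignment) with the percentage of
#' replicates containing the same bipartition. Replicates yielding an
#' undefined distance are dropped and counted; more than 10% dropped is an
#' error.
#'
#' @param msa a [progressive_msa()] result (or named character vector of
#'   equal-length gapped sequences, >= 4 rows).
#' @param n_replicates number of pseudoreplicates.
#' @param seed RNG seed (resampling is fully determined by it).
#' @param metric `"tn93"` (default) or `"p"`.
#' @return list with `tree` (reference `phylo`, supports in `node.label`),
#'   `supports` (named integer vector keyed by canonical bipartition),
#'   `n_dropped`.
#' @export
bootstrap_support <- function(msa, n_replicates = 1000L, seed = 1L,
                              metric = "tn93") {
  rows <- if (inherits(msa, "barcode_msa")) msa$rows else msa
  if (length(rows) < 4L) stop("need >= 4 aligned sequences")
  stopifnot(n_replicates >= 1L)
  masks <- lapply(rows, seq_to_mask)
  L <- length(masks[[1]])
  mat <- do.call(rbind, masks)  # n x L integer matrix
  rownames(mat) <- names(rows)

  dist_from_cols <- function(cols) {
    sub <- mat[, cols, drop = FALSE]
    n <- nrow(sub)
    d <- matrix(0, n, n, dimnames = list(rownames(sub), rownames(sub)))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        sc <- tryCatch(count_site_patterns(sub[i, ], sub[j, ]),
                       error = function(e) NULL)
        if (is.null(sc)) return(NULL)
        v <- if (metric == "p") p_distance(sc) else tn93_distance(sc)
        if (is.na(v)) return(NULL)
        d[i, j] <- d[j, i] <- v
      }
    }
    d
  }

  ref_d <- dist_from_cols(seq_len(L))
  if (is.null(ref_d)) stop("undefined distance on the unresampled alignment")
  ref <- clamp_negative_branches(ape::nj(as.dist(ref_d)))
  ref_bip <- tree_bipartitions(ref)
  hits <- setNames(integer(length(ref_bip)), ref_bip)

  set.seed(seed)
  dropped <- 0L
  kept <- 0L
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    d <- dist_from_cols(cols)
    if (is.null(d)) { dropped <- dropped + 1L; next }
    kept <- kept + 1L
    bip <- tree_bipartitions(clamp_negative_branches(ape::nj(as.dist(d))))
    inb <- ref_bip %in% bip
    hits[inb] <- hits[inb] + 1L
  }
  if (dropped > 0.10 * n_replicates) {
    stop(dropped, " of ", n_replicates,
         " replicates dropped (undefined distances)")
  }
  supports <- round(100 * hits / kept)

  # annotate internal nodes of the reference tree
  nt <- length(ref$tip.label)
  desc <- descendant_tips(ref)
  anchor <- sort(ref$tip.label)[1]
  node_lab <- character(ref$Nnode)
  for (e in seq_len(nrow(ref$edge))) {
    ch <- ref$edge[e, 2]
    if (ch <= nt) next
    side <- ref$tip.label[desc[[ch]]]
    if (anchor %in% side) side <- setdiff(ref$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(supports)) {
      node_lab[ch - nt] <- as.character(supports[[key]])
    }
  }
  ref$node.label <- node_lab
  list(tree = ref, supports = supports, n_dropped = dropped)
}

#' Write / read trees in newick format
#'
#' Thin wrappers keeping branch lengths (6 decimals) and bootstrap supports
#' (as internal node labels) through a round trip.
#'
#' @param tree a `phylo` object.
#' @param path file path; for [write_newick()] omit to get the string.
#' @return [write_newick()]: the newick string, invisibly if written to file.
#'   [read_newick()]: a `phylo` object.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 6)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @param text newick string (used when `path` is `NULL`).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- suppressWarnings(
    if (is.null(path)) ape::read.tree(text = text) else ape::read.tree(path))
  if (is.null(tr)) stop("malformed newick input")
  tr
}
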