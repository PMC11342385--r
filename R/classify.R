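# Species-level evaluation of a barcode reference library: Match / Split /
# Merge / Mixture categories from the NJ tree and distance matrix, the
# single-specimen rule, the caution threshold on nearest-heterospecific
# distance, and the curation screen for anomalous sequences.
#
# "OTU" is operationalized deterministically: two leaves belong to the same
# OTU iff (a) their distance is <= identity_epsilon, or (b) they form a clade
# of the reference NJ tree with no heterospecific leaf inside. This
# reproduces, without visual inspection, the published category definitions.

#' Classifier configuration
#'
#' @param caution_threshold distance (substitutions/site) at or below which a
#'   discriminable species is flagged for caution; success strictly requires
#'   nearest-heterospecific distance above it. Default 0.01.
#' @param identity_epsilon distance at or below which two sequences count as
#'   identical (default 0: exact sharing only).
#' @param metric metric used for thresholding and identity, `"p"` (default)
#'   or `"tn93"`.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(caution_threshold = 0.01, identity_epsilon = 0,
                              metric = "p") {
  stopifnot(identity_epsilon >= 0, identity_epsilon < caution_threshold)
  structure(list(caution_threshold = caution_threshold,
                 identity_epsilon = identity_epsilon,
                 metric = match.arg(metric, c("p", "tn93"))),
            class = "classifier_config")
}

#' Pure clusters of a species on the reference tree
#'
#' Partitions the focal species' leaves into maximal clades containing only
#' conspecific leaves. The computation is unrooted-safe: the tree is rooted at
#' a heterospecific leaf, under which every pure bipartition side becomes a
#' rooted clade. When a distance matrix is supplied, leaves within
#' `epsilon` of each other are additionally merged into one cluster
#' (identical haplotypes belong to one OTU wherever the tree puts them).
#'
#' @param tree `phylo` object whose tip labels are accessions.
#' @param species_labels named character vector accession -> species.
#' @param species focal species (>= 2 sequences in the tree).
#' @param dm optional [distance_matrix()] for the epsilon rule.
#' @param epsilon identity distance, see [classifier_config()].
#' @param metric metric for the epsilon rule.
#' @return list with `k` (number of pure clusters) and `clusters` (list of
#'   accession vectors).
#' @export
pure_clusters <- function(tree, species_labels, species, dm = NULL,
                          epsilon = 0, metric = "p") {
  tips <- tree$tip.label
  sp <- species_labels[tips]
  if (anyNA(sp)) stop("species label missing for some tree tips")
  focal <- tips[sp == species]
  if (!length(focal)) stop("species absent from tree: ", species)
  if (length(focal) == 1L) {
    return(list(k = 1L, clusters = list(focal)))
  }
  het <- tips[sp != species]
  if (!length(het)) {
    return(list(k = 1L, clusters = list(focal)))
  }
  root_tip <- sort(het)[1]
  rt <- ape::root(tree, outgroup = root_tip, resolve.root = TRUE)
  nt <- length(rt$tip.label)
  desc <- descendant_tips(rt)
  is_focal_tip <- rt$tip.label %in% focal

  pure <- vapply(seq_along(desc), function(nd)
    length(desc[[nd]]) > 0L && all(is_focal_tip[desc[[nd]]]), logical(1))
  # parent lookup
  parent <- integer(nt + rt$Nnode)
  parent[rt$edge[, 2]] <- rt$edge[, 1]
  root_node <- nt + 1L
  maximal <- which(pure & vapply(seq_along(pure), function(nd) {
    nd == root_node || parent[nd] == 0L || !pure[parent[nd]]
  }, logical(1)))
  clusters <- lapply(maximal, function(nd) rt$tip.label[desc[[nd]]])

  # epsilon rule: merge clusters holding (near-)identical focal haplotypes
  if (!is.null(dm) && length(clusters) > 1L) {
    d <- dist_metric(dm, metric)
    comp <- seq_along(clusters)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        sub <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        if (any(sub <= epsilon)) {
          old <- comp[j]; comp[comp == old] <- comp[i]
        }
      }
    }
    merged <- lapply(unique(comp), function(cc)
      sort(unlist(clusters[comp == cc])))
    clusters <- merged
  }
  list(k = length(clusters), clusters = clusters)
}

#' Does a species share (near-)identical sequences with another species?
#'
#' @param dm a [distance_matrix()].
#' @param species focal species.
#' @param epsilon identity distance (default 0).
#' @param metric `"p"` (default) or `"tn93"`.
#' @return list with `shared` (logical) and `witnesses` (data.frame of
#'   focal/other accession pairs and the other species).
#' @export
shares_identity <- function(dm, species, epsilon = 0, metric = "p") {
  d <- dist_metric(dm, metric)
  foc <- which(dm$species == species)
  het <- which(dm$species != species)
  if (!length(foc) || !length(het)) {
    return(list(shared = FALSE,
                witnesses = data.frame(focal = character(0),
                                       other = character(0),
                                       other_species = character(0))))
  }
  sub <- d[foc, het, drop = FALSE]
  w <- which(sub <= epsilon, arr.ind = TRUE)
  list(shared = nrow(w) > 0L,
       witnesses = data.frame(
         focal = dm$labels[foc[w[, 1]]],
         other = dm$labels[het[w[, 2]]],
         other_species = dm$species[het[w[, 2]]],
         stringsAsFactors = FALSE))
}

#' Classify every species of a reference library
#'
#' For species with >= 2 sequences, the category follows from the number of
#' pure clusters k and identity sharing: Match (k = 1, no sharing), Split
#' (k >= 2, no sharing), Merge (k = 1, sharing), Mixture (k >= 2, sharing).
#' Single-specimen species cannot be judged by clustering; they fail only when
#' their sequence is shared by another species (the single-specimen Merge
#' rule) and are otherwise judged by nearest-heterospecific distance.
#' Judgement: `failure` iff the category is Split/Merge/Mixture or a
#' single-specimen merge; otherwise `caution` iff the nearest-heterospecific
#' distance is positive but does not exceed the threshold (a distance exactly
#' at the threshold is a caution); otherwise `success`.
#'
#' @param tree reference NJ `phylo` over the same accessions as `dm`.
#' @param dm a [distance_matrix()].
#' @param config a [classifier_config()].
#' @return data.frame of class `species_assessment`, one row per species:
#'   `species`, `genus`, `n_seqs`, `category` (Match/Split/Merge/Mixture or
#'   NA_single), `k`, `single_specimen_merge`, `max_intra`, `nn_hetero`,
#'   `nn_species` (comma-joined), `judgement`.
#' @export
classify_species <- function(tree, dm, config = classifier_config()) {
  stopifnot(setequal(tree$tip.label, dm$labels))
  sp_labels <- setNames(dm$species, dm$labels)
  metric <- config$metric
  d <- dist_metric(dm, metric)
  species <- sort(unique(dm$species))
  intra <- intraspecific_summary(dm, metric)$per_species
  rows <- lapply(species, function(s) {
    idx <- which(dm$species == s)
    n <- length(idx)
    sh <- shares_identity(dm, s, config$identity_epsilon, metric)
    nn <- nearest_heterospecific(dm, s, metric)
    if (n >= 2L) {
      pc <- pure_clusters(tree, sp_labels, s, dm = dm,
                          epsilon = config$identity_epsilon, metric = metric)
      k <- pc$k
      category <- if (k == 1L && !sh$shared) "Match"
      else if (k >= 2L && !sh$shared) "Split"
      else if (k == 1L) "Merge" else "Mixture"
      ssm <- FALSE
    } else {
      k <- NA_integer_
      category <- "NA_single"
      ssm <- sh$shared
    }
    failure <- category %in% c("Split", "Merge", "Mixture") || ssm
    judgement <- if (failure) "failure"
    else if (nn$distance > 0 && nn$distance <= config$caution_threshold) "caution"
    else "success"
    data.frame(
      species = s, genus = strsplit(s, " ", fixed = TRUE)[[1]][1],
      n_seqs = n, category = category, k = k,
      single_specimen_merge = ssm,
      max_intra = intra$max_dist[intra$species == s],
      nn_hetero = nn$distance,
      nn_species = paste(nn$other_species, collapse = ","),
      judgement = judgement, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("species_assessment", "data.frame")
  out
}

#' Report species needing caution or failing
#'
#' Groups all species whose judgement is not `success` by genus, mirroring the
#' usual caution-table layout (category in parentheses, sub-threshold
#' neighbours flagged as Cautions).
#'
#' @param assessments a [classify_species()] result.
#' @param config the [classifier_config()] used (for the threshold shown in
#'   reasons).
#' @return data.frame with `genus`, `species`, `label` (e.g.
#'   `"Genus species (Mixture)"` or `"... (Cautions)"`), `reason`.
#' @export
caution_report <- function(assessments, config = classifier_config()) {
  bad <- assessments[assessments$judgement != "success", , drop = FALSE]
  if (!nrow(bad)) {
    return(data.frame(genus = character(0), species = character(0),
                      label = character(0), reason = character(0)))
  }
  lab <- ifelse(bad$judgement == "failure",
                ifelse(bad$single_specimen_merge,
                       paste0(bad$species, " (Merge)"),
                       paste0(bad$species, " (", bad$category, ")")),
                paste0(bad$species, " (Cautions)"))
  reason <- ifelse(bad$judgement == "failure",
                   ifelse(bad$single_specimen_merge,
                          "single sequence shared with another species",
                          paste0("category ", bad$category)),
                   sprintf("nearest heterospecific distance %.4f <= %.4g",
                           bad$nn_hetero,
                           config$caution_threshold))
  out <- data.frame(genus = bad$genus, species = bad$species, label = lab,
                    reason = reason, stringsAsFactors = FALSE)
  out <- out[order(out$genus, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overall discriminability of the reference library
#'
#' A species is counted discriminable ("possesses a unique sequence") unless
#' its judgement is `failure`. Percentage reported to one decimal.
#'
#' @param assessments a [classify_species()] result.
#' @return list with `n_species`, `n_failures`, `n_unique`, `pct_unique`.
#' @export
discriminability <- function(assessments) {
  n <- nrow(assessments)
  nf <- sum(assessments$judgement == "failure")
  list(n_species = n, n_failures = nf, n_unique = n - nf,
       pct_unique = round(100 * (n - nf) / n, 1))
}

#' Screen a dataset for anomalous sequences
#'
#' Flags (never excludes) sequences that look mislabelled or otherwise
#' unreliable: a sequence whose nearest conspecific is farther than
#' `max_conspecific_dist`, or whose nearest neighbour overall belongs to a
#' different genus while conspecifics exist elsewhere. Exclusion is a human
#' curation decision recorded in the metadata, not an automatic one.
#'
#' @param dm a [distance_matrix()].
#' @param max_conspecific_dist flag threshold for the nearest conspecific
#'   (default 0.05).
#' @param require_genus_neighbor if `TRUE` (default), also flag sequences
#'   whose nearest neighbour is heterogeneric despite conspecifics existing.
#' @param metric `"p"` (default) or `"tn93"`.
#' @return data.frame review list: `accession`, `species`, `reason`,
#'   `nearest_conspecific_dist`, `nearest_neighbor_species`.
#' @export
curation_screen <- function(dm, max_conspecific_dist = 0.05,
                            require_genus_neighbor = TRUE, metric = "p") {
  d <- dist_metric(dm, metric)
  n <- length(dm$labels)
  rows <- list()
  for (i in seq_len(n)) {
    cons <- which(dm$species == dm$species[i])
    cons <- setdiff(cons, i)
    others <- setdiff(seq_len(n), i)
    nn <- others[which.min(d[i, others])]
    reasons <- character(0)
    ncd <- NA_real_
    if (length(cons)) {
      ncd <- min(d[i, cons])
      if (ncd > max_conspecific_dist) {
        reasons <- c(reasons, sprintf(
          "nearest conspecific at %.4f > %.4g", ncd, max_conspecific_dist))
      }
      if (require_genus_neighbor && dm$genus[nn] != dm$genus[i]) {
        reasons <- c(reasons, paste0(
          "nearest neighbour is heterogeneric (", dm$species[nn],
          ") despite conspecifics present"))
      }
    }
    if (length(reasons)) {
      rows[[length(rows) + 1L]] <- data.frame(
        accession = dm$labels[i], species = dm$species[i],
        reason = paste(reasons, collapse = "; "),
        nearest_conspecific_dist = ncd,
        nearest_neighbor_species = dm$species[nn],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(0), species = character(0),
               reason = character(0), nearest_conspecific_dist = numeric(0),
               nearest_neighbor_species = character(0))
  rownames(out) <- NULL
  out
}
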