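# End-to-end evaluation: barcode_eval() is the central fitting function
# (records in, classified assessment out as a classed object with methods);
# run_pipeline() orchestrates a full on-disk run; compare_regions() contrasts
# the same library analysed on two regions.

#' Evaluate a barcode reference library
#'
#' The core computation: every pair of sequences is globally aligned, p and
#' TN93 distance matrices are computed under pairwise deletion, a
#' neighbour-joining tree is built (TN93 by default, the usual tree metric),
#' every species is classified Match/Split/Merge/Mixture with the
#' single-specimen rule, and judgements are assigned with the distance
#' caution threshold (default 0.01 substitutions/site).
#'
#' @param records record data.frame (see [read_barcode_fasta()]), >= 3
#'   sequences, >= 2 species.
#' @param config a [classifier_config()].
#' @param params an [align_params()].
#' @param tree_metric metric for tree building, `"tn93"` (default, falling
#'   back to `"p"` with a warning if any TN93 entry is undefined) or `"p"`.
#' @param bootstrap number of bootstrap pseudoreplicates for node supports
#'   (0 = skip; supports do not affect the classification).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `barcode_eval`: list with `records`, `dist`
#'   (a `barcode_dist`), `tree` (`phylo`), `assessments`
#'   (a [classify_species()] data.frame), `summary` (see
#'   [summary.barcode_eval()]), `config`, and `bootstrap` (or `NULL`).
#' @export
barcode_eval <- function(records, config = classifier_config(),
                         params = align_params(), tree_metric = "tn93",
                         bootstrap = 0L, seed = 1L) {
  validate_records(records)
  if (nrow(records) < 3L) stop("need at least 3 sequences")
  if (length(unique(records$species)) < 2L) stop("need at least 2 species")

  dm <- distance_matrix(records, params)
  metric_used <- tree_metric
  if (tree_metric == "tn93" && anyNA(dm$tn93)) {
    warning("undefined TN93 distance(s); falling back to p-distance for ",
            "tree building")
    metric_used <- "p"
  }
  tree <- nj_tree(dm, metric_used)

  boot <- NULL
  if (bootstrap > 0L) {
    msa <- progressive_msa(records, params)
    boot <- bootstrap_support(msa, n_replicates = bootstrap, seed = seed,
                              metric = metric_used)
  }

  assessments <- classify_species(tree, dm, config)
  obj <- structure(list(records = records, dist = dm, tree = tree,
                        assessments = assessments, config = config,
                        params = params, tree_metric = metric_used,
                        bootstrap = boot),
                   class = "barcode_eval")
  obj$summary <- summarize_eval(obj)
  obj
}

# Build the run summary (internally consistent by construction; asserted).
summarize_eval <- function(obj) {
  a <- obj$assessments
  dm <- obj$dist
  config <- obj$config
  disc <- discriminability(a)
  cats <- c("Match", "Split", "Merge", "Mixture", "NA_single")
  cat_counts <- setNames(vapply(cats, function(cc) sum(a$category == cc),
                                integer(1)), cats)
  intra <- intraspecific_summary(dm, config$metric)
  multi <- a$n_seqs > 1L
  n_multi <- sum(multi)
  pct_intra_lt <- if (n_multi) {
    round(100 * sum(a$max_intra[multi] < config$caution_threshold) / n_multi, 1)
  } else NA_real_
  s <- list(
    n_seqs = nrow(obj$records),
    n_species = disc$n_species,
    n_multi = n_multi,
    category_counts = cat_counts,
    n_single_merge = sum(a$single_specimen_merge),
    n_caution = sum(a$judgement == "caution"),
    n_failures = disc$n_failures,
    n_unique = disc$n_unique,
    pct_unique = disc$pct_unique,
    mean_conspecific_subst = intra$mean_subst_overall,
    mean_conspecific_dist = intra$mean_dist_overall,
    max_conspecific_dist = if (n_multi) max(a$max_intra[multi]) else NA_real_,
    pct_intra_below_threshold = pct_intra_lt,
    per_genus = interspecific_summary(dm, config$metric)
  )
  # internal consistency invariants
  stopifnot(sum(s$category_counts) == s$n_species,
            s$n_failures == sum(s$category_counts[c("Split", "Merge",
                                                    "Mixture")]) +
              s$n_single_merge,
            s$n_unique + s$n_failures == s$n_species)
  s
}

#' @export
print.barcode_eval <- function(x, ...) {
  s <- x$summary
  cat("Barcode reference library evaluation\n")
  cat(sprintf("  %d sequences, %d species (%d with >1 sequence)\n",
              s$n_seqs, s$n_species, s$n_multi))
  cat(sprintf("  tree metric: %s; threshold: %.3g (%s)\n", x$tree_metric,
              x$config$caution_threshold, x$config$metric))
  cc <- s$category_counts
  cat(sprintf("  Match %d | Split %d | Merge %d | Mixture %d | single %d (of which %d merged)\n",
              cc["Match"], cc["Split"], cc["Merge"], cc["Mixture"],
              cc["NA_single"], s$n_single_merge))
  cat(sprintf("  discriminable: %d/%d (%.1f%%); cautions: %d\n",
              s$n_unique, s$n_species, s$pct_unique, s$n_caution))
  invisible(x)
}

#' Summary of a barcode evaluation
#'
#' @param object a [barcode_eval()] object.
#' @param ... unused.
#' @return the summary list (counts, category table, distance summaries,
#'   per-genus table) described in [barcode_eval()].
#' @export
summary.barcode_eval <- function(object, ...) {
  object$summary
}

#' Barcode-gap plot
#'
#' Overlaid histograms of intraspecific and congeneric interspecific
#' p-distances; the caution threshold is drawn as a vertical line. The
#' separation (or overlap) of the two distributions is the barcode gap.
#'
#' @param x a [barcode_eval()] object.
#' @param breaks histogram breaks.
#' @param ... passed to [graphics::hist()].
#' @export
plot.barcode_eval <- function(x, breaks = 30, ...) {
  dm <- x$dist
  d <- dist_metric(dm, x$config$metric)
  sp <- dm$species; gen <- dm$genus
  ut <- upper.tri(d)
  same_sp <- outer(sp, sp, "==") & ut
  congeneric <- outer(gen, gen, "==") & !outer(sp, sp, "==") & ut
  intra <- d[same_sp]; inter <- d[congeneric]
  if (!length(intra) && !length(inter)) stop("nothing to plot")
  rng <- range(c(intra, inter, x$config$caution_threshold))
  br <- seq(0, max(rng) * 1.05 + 1e-9, length.out = breaks)
  h1 <- if (length(intra)) hist(intra, breaks = br, plot = FALSE)
  h2 <- if (length(inter)) hist(inter, breaks = br, plot = FALSE)
  ymax <- max(c(h1$counts, h2$counts))
  plot(NULL, xlim = c(0, max(rng) * 1.05), ylim = c(0, ymax),
       xlab = sprintf("%s distance", x$config$metric),
       ylab = "sequence pairs", main = "Barcode gap", ...)
  if (length(intra)) {
    plot(h1, col = grDevices::adjustcolor("steelblue", 0.6), add = TRUE)
  }
  if (length(inter)) {
    plot(h2, col = grDevices::adjustcolor("firebrick", 0.45), add = TRUE)
  }
  abline(v = x$config$caution_threshold, lty = 2)
  legend("topright", fill = c("steelblue", "firebrick"),
         legend = c("intraspecific", "interspecific (congeneric)"),
         bty = "n")
  invisible(x)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param records record data.frame (or `NULL` to simulate with `sim`).
#' @param sim optional [sim_config()]; used when `records` is `NULL`.
#' @param primers optional [primer_pair()]; when given, the pipeline also
#'   excises the subregion and evaluates it alongside the full region.
#' @param classifier a [classifier_config()].
#' @param params an [align_params()].
#' @param bootstrap bootstrap replicates (0 = none).
#' @param out_dir output directory (`NULL` = no artifacts written).
#' @param seed run seed; all randomness flows from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(records = NULL, sim = NULL, primers = NULL,
                       classifier = classifier_config(),
                       params = align_params(), bootstrap = 0L,
                       out_dir = NULL, seed = 1L) {
  structure(list(records = records, sim = sim, primers = primers,
                 classifier = classifier, params = params,
                 bootstrap = bootstrap, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the full evaluation pipeline
#'
#' Assemble (or simulate) the reference library, optionally excise the
#' subregion with the primer pair, compute distances and trees, classify
#' every species, and (optionally) write the artifacts: distance matrix TSV,
#' newick tree, assessments TSV, caution report, and a summary JSON.
#'
#' @param config a [run_config()].
#' @return list with `full` (the [barcode_eval()] of the input region),
#'   `sub` (evaluation of the excised subregion, or `NULL`), `truth`
#'   (simulation ground truth when simulated), and `summary` (the `full`
#'   summary, plus `sub_summary` when present).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  records <- config$records
  if (is.null(records)) {
    if (is.null(config$sim)) stop("run_config needs records or a sim config")
    simc <- config$sim
    simc$seed <- config$seed
    lib <- sim_barcode_library(simc)
    records <- lib$records
    truth <- lib$truth
  }
  full <- barcode_eval(records, config$classifier, config$params,
                       bootstrap = config$bootstrap, seed = config$seed)
  sub <- NULL
  if (!is.null(config$primers)) {
    sub_records <- extract_subregions(records, config$primers)
    sub <- barcode_eval(sub_records, config$classifier, config$params,
                        bootstrap = config$bootstrap, seed = config$seed)
  }
  out <- list(full = full, sub = sub, truth = truth,
              summary = full$summary,
              sub_summary = if (!is.null(sub)) sub$summary else NULL)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_eval_artifacts(full, config$out_dir, prefix = "full")
    if (!is.null(sub)) write_eval_artifacts(sub, config$out_dir,
                                            prefix = "sub")
  }
  out
}

write_eval_artifacts <- function(ev, dir, prefix) {
  dmat <- dist_metric(ev$dist, ev$config$metric)
  write.table(data.frame(accession = rownames(dmat), dmat,
                         check.names = FALSE),
              file.path(dir, paste0(prefix, "_matrix.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(ev$tree, file.path(dir, paste0(prefix, "_tree.nwk")))
  write.table(ev$assessments,
              file.path(dir, paste0(prefix, "_assessments.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(caution_report(ev$assessments, ev$config),
              file.path(dir, paste0(prefix, "_cautions.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- ev$summary
  s$per_genus <- NULL
  jsonlite::write_json(s, file.path(dir, paste0(prefix, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Compare evaluations of the same library on two regions
#'
#' Lists species whose judgement changes between a longer-region and a
#' shorter-region analysis of the same species set (e.g. full 12S fragment
#' versus excised hypervariable window).
#'
#' @param eval_long,eval_short [barcode_eval()] objects (or their
#'   `assessments`).
#' @return list with `delta` (data.frame: species, judgement in each run,
#'   direction), `n_degraded`, `n_improved`.
#' @export
compare_regions <- function(eval_long, eval_short) {
  a <- if (inherits(eval_long, "barcode_eval")) eval_long$assessments else eval_long
  b <- if (inherits(eval_short, "barcode_eval")) eval_short$assessments else eval_short
  common <- intersect(a$species, b$species)
  if (!setequal(a$species, b$species)) {
    warning("species sets differ; restricting to the intersection (",
            length(common), " species)")
  }
  rank <- c(success = 0L, caution = 1L, failure = 2L)
  ja <- setNames(a$judgement, a$species)[common]
  jb <- setNames(b$judgement, b$species)[common]
  changed <- ja != jb
  delta <- data.frame(species = common[changed],
                      judgement_long = unname(ja[changed]),
                      judgement_short = unname(jb[changed]),
                      direction = ifelse(rank[jb[changed]] > rank[ja[changed]],
                                         "degraded", "improved"),
                      stringsAsFactors = FALSE)
  rownames(delta) <- NULL
  list(delta = delta,
       n_degraded = sum(delta$direction == "degraded"),
       n_improved = sum(delta$direction == "improved"))
}
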