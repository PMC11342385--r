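# In-silico excision of an amplicon subregion (e.g. the hypervariable MiFish
# window of 12S) by degenerate primer matching, with a reference-anchored
# fallback for deposited fragments that lack the primer sites.

#' Define a primer pair for subregion excision
#'
#' The forward primer is given 5'->3' on the sense strand; the reverse primer
#' is given 5'->3' on the antisense strand (the usual way primers are printed)
#' and is reverse-complemented internally before matching the sense strand.
#'
#' @param fwd forward primer (IUPAC string).
#' @param rev reverse primer (IUPAC string, antisense 5'->3').
#' @param max_mismatch maximum mismatches tolerated per primer site. The
#'   default 3 for ~20-mers absorbs natural variation in conserved flanks.
#' @param fwd_window,rev_window optional 0-based half-open intervals
#'   restricting where each primer may bind; `NULL` means anywhere.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(fwd, rev, max_mismatch = 3L,
                        fwd_window = NULL, rev_window = NULL) {
  fwd <- normalize_seq(fwd); rev <- normalize_seq(rev)
  if (nchar(fwd) < 10L || nchar(rev) < 10L) stop("primers must be >= 10 nt")
  lim <- floor(min(nchar(fwd), nchar(rev)) / 4)
  if (max_mismatch > lim) {
    stop("max_mismatch must be <= floor(primer length / 4) = ", lim)
  }
  structure(list(fwd = fwd, rev = rev, max_mismatch = as.integer(max_mismatch),
                 fwd_window = fwd_window, rev_window = rev_window),
            class = "primer_pair")
}

#' Match a degenerate primer against a target sequence
#'
#' Slides the primer over the (windowed) target and returns the best hit: the
#' offset with the fewest mismatches, ties broken by smallest start. A primer
#' symbol matches a target base when the target base's set is contained in the
#' primer symbol's IUPAC set (so primer N matches anything, primer R matches A
#' or G, but a primer A does not match a target N).
#'
#' @param target nucleotide string.
#' @param primer IUPAC primer string (sense strand orientation).
#' @param max_mismatch maximum mismatches for a reportable hit.
#' @param window optional 0-based half-open `c(start, end)` interval of
#'   allowed primer start positions' span on the target.
#' @return `NULL` if no hit within budget, else a list with 0-based half-open
#'   `start`, `end`, and `mismatches`.
#' @export
match_primer <- function(target, primer, max_mismatch = 3L, window = NULL) {
  tm <- seq_to_mask(normalize_seq(target))
  pm <- seq_to_mask(normalize_seq(primer))
  k <- length(pm); n <- length(tm)
  lo <- 0L; hi <- n
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] >= 0L, window[2] <= n)
    lo <- as.integer(window[1]); hi <- as.integer(window[2])
  }
  if (hi - lo < k) return(NULL)
  starts <- lo:(hi - k)  # 0-based
  # mismatch iff target set not contained in primer set
  mm <- vapply(starts, function(s) {
    tt <- tm[(s + 1L):(s + k)]
    sum(bitwAnd(tt, bitwNot(pm)) != 0L | tt == 0L)
  }, integer(1))
  best <- which.min(mm)  # first minimum -> smallest start on ties
  if (mm[best] > max_mismatch) return(NULL)
  list(start = starts[best], end = starts[best] + k,
       mismatches = mm[best], strand = "+")
}

#' Excise the amplicon subregion between a primer pair
#'
#' Locates both primer sites and returns the insert between them (primers
#' excluded), consistent with reported subregion lengths being insert-only.
#' A warning is emitted if the excised length falls outside
#' `expected_range`.
#'
#' @param record one-row record data.frame with `region == "longer12S"`.
#' @param primers a [primer_pair()].
#' @param expected_range expected insert length range, default `c(166, 199)`.
#' @return the record with `seq` replaced by the insert and
#'   `region = "mifish"`.
#' @export
extract_subregion <- function(record, primers, expected_range = c(166L, 199L)) {
  stopifnot(inherits(primers, "primer_pair"), nrow(record) == 1L)
  if (record$region != "longer12S") {
    stop("record ", record$accession, " is not a longer12S record")
  }
  target <- record$seq
  fh <- match_primer(target, primers$fwd, primers$max_mismatch,
                     primers$fwd_window)
  if (is.null(fh)) {
    stop("forward primer not found within mismatch budget for accession ",
         record$accession)
  }
  rc <- revcomp(primers$rev)
  rwin <- primers$rev_window
  if (is.null(rwin)) rwin <- c(fh$end, nchar(target))
  rh <- match_primer(target, rc, primers$max_mismatch, rwin)
  if (is.null(rh) || rh$start < fh$end) {
    stop("reverse primer not found within mismatch budget for accession ",
         record$accession)
  }
  core <- substr(target, fh$end + 1L, rh$start)  # 0-based half-open -> 1-based
  len <- nchar(core)
  if (len < expected_range[1] || len > expected_range[2]) {
    warning(sprintf("accession %s: excised length %d outside %d-%d",
                    record$accession, len, expected_range[1],
                    expected_range[2]))
  }
  record$seq <- core
  record$region <- "mifish"
  record
}

#' Excise subregions for a whole record table
#'
#' @param records record data.frame of longer-region sequences.
#' @param primers a [primer_pair()].
#' @param expected_range see [extract_subregion()].
#' @param reference optional one-row mifish-region record used by
#'   [anchor_trim()] as a fallback when a primer site is missing.
#' @return record data.frame of excised subregions (region `"mifish"`).
#' @export
extract_subregions <- function(records, primers, expected_range = c(166L, 199L),
                               reference = NULL) {
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    out[[i]] <- tryCatch(
      extract_subregion(rec, primers, expected_range),
      error = function(e) {
        if (is.null(reference)) stop(e)
        anchor_trim(rec, reference)
      })
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trim a record to a reference-anchored interval
#'
#' Fallback for sequences whose primer sites are absent (e.g. deposited
#' fragments that start inside the amplicon): globally aligns the record to a
#' trusted subregion exemplar and returns the record's residues spanning the
#' reference's aligned extent.
#'
#' @param record one-row record data.frame.
#' @param reference one-row record data.frame with `region == "mifish"`.
#' @param min_coverage minimum fraction of reference positions aligned to
#'   record residues; below this the trim is refused.
#' @param params alignment parameters, see [align_params()].
#' @return the trimmed record with `region = "mifish"`.
#' @export
anchor_trim <- function(record, reference, min_coverage = 0.8,
                        params = align_params()) {
  stopifnot(nrow(record) == 1L, nrow(reference) == 1L)
  if (reference$region != "mifish") stop("reference must be a mifish record")
  al <- nw_align(record$seq, reference$seq, params)
  a <- seq_to_mask(al$a); b <- seq_to_mask(al$b)
  ref_cols <- which(b != 0L)
  covered <- sum(a[ref_cols] != 0L) / length(ref_cols)
  if (covered < min_coverage) {
    stop(sprintf("accession %s: aligned coverage of reference %.2f < %.2f",
                 record$accession, covered, min_coverage))
  }
  span <- a[min(ref_cols):max(ref_cols)]
  record$seq <- mask_to_seq(span[span != 0L])
  record$region <- "mifish"
  record
}
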