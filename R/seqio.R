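# Sequence and metadata I/O, taxonomic-name revision, and dataset assembly.
#
# A sequence record set is a plain data.frame with columns:
#   accession, species, genus, voucher, source ("determined"/"retrieved"),
#   region ("longer12S"/"mifish"), seq
# Accessions must be unique; genus is always the first token of species.

.RECORD_COLS <- c("accession", "species", "genus", "voucher", "source",
                  "region", "seq")

#' Normalize a species name
#'
#' Collapses whitespace/underscores, strips trailing author-and-year text,
#' and keeps open-nomenclature epithets such as `"sp. minamiiso"` verbatim so
#' undescribed morphotypes map to a single species key.
#'
#' @param x character vector of raw species names.
#' @return character vector of normalized binomials.
#' @export
#' @examples
#' normalize_species("Abudefduf_vaigiensis (Quoy & Gaimard, 1825)")
#' normalize_species("Pomacentrus sp. minamiiso")
normalize_species <- function(x) {
  s <- gsub("_", " ", x, fixed = TRUE)
  s <- gsub("\\s+", " ", trimws(s))
  # strip parenthesized or trailing "Author, year" annotations
  s <- gsub("\\s*\\([^)]*\\)", "", s)
  s <- gsub(",\\s*\\d{4}.*$", "", s)
  s <- gsub("\\s+", " ", trimws(s))
  # keep only "Genus epithet" or "Genus sp. tag"
  out <- vapply(strsplit(s, " ", fixed = TRUE), function(tok) {
    if (length(tok) >= 3L && tok[2] %in% c("sp.", "sp", "cf.", "aff.")) {
      paste(tok[1], "sp.", tok[3])
    } else if (length(tok) >= 2L) {
      paste(tok[1], tok[2])
    } else {
      tok[1]
    }
  }, character(1))
  out
}

new_record <- function(accession, species, voucher = NA_character_,
                       source = "retrieved", region = "longer12S", seq) {
  species <- normalize_species(species)
  data.frame(
    accession = accession,
    species = species,
    genus = vapply(strsplit(species, " ", fixed = TRUE), `[`, character(1), 1L),
    voucher = voucher,
    source = source,
    region = region,
    seq = seq,
    stringsAsFactors = FALSE
  )
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records), all(.RECORD_COLS %in% names(records)))
  if (anyDuplicated(records$accession)) {
    stop("duplicate accession(s): ",
         paste(unique(records$accession[duplicated(records$accession)]),
               collapse = ", "))
  }
  if (any(!nzchar(records$seq))) stop("empty sequence present")
  first_tok <- vapply(strsplit(records$species, " ", fixed = TRUE),
                      `[`, character(1), 1L)
  if (!all(records$genus == first_tok)) {
    stop("genus must equal the first token of species")
  }
  invisible(records)
}

#' Read a barcode FASTA file into a record table
#'
#' Two header dialects are supported. The default pipe-delimited dialect is
#' `>accession|Species_with_underscores|voucher` (voucher optional); INSD-style
#' headers are unreliable as species labels, so with `plain = TRUE` only the
#' first whitespace token is taken as the accession and species labels must be
#' supplied through a metadata table (see [read_metadata()]).
#'
#' Sequences are uppercased and U is mapped to T.
#'
#' @param path FASTA file.
#' @param plain if `TRUE`, parse only the accession from each header.
#' @param region region tag to assign (`"longer12S"` or `"mifish"`).
#' @param source provenance tag (`"determined"` or `"retrieved"`).
#' @return record data.frame (one row per entry, input order preserved).
#' @export
read_barcode_fasta <- function(path, plain = FALSE, region = "longer12S",
                               source = "retrieved") {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(dna) || length(dna) == 0L) stop("empty FASTA file: ", path)
  headers <- names(dna)
  seqs <- vapply(as.character(dna), function(ch) {
    normalize_seq(paste(ch, collapse = ""))
  }, character(1))

  if (plain) {
    acc <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
    rec <- new_record(acc, species = "Unknown sp. pending",
                      region = region, source = source, seq = unname(seqs))
    rec$species <- NA_character_
    rec$genus <- NA_character_
  } else {
    parts <- strsplit(headers, "|", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) < 2L
    if (any(bad)) {
      stop("malformed header (no species token): ",
           paste(headers[bad], collapse = "; "))
    }
    rec <- new_record(
      accession = vapply(parts, `[`, character(1), 1L),
      species = vapply(parts, `[`, character(1), 2L),
      voucher = vapply(parts, function(p)
        if (length(p) >= 3L && nzchar(p[3])) p[3] else NA_character_,
        character(1)),
      region = region, source = source, seq = unname(seqs)
    )
    validate_records(rec)
  }
  rownames(rec) <- NULL
  rec
}

#' Write a record table as FASTA
#'
#' Headers use the pipe-delimited dialect read back by [read_barcode_fasta()],
#' so `read(write(x))` is the identity on normalized records.
#'
#' @param records record data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(records, path) {
  validate_records(records)
  records$seq <- vapply(records$seq, normalize_seq, character(1),
                        USE.NAMES = FALSE)
  hdr <- ifelse(is.na(records$voucher),
                paste(records$accession,
                      gsub(" ", "_", records$species, fixed = TRUE), sep = "|"),
                paste(records$accession,
                      gsub(" ", "_", records$species, fixed = TRUE),
                      records$voucher, sep = "|"))
  dna <- lapply(records$seq, function(s) strsplit(tolower(s), "")[[1]])
  names(dna) <- hdr
  ape::write.FASTA(ape::as.DNAbin(dna), path)
  invisible(path)
}

#' Read a metadata table
#'
#' Tab-separated, with columns `accession`, `species`, `genus`, `voucher`,
#' `source`, `d1_flag`, `d2_flag`, `d3_flag` and optionally
#' `original_insd_name`, `morphotype`. Dataset flags are truthy for `1`,
#' `TRUE`, `yes`, `x` or a circle mark.
#'
#' @param path TSV file.
#' @return data.frame with logical flag columns.
#' @export
read_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("accession", "species", "d1_flag", "d2_flag", "d3_flag")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  truthy <- function(x) {
    x <- trimws(tolower(as.character(x)))
    !is.na(x) & x %in% c("1", "true", "t", "yes", "y", "x", "○", "〇")
  }
  for (fl in c("d1_flag", "d2_flag", "d3_flag")) meta[[fl]] <- truthy(meta[[fl]])
  meta$species <- normalize_species(meta$species)
  if (is.null(meta$genus)) {
    meta$genus <- vapply(strsplit(meta$species, " ", fixed = TRUE),
                         `[`, character(1), 1L)
  }
  meta
}

#' Apply taxonomic name revisions to records
#'
#' Reference sequences deposited under superseded names must be relabelled
#' before evaluation; each revision maps one original binomial to its current
#' one (many-to-one allowed, conflicting duplicates are an error).
#'
#' @param records record data.frame.
#' @param revisions data.frame with columns `original_name`, `revised_name`.
#' @return list with `records` (revised), `n_replaced`, and `unmatched`
#'   (revisions whose original matched no record).
#' @export
apply_name_revisions <- function(records, revisions) {
  if (is.null(revisions) || nrow(revisions) == 0L) {
    return(list(records = records, n_replaced = 0L, unmatched = character(0)))
  }
  stopifnot(all(c("original_name", "revised_name") %in% names(revisions)))
  orig <- normalize_species(revisions$original_name)
  revd <- normalize_species(revisions$revised_name)
  if (any(orig == revd)) stop("revision maps a name to itself")
  dup <- duplicated(orig)
  if (any(dup)) {
    conflict <- vapply(unique(orig[dup]), function(o)
      length(unique(revd[orig == o])) > 1L, logical(1))
    if (any(conflict)) {
      stop("conflicting revisions for: ",
           paste(unique(orig[dup])[conflict], collapse = ", "))
    }
    keep <- !dup
    orig <- orig[keep]; revd <- revd[keep]
  }
  unmatched <- orig[!orig %in% records$species]
  hit <- match(records$species, orig)
  n_replaced <- sum(!is.na(hit))
  records$species[!is.na(hit)] <- revd[hit[!is.na(hit)]]
  records$genus <- vapply(strsplit(records$species, " ", fixed = TRUE),
                          `[`, character(1), 1L)
  list(records = records, n_replaced = n_replaced, unmatched = unmatched)
}

.DATASET_RANGES <- list(
  D1_longer = c(725L, 773L),
  D2_mifish_same = c(166L, 199L),
  D3_mifish_extended = c(166L, 199L)
)

#' Assemble an analysis dataset from records and metadata flags
#'
#' Selects the records flagged for a dataset, attaches authoritative species
#' labels from the metadata, and reports species/sequence counts. Members with
#' lengths outside the expected range for the dataset trigger a warning but are
#' retained: exclusion is an explicit curation decision (see
#' [curation_screen()]), not an automatic one.
#'
#' @param records record data.frame (all candidate sequences).
#' @param meta metadata table from [read_metadata()].
#' @param dataset one of `"D1_longer"`, `"D2_mifish_same"`,
#'   `"D3_mifish_extended"`.
#' @return list with `name`, `records` (members only), `n_seqs`, `n_species`,
#'   `n_multi` (species with >1 sequence), `expected_length_range`,
#'   `out_of_range` (accessions outside the range).
#' @export
assemble_dataset <- function(records, meta,
                             dataset = c("D1_longer", "D2_mifish_same",
                                         "D3_mifish_extended")) {
  dataset <- match.arg(dataset)
  flag_col <- switch(dataset, D1_longer = "d1_flag",
                     D2_mifish_same = "d2_flag",
                     D3_mifish_extended = "d3_flag")
  members <- meta$accession[meta[[flag_col]]]
  missing <- setdiff(members, records$accession)
  if (length(missing)) {
    stop("flagged accession(s) with no sequence: ",
         paste(missing, collapse = ", "))
  }
  sel <- records[match(members, records$accession), , drop = FALSE]
  # metadata is the authoritative species source
  mi <- match(sel$accession, meta$accession)
  sel$species <- meta$species[mi]
  sel$genus <- meta$genus[mi]
  if (!is.null(meta$voucher)) sel$voucher <- as.character(meta$voucher[mi])
  rownames(sel) <- NULL
  validate_records(sel)

  rng <- .DATASET_RANGES[[dataset]]
  len <- nchar(sel$seq)
  oor <- sel$accession[len < rng[1] | len > rng[2]]
  if (length(oor)) {
    warning(sprintf("%d member(s) outside expected length range %d-%d: %s",
                    length(oor), rng[1], rng[2],
                    paste(oor, collapse = ", ")))
  }
  tab <- table(sel$species)
  list(name = dataset, records = sel,
       n_seqs = nrow(sel), n_species = length(tab),
       n_multi = sum(tab > 1L),
       expected_length_range = rng, out_of_range = oor)
}
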