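# IUPAC nucleotide machinery shared across the package. Symbols are encoded as
# bitmasks over {A=1, C=2, G=4, T=8}; gaps encode as 0.

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
  "-" = 0L, "." = 0L
)

.MASK_CHAR <- character(16)
.MASK_CHAR[1 + c(1L, 2L, 4L, 8L, 5L, 10L, 6L, 9L, 12L, 3L, 14L, 13L, 11L, 7L, 15L)] <-
  c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
.MASK_CHAR[1] <- "-"

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", "-" = "-"
)

#' Encode a nucleotide string as IUPAC bitmasks
#'
#' Internal representation used by the aligner and distance code: A=1, C=2,
#' G=4, T=8, ambiguity codes as unions, gaps as 0. Input is case-insensitive
#' and U is treated as T.
#'
#' @param x single nucleotide string.
#' @return integer vector of bitmasks, one per position.
#' @keywords internal
seq_to_mask <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  m <- .IUPAC_MASK[ch]
  if (anyNA(m)) {
    bad <- unique(ch[is.na(m)])
    stop("non-IUPAC symbol(s) in sequence: ", paste(bad, collapse = ", "))
  }
  unname(m)
}

#' @rdname seq_to_mask
#' @param m integer mask vector.
#' @keywords internal
mask_to_seq <- function(m) {
  paste(.MASK_CHAR[m + 1L], collapse = "")
}

#' Reverse-complement a nucleotide string
#'
#' Handles all IUPAC ambiguity codes and gaps; U maps to A on complementing.
#'
#' @param x single nucleotide string.
#' @return reverse-complemented string, uppercase.
#' @export
#' @examples
#' revcomp("ACGTRN")
revcomp <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  cc <- .IUPAC_COMPLEMENT[ch]
  if (anyNA(cc)) {
    stop("non-IUPAC symbol(s) in sequence: ",
         paste(unique(ch[is.na(cc)]), collapse = ", "))
  }
  paste(rev(unname(cc)), collapse = "")
}

# Normalize a raw sequence string: uppercase, U -> T; error on non-IUPAC.
normalize_seq <- function(x) {
  s <- gsub("U", "T", toupper(x), fixed = TRUE)
  seq_to_mask(s)  # validates
  s
}

# TRUE for masks that are exactly one of A, C, G, T.
is_acgt_mask <- function(m) m == 1L | m == 2L | m == 4L | m == 8L
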