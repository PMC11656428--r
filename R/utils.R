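# Low-level sequence utilities shared by every module.
#
# Coordinate convention: 0-based, half-open [start, end) everywhere inside the
# package.  Conversion to 1-based inclusive happens only in the GFF writer.

# Integer encoding of DNA: A=1, C=2, G=3, T=4, N=0.  N never matches anything.
.dna_code_table <- local({
  tab <- integer(256)
  tab[utf8ToInt("A") + 1L] <- 1L
  tab[utf8ToInt("C") + 1L] <- 2L
  tab[utf8ToInt("G") + 1L] <- 3L
  tab[utf8ToInt("T") + 1L] <- 4L
  tab
})

# complement lookup indexed by code + 1 (N -> N)
.dna_comp_code <- c(0L, 4L, 3L, 2L, 1L)

#' Encode a DNA string as an integer vector
#'
#' A=1, C=2, G=3, T=4, N (or anything else) = 0.  Internal helper exposed for
#' tests and for user code that wants fast per-position comparison.
#'
#' @param x single normalised DNA string over A/C/G/T/N.
#' @return integer vector of length `nchar(x)`.
#' @keywords internal
#' @export
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  .dna_code_table[as.integer(charToRaw(x)) + 1L]
}

#' Reverse complement of a DNA string
#'
#' Works on normalised sequences (A/C/G/T/N, upper case).
#'
#' @param x single DNA string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", x))))
}

#' Normalise raw FASTA residues
#'
#' Uppercases, maps U to T, maps IUPAC ambiguity codes other than N to N.  Any
#' character outside the IUPAC alphabet raises a format error.
#'
#' @param x single string of residues as read from file.
#' @param context character used in error messages (e.g. file name).
#' @return normalised string over A/C/G/T/N.
#' @export
normalize_residues <- function(x, context = "sequence") {
  s <- toupper(x)
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", s)
  if (nchar(bad) > 0L) {
    stop(sprintf("format error in %s: invalid residue character(s) '%s'",
                 context, substr(bad, 1L, 10L)), call. = FALSE)
  }
  # ambiguity codes other than N carry no usable base: collapse to N
  chartr("RYSWKMBDHV", "NNNNNNNNNN", s)
}

# --- interval helpers (0-based half-open, matrix with columns start, end) ----

empty_intervals <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

as_interval_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L) return(empty_intervals())
  m <- matrix(as.integer(x), ncol = 2L)
  colnames(m) <- c("start", "end")
  m
}

# union of possibly overlapping intervals; merges intervals whose gap is
# <= gap (gap = next_start - prev_end); gap 0 merges touching intervals
merge_intervals <- function(iv, gap = 0L) {
  iv <- as_interval_matrix(iv)
  if (nrow(iv) == 0L) return(iv)
  ir <- IRanges::IRanges(start = iv[, 1L] + 1L, end = iv[, 2L])
  red <- IRanges::reduce(ir, min.gapwidth = gap + 1L)
  cbind(start = IRanges::start(red) - 1L, end = IRanges::end(red))
}

interval_total_length <- function(iv) {
  iv <- as_interval_matrix(iv)
  if (nrow(iv) == 0L) return(0L)
  sum(iv[, 2L] - iv[, 1L])
}

# positions (0-based) covered by an interval set, as a sorted integer vector
interval_positions <- function(iv) {
  iv <- as_interval_matrix(iv)
  if (nrow(iv) == 0L) return(integer(0))
  sort(unique(unlist(lapply(seq_len(nrow(iv)), function(i) {
    if (iv[i, 2L] > iv[i, 1L]) seq.int(iv[i, 1L], iv[i, 2L] - 1L) else integer(0)
  }))))
}
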