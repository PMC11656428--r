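# FASTA input/output and the sequence containers used by every other module.

#' Construct a sequence record
#'
#' A `seq_record` holds one named DNA sequence after normalisation (upper case,
#' ambiguity codes other than N collapsed to N).  If the input carried
#' soft-masking (lowercase runs), the corresponding 0-based half-open intervals
#' are kept in `$masked_intervals`.
#'
#' @param id FASTA header token up to the first whitespace.
#' @param residues DNA string; normalised with [normalize_residues()].
#' @param description remainder of the header line (may be `""`).
#' @param masked_intervals optional two-column matrix (start, end), 0-based
#'   half-open, sorted and disjoint.
#' @return object of class `seq_record` with fields `id`, `description`,
#'   `residues`, `length`, `masked_intervals`.
#' @export
seq_record <- function(id, residues, description = "",
                       masked_intervals = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- normalize_residues(residues, context = id)
  structure(
    list(id = id,
         description = description,
         residues = residues,
         length = nchar(residues),
         masked_intervals = as_interval_matrix(masked_intervals)),
    class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s  (%d bp)\n", x$id, x$length))
  invisible(x)
}

#' Attach a mask to a sequence record
#'
#' @param record a [seq_record()].
#' @param intervals two-column matrix (start, end) of 0-based half-open
#'   intervals to render lowercase; must be sorted and pairwise disjoint.
#' @return object of class `masked_seq`.
#' @export
masked_sequence <- function(record, intervals) {
  stopifnot(inherits(record, "seq_record"))
  iv <- as_interval_matrix(intervals)
  if (nrow(iv) > 0L) {
    if (any(iv[, 1L] < 0L) || any(iv[, 2L] > record$length) ||
        any(iv[, 2L] <= iv[, 1L]))
      stop("mask intervals out of range or empty", call. = FALSE)
    if (is.unsorted(iv[, 1L], strictly = TRUE) ||
        any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
      stop("mask intervals must be sorted and disjoint", call. = FALSE)
  }
  structure(list(record = record, masked_intervals = iv),
            class = "masked_seq")
}

# lowercase runs of a raw (un-normalised) residue string -> 0-based intervals
.lowercase_runs <- function(raw_residues) {
  if (!nzchar(raw_residues)) return(empty_intervals())
  bytes <- as.integer(charToRaw(raw_residues))
  low <- bytes >= 97L & bytes <= 122L
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

.fasta_file_pattern <- "\\.(fa|fasta|fna)$"

#' Read FASTA sequences from a file or directory
#'
#' For a directory, every `.fa`/`.fasta`/`.fna` file (case-insensitive) is read
#' in lexicographic name order.  Residues are normalised (upper case; IUPAC
#' ambiguity codes other than N become N; U becomes T).  Lowercase runs in the
#' input are preserved as `masked_intervals` on each record so that soft-masked
#' output round-trips.
#'
#' @param path FASTA file or directory containing FASTA files.
#' @return list of [seq_record()] objects in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("input error: '%s' does not exist", path),
                               call. = FALSE)
  files <- if (dir.exists(path)) {
    f <- list.files(path, pattern = .fasta_file_pattern, ignore.case = TRUE,
                    full.names = TRUE)
    f[order(basename(f), method = "radix")]
  } else path
  if (length(files) == 0L)
    stop(sprintf("input error: no FASTA files (.fa/.fasta/.fna) in '%s'", path),
         call. = FALSE)
  unlist(lapply(files, .read_fasta_file), recursive = FALSE)
}

.read_fasta_file <- function(file) {
  lines <- readLines(file, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    stop(sprintf("format error: '%s' is empty", file), call. = FALSE)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop(sprintf("format error: '%s' line %d: expected FASTA header '>'",
                 file, nonblank[1L]), call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(file),
                  error = function(e)
                    stop(sprintf("format error in '%s': %s",
                                 file, conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L)
    stop(sprintf("format error: '%s' contains no sequences", file),
         call. = FALSE)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    header <- headers[i]
    if (is.null(header) || !nzchar(trimws(header)))
      stop(sprintf("format error: '%s': record %d has an empty header",
                   file, i), call. = FALSE)
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    raw <- as.character(set[[i]])
    seq_record(id = id, residues = raw, description = desc,
               masked_intervals = .lowercase_runs(raw))
  })
}

# render the residues of a masked_seq with lowercase masked intervals
.render_masked <- function(masked) {
  s <- masked$record$residues
  iv <- masked$masked_intervals
  if (nrow(iv) == 0L) return(s)
  for (i in seq_len(nrow(iv))) {
    lo <- iv[i, 1L] + 1L
    hi <- iv[i, 2L]
    substr(s, lo, hi) <- tolower(substr(s, lo, hi))
  }
  s
}

#' Write a soft-masked FASTA file
#'
#' Masked intervals are rendered lowercase, everything else uppercase; sequence
#' lines are wrapped at 60 columns.
#'
#' @param masked a [masked_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_masked_fasta <- function(masked, path) {
  stopifnot(inherits(masked, "masked_seq"))
  header <- masked$record$id
  if (nzchar(masked$record$description))
    header <- paste(header, masked$record$description)
  s <- Biostrings::BStringSet(.render_masked(masked))
  names(s) <- header
  tryCatch(
    Biostrings::writeXStringSet(s, filepath = path, width = 60L),
    error = function(e) stop(sprintf("I/O error writing '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  invisible(path)
}
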