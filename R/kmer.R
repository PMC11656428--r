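# k-mer occurrence index and seed-pair enumeration.
#
# Detection anchors on exact k-mer identity: two loci sharing a k-mer (same
# strand) seed a direct-repeat candidate; a locus whose k-mer equals the
# reverse complement of another locus' k-mer seeds an inverted-repeat
# candidate.  k-mers containing N are never indexed.

#' Build the k-mer occurrence index of a sequence
#'
#' Every N-free window of length `k` is recorded with its 0-based start
#' position.  The minimum usable k-mer length is 5; a `k` longer than the
#' sequence yields an empty index.
#'
#' @param record a [seq_record()].
#' @param k k-mer length (integer, >= 5).
#' @return object of class `kmer_index` with fields `k`, `occurrences` (named
#'   list of strictly increasing 0-based position vectors), `sequence_length`,
#'   `n_windows` (number of N-free windows indexed).
#' @export
build_kmer_index <- function(record, k) {
  stopifnot(inherits(record, "seq_record"))
  k <- as.integer(k)
  if (is.na(k) || k < 5L)
    stop("parameter error: k-mer length must be at least 5", call. = FALSE)
  L <- record$length
  if (k > L) {
    return(structure(list(k = k, occurrences = list(),
                          sequence_length = L, n_windows = 0L),
                     class = "kmer_index"))
  }
  n <- L - k + 1L
  kmers <- substring(record$residues, seq_len(n), seq_len(n) + k - 1L)
  valid <- !grepl("N", kmers, fixed = TRUE)
  occ <- split(seq_len(n)[valid] - 1L, kmers[valid])
  structure(list(k = k, occurrences = occ, sequence_length = L,
                 n_windows = sum(valid)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d  %d windows, %d distinct k-mers (L=%d)\n",
              x$k, x$n_windows, length(x$occurrences), x$sequence_length))
  invisible(x)
}

# all i<j index pairs of a vector, vectorised
.pairs_within <- function(v) {
  n <- length(v)
  if (n < 2L) return(cbind(a = integer(0), b = integer(0)))
  m <- rev(seq_len(n - 1L))
  ia <- rep.int(seq_len(n - 1L), m)
  ib <- sequence(m) + ia
  cbind(a = v[ia], b = v[ib])
}

# full cross product of two disjoint position vectors
.pairs_cross <- function(u, v) {
  cbind(a = rep(u, each = length(v)), b = rep(v, times = length(u)))
}

#' Enumerate seed pairs from a k-mer index
#'
#' Yields every forward pair of occurrences of a k-mer with multiplicity
#' between 2 and `occurrence_cap`, and (optionally) every inverted pair of
#' loci whose k-mers are reverse complements of each other.  Inverted pairs
#' whose windows overlap by more than `floor(k/2)` positions are suppressed so
#' that hairpins and palindromes are found without degenerate self-pairs.
#' k-mers above `occurrence_cap` are withheld from pair enumeration and
#' reported as high-frequency (low-complexity candidates for the tandem
#' scanner) in the `"high_freq"` attribute.
#'
#' @param index a [build_kmer_index()] result.
#' @param record the record the index was built from.
#' @param search_inverted also enumerate reverse-complement pairs?
#' @param occurrence_cap maximum multiplicity for pair enumeration.
#' @return data.frame with columns `pos_a`, `pos_b` (0-based window starts,
#'   `pos_a <= pos_b`), `orientation` ("forward"/"inverted") and `k`; attribute
#'   `"high_freq"` is a data.frame (`kmer`, `count`) of capped k-mers.
#' @export
enumerate_seed_pairs <- function(index, record, search_inverted = TRUE,
                                 occurrence_cap = 1000L) {
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  occ <- index$occurrences
  mult <- lengths(occ)
  high <- data.frame(kmer = names(occ)[mult > occurrence_cap],
                     count = unname(mult[mult > occurrence_cap]),
                     stringsAsFactors = FALSE)
  usable <- mult <= occurrence_cap

  fwd <- do.call(rbind, lapply(occ[mult >= 2L & usable], .pairs_within))
  if (is.null(fwd)) fwd <- cbind(a = integer(0), b = integer(0))

  inv <- cbind(a = integer(0), b = integer(0))
  if (search_inverted && length(occ) > 0L) {
    nm <- names(occ)
    rc <- vapply(nm, revcomp, character(1L), USE.NAMES = FALSE)
    min_sep <- as.integer(ceiling(k / 2))  # window overlap <= floor(k/2)
    present <- match(rc, nm)
    parts <- vector("list", length(nm))
    for (i in seq_along(nm)) {
      j <- present[i]
      if (is.na(j) || !usable[i] || !usable[j]) next
      if (nm[i] < rc[i]) {
        parts[[i]] <- .pairs_cross(occ[[i]], occ[[j]])
      } else if (nm[i] == rc[i]) {
        parts[[i]] <- .pairs_within(occ[[i]])
      } # nm[i] > rc[i]: handled when the partner k-mer is visited
    }
    parts <- parts[!vapply(parts, is.null, logical(1L))]
    if (length(parts) > 0L) {
      inv <- do.call(rbind, parts)
      pa <- pmin(inv[, 1L], inv[, 2L])
      pb <- pmax(inv[, 1L], inv[, 2L])
      keep <- (pb - pa) >= min_sep
      inv <- cbind(a = pa[keep], b = pb[keep])
    }
  }

  pos_a <- c(fwd[, 1L], inv[, 1L])
  out <- data.frame(
    pos_a = pos_a,
    pos_b = c(fwd[, 2L], inv[, 2L]),
    orientation = rep(c("forward", "inverted"), c(nrow(fwd), nrow(inv))),
    k = rep.int(k, length(pos_a)),
    stringsAsFactors = FALSE)
  out <- out[order(out$pos_a, out$pos_b, out$orientation), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "high_freq") <- high
  out
}
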