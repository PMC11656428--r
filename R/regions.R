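# Projection of segment pairs onto the genome: length filtering, merging of
# adjacent repetitive areas into boundary-defined repeat blocks, coverage
# statistics and soft-masking.

#' Filtering and merging parameters
#'
#' Two independent length filters, mirroring the two knobs of the method: the
#' initial filter applies to the aligned length of each segment pair before
#' merging; the final filter applies to merged blocks.  `merge_gap` 0 merges
#' only overlapping or touching intervals (the conservative reading of
#' "adjacent"); the final length filter removes any leftover fragments.
#'
#' @param initial_string_length minimum aligned length of a segment pair
#'   (default 50).
#' @param string_length_filter minimum length of a merged repeat block
#'   (default 100).
#' @param merge_gap maximum gap (bases) between intervals that still merge
#'   (default 0).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(initial_string_length = 50L,
                          string_length_filter = 100L,
                          merge_gap = 0L) {
  stopifnot(initial_string_length >= 1, string_length_filter >= 1,
            merge_gap >= 0)
  structure(list(initial_string_length = as.integer(initial_string_length),
                 string_length_filter = as.integer(string_length_filter),
                 merge_gap = as.integer(merge_gap)),
            class = "filter_params")
}

#' Drop segment pairs shorter than the initial length filter
#'
#' @param pairs data.frame of extended pairs.
#' @param params a [filter_params()] list.
#' @return filtered data.frame (boundary inclusive: a pair of exactly the
#'   filter length is kept).
#' @export
filter_pairs <- function(pairs, params = filter_params()) {
  if (nrow(pairs) == 0L) return(pairs)
  res <- pairs[pairs$aligned_length >= params$initial_string_length, ,
               drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge pair intervals into repeat blocks
#'
#' Both intervals of every pair are projected onto the genome; intervals
#' separated by at most `merge_gap` bases are unioned; merged blocks shorter
#' than `string_length_filter` are discarded.  Blocks are numbered 1..B in
#' genomic order.
#'
#' @param pairs filtered data.frame of segment pairs.
#' @param sequence_length length of the sequence the pairs came from.
#' @param params a [filter_params()] list.
#' @return data.frame with columns `id`, `start`, `end` (0-based half-open),
#'   `max_identity`, and a list-column `pair_idx` of supporting row indices
#'   into `pairs`.
#' @export
merge_blocks <- function(pairs, sequence_length, params = filter_params()) {
  empty <- data.frame(id = integer(0), start = integer(0), end = integer(0),
                      max_identity = numeric(0))
  empty$pair_idx <- list()
  if (nrow(pairs) == 0L) return(empty)
  iv <- rbind(cbind(pairs$a_start, pairs$a_end),
              cbind(pairs$b_start, pairs$b_end))
  merged <- merge_intervals(iv, gap = params$merge_gap)
  keep <- (merged[, 2L] - merged[, 1L]) >= params$string_length_filter
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty)

  block_ir <- IRanges::IRanges(start = merged[, 1L] + 1L, end = merged[, 2L])
  side_ir <- IRanges::IRanges(start = iv[, 1L] + 1L, end = iv[, 2L])
  hits <- IRanges::findOverlaps(side_ir, block_ir)
  pair_of_side <- rep(seq_len(nrow(pairs)), 2L)
  sup <- lapply(seq_len(nrow(merged)), function(bi) {
    sort(unique(pair_of_side[S4Vectors_queryHits(hits)[
      S4Vectors_subjectHits(hits) == bi]]))
  })
  res <- data.frame(id = seq_len(nrow(merged)),
                    start = merged[, 1L], end = merged[, 2L],
                    max_identity = vapply(sup, function(ix)
                      if (length(ix)) max(pairs$identity[ix]) else NA_real_,
                      numeric(1L)))
  res$pair_idx <- sup
  res
}

# thin wrappers so the Hits accessors stay in one place
S4Vectors_queryHits <- function(h) S4Vectors::queryHits(h)
S4Vectors_subjectHits <- function(h) S4Vectors::subjectHits(h)

#' Percentage of the sequence covered by repeat blocks
#'
#' @param blocks data.frame from [merge_blocks()] (disjoint intervals).
#' @param sequence_length sequence length.
#' @return percentage (0..100), rounded to 2 decimals.
#' @export
coverage_fraction <- function(blocks, sequence_length) {
  if (sequence_length == 0L) {
    warning("coverage undefined for a zero-length sequence; reporting 0")
    return(0)
  }
  if (nrow(blocks) == 0L) return(0)
  round(100 * sum(blocks$end - blocks$start) / sequence_length, 2L)
}

#' Soft-mask a record from its repeat blocks
#'
#' @param record a [seq_record()].
#' @param blocks data.frame from [merge_blocks()].
#' @return a [masked_sequence()] whose masked intervals are the block
#'   intervals.
#' @export
mask_from_blocks <- function(record, blocks) {
  masked_sequence(record, cbind(start = blocks$start, end = blocks$end))
}
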