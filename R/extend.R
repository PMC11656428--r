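# Ungapped X-drop extension of seed pairs into maximal homologous segment
# pairs.  The model is substitution-only (no indels): both intervals of a pair
# always have equal length, and the method stays alignment-free.
#
# Scoring: +1 per match, -2 per mismatch.  Each direction extends until the
# running score falls `xdrop` below its running maximum, or a sequence end or
# an N is reached; the extension endpoint is the position of the running
# maximum (the first position attaining it, so a tie resolves to the shorter
# extension).  At +1/-2, sequence stretches below ~2/3 identity cannot grow
# the score, which is consonant with the 60% homology floor.

#' Extension parameters
#'
#' @param match_score score per matching position (default +1).
#' @param mismatch_score score per mismatching position (default -2).
#' @param xdrop stop a direction once the running score drops this far below
#'   its running maximum (default 10, must be > 0).
#' @param homology_floor minimum identity of a reported pair (default 0.60).
#' @return list of class `extend_params`.
#' @export
extend_params <- function(match_score = 1L, mismatch_score = -2L,
                          xdrop = 10L, homology_floor = 0.60) {
  stopifnot(xdrop > 0, homology_floor > 0, homology_floor <= 1,
            match_score > 0, mismatch_score < 0)
  structure(list(match_score = as.integer(match_score),
                 mismatch_score = as.integer(mismatch_score),
                 xdrop = as.integer(xdrop),
                 homology_floor = homology_floor),
            class = "extend_params")
}

# X-drop walk over a logical match vector (NA = hard stop at N).
# Returns c(steps, matches): number of positions taken and matches among them.
.xdrop_walk <- function(m, params) {
  n <- length(m)
  if (n == 0L) return(c(0L, 0L))
  .xdrop_walk_lazy(function(from, to) m[from:to], n, params)
}

# Same walk, but the match vector is produced chunk-wise on demand so that a
# huge admissible range (e.g. the whole gap between two distant copies) costs
# only as much as the walk actually travels before the X-drop stop.
.xdrop_walk_lazy <- function(make_chunk, total_max, params, chunk = 1024L) {
  if (total_max <= 0L) return(c(0L, 0L))
  cs <- 0L; rmax <- 0L
  best_score <- 0L; best_t <- 0L
  done <- 0L
  while (done < total_max) {
    hi <- min(total_max, done + chunk)
    m <- make_chunk(done + 1L, hi)
    trunc <- FALSE
    firstNA <- which(is.na(m))[1L]
    if (!is.na(firstNA)) {
      m <- if (firstNA == 1L) logical(0) else m[seq_len(firstNA - 1L)]
      trunc <- TRUE
    }
    if (length(m) > 0L) {
      sc <- cs + cumsum(ifelse(m, params$match_score, params$mismatch_score))
      rm_vec <- cummax(c(rmax, sc))[-1L]
      stop_i <- which(rm_vec - sc >= params$xdrop)[1L]
      lim <- if (is.na(stop_i)) length(sc) else stop_i
      local_best <- which.max(sc[seq_len(lim)])
      if (sc[local_best] > best_score) {
        best_score <- sc[local_best]
        best_t <- done + local_best
      }
      cs <- sc[lim]
      rmax <- rm_vec[lim]
      done <- done + lim
      if (!is.na(stop_i)) break
    }
    if (trunc) break
  }
  if (best_score <= 0L) return(c(0L, 0L))
  matches <- (best_score - best_t * params$mismatch_score) %/%
    (params$match_score - params$mismatch_score)
  c(best_t, matches)
}

.match_vec <- function(x, y) {
  m <- x == y
  m[x == 0L | y == 0L] <- NA  # N stops extension
  m
}

#' Extend one seed pair to its maximal homologous segment pair
#'
#' Greedy ungapped X-drop extension leftward and rightward from the seed.  For
#' forward pairs the two intervals advance together on the same strand and are
#' not allowed to cross (`interval_a` must end at or before `interval_b`
#' starts; the left direction is extended first when the gap between the
#' copies limits the total).  For inverted pairs, rightward extension of the
#' first interval corresponds to leftward growth of the second (coordinates
#' mirrored through the reverse complement) and extension stops before the two
#' intervals would cross their common centre.
#'
#' @param record a [seq_record()].
#' @param pos_a,pos_b 0-based window starts of the seed, `pos_a <= pos_b`.
#' @param orientation "forward" or "inverted".
#' @param k seed length.
#' @param params an [extend_params()] list.
#' @param enc optional pre-computed [encode_dna()] vector of the record.
#' @return one-row data.frame with columns `a_start`, `a_end`, `b_start`,
#'   `b_end` (0-based half-open), `orientation`, `matches`, `aligned_length`,
#'   `identity`; or `NULL` if the final identity falls below the homology
#'   floor.
#' @export
extend_pair <- function(record, pos_a, pos_b, orientation = "forward",
                        k, params = extend_params(), enc = NULL) {
  if (is.null(enc)) enc <- encode_dna(record$residues)
  L <- length(enc)
  a <- as.integer(pos_a); b <- as.integer(pos_b); k <- as.integer(k)
  stopifnot(a >= 0L, b >= a, b + k <= L)

  if (orientation == "forward") {
    gap <- b - a - k                     # bases between a's end and b's start
    nl <- max(0L, min(a, gap))
    lw <- .xdrop_walk_lazy(function(lo, hi)
      .match_vec(enc[(a + 1L) - (lo:hi)], enc[(b + 1L) - (lo:hi)]),
      nl, params)
    nr <- max(0L, min(L - (a + k), L - (b + k), gap - lw[1L]))
    rw <- .xdrop_walk_lazy(function(lo, hi)
      .match_vec(enc[(a + k) + (lo:hi)], enc[(b + k) + (lo:hi)]),
      nr, params)
    a_start <- a - lw[1L]; a_end <- a + k + rw[1L]
    b_start <- b - lw[1L]; b_end <- b + k + rw[1L]
  } else {
    # pairing: position i in interval_a matches complement of position
    # S - i in interval_b, with S = pos_a + pos_b + k - 1 (anti-diagonal)
    comp <- .dna_comp_code[enc + 1L]
    # a rightward / b leftward: i = a+k-1+t pairs with j = b-t; require j > i
    nr <- max(0L, min(L - (a + k), (b - a - k) %/% 2L))
    rw <- .xdrop_walk_lazy(function(lo, hi)
      .match_vec(enc[(a + k) + (lo:hi)], comp[(b + 1L) - (lo:hi)]),
      nr, params)
    # a leftward / b rightward: i = a-t pairs with j = b+k-1+t
    nl <- max(0L, min(a, L - (b + k)))
    lw <- .xdrop_walk_lazy(function(lo, hi)
      .match_vec(enc[(a + 1L) - (lo:hi)], comp[(b + k) + (lo:hi)]),
      nl, params)
    a_start <- a - lw[1L]; a_end <- a + k + rw[1L]
    b_start <- b - rw[1L]; b_end <- b + k + lw[1L]
  }

  aligned <- a_end - a_start
  matches <- k + lw[2L] + rw[2L]
  identity <- matches / aligned
  if (identity < params$homology_floor) return(NULL)
  data.frame(a_start = a_start, a_end = a_end,
             b_start = b_start, b_end = b_end,
             orientation = orientation,
             matches = matches, aligned_length = aligned,
             identity = identity,
             stringsAsFactors = FALSE)
}

#' Extend a whole table of seed pairs
#'
#' Applies [extend_pair()] to every seed, with one sound shortcut: a seed whose
#' window (on the a-side) is contained in an already-accepted pair with
#' identity 1.0 on the same (anti-)diagonal is skipped, because a fully exact
#' covering pair forces the identical extension result for any interior seed.
#'
#' @param record a [seq_record()].
#' @param seeds data.frame from [enumerate_seed_pairs()].
#' @param params an [extend_params()] list.
#' @return data.frame of extended pairs (possibly with duplicate footprints;
#'   see [dedupe_pairs()]).
#' @export
extend_seed_pairs <- function(record, seeds, params = extend_params()) {
  enc <- encode_dna(record$residues)
  if (nrow(seeds) == 0L) {
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      orientation = character(0), matches = integer(0),
                      aligned_length = integer(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  covered <- new.env(parent = emptyenv())  # diag key -> matrix of exact spans
  out <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    a <- seeds$pos_a[i]; b <- seeds$pos_b[i]
    ori <- seeds$orientation[i]; k <- seeds$k[i]
    key <- if (ori == "forward") paste0("f", b - a)
           else paste0("i", a + b + k - 1L)
    spans <- covered[[key]]
    if (!is.null(spans) &&
        any(spans[, 1L] <= a & a + k <= spans[, 2L])) next
    p <- extend_pair(record, a, b, ori, k, params, enc = enc)
    if (is.null(p)) next
    out[[i]] <- p
    if (p$identity == 1) {
      covered[[key]] <- rbind(spans, c(p$a_start, p$a_end))
    }
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) return(extend_seed_pairs(record, seeds[0, ], params))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove contained and duplicate segment pairs
#'
#' A pair whose two intervals are both contained within another pair's
#' intervals (same orientation) is dropped; among identical footprints exactly
#' one survives.  Output is sorted by (`a_start`, `b_start`).
#'
#' @param pairs data.frame of extended pairs.
#' @return deduplicated, sorted data.frame.
#' @export
dedupe_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  pairs <- pairs[!duplicated(pairs[, c("a_start", "a_end", "b_start",
                                       "b_end", "orientation")]), ,
                 drop = FALSE]
  # sort so potential containers come first: wider a-interval wins ties
  ord <- order(pairs$a_start, -pairs$a_end, pairs$b_start, -pairs$b_end)
  pairs <- pairs[ord, , drop = FALSE]
  n <- nrow(pairs)
  keep <- logical(n)
  ka_s <- integer(0); ka_e <- integer(0)
  kb_s <- integer(0); kb_e <- integer(0); kor <- character(0)
  for (i in seq_len(n)) {
    contained <- any(kor == pairs$orientation[i] &
                     ka_s <= pairs$a_start[i] & pairs$a_end[i] <= ka_e &
                     kb_s <= pairs$b_start[i] & pairs$b_end[i] <= kb_e)
    if (!contained) {
      keep[i] <- TRUE
      ka_s <- c(ka_s, pairs$a_start[i]); ka_e <- c(ka_e, pairs$a_end[i])
      kb_s <- c(kb_s, pairs$b_start[i]); kb_e <- c(kb_e, pairs$b_end[i])
      kor <- c(kor, pairs$orientation[i])
    }
  }
  res <- pairs[keep, , drop = FALSE]
  res <- res[order(res$a_start, res$b_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
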