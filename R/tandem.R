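# Low-complexity and tandem structure: perfect and imperfect microsatellites
# (unit 2-6 bp), telomere-like motifs (unit 5-10 bp), longer tandem arrays and
# higher-order ("repeat within repeat") arrangements.
#
# Periodicity is measured by autocorrelation identity: A(p) is the fraction of
# positions i with s[i] == s[i+p].  The genome-wide scanner locates candidate
# arrays directly from per-period match runs, which finds short arrays that no
# global k-mer frequency statistic would flag, then validates each candidate
# against the periodic extrapolation of its consensus motif.

# default telomere-like motif list; rotations and reverse complements of these
# are recognised too
.default_telomere_motifs <- c("TTAGGG", "TTTAGGG", "TTAGG")

#' Canonical cyclic rotation of a motif
#'
#' Lexicographically smallest rotation of the strand as written; gives every
#' phase of one array the same reported motif.
#'
#' @param motif DNA string.
#' @return canonical rotation.
#' @export
canonical_motif <- function(motif) {
  n <- nchar(motif)
  if (n <= 1L) return(motif)
  dbl <- paste0(motif, motif)
  rots <- substring(dbl, seq_len(n), seq_len(n) + n - 1L)
  min(rots)
}

# smallest q (dividing p) such that the motif is q-periodic
.min_cyclic_period <- function(motif) {
  p <- nchar(motif)
  for (q in seq_len(p - 1L)) {
    if (p %% q == 0L && motif == strrep(substr(motif, 1L, q), p %/% q))
      return(q)
  }
  p
}

.telomere_set <- function(motifs = .default_telomere_motifs) {
  all <- unlist(lapply(motifs, function(m) c(m, revcomp(m))))
  unique(vapply(all, canonical_motif, character(1L), USE.NAMES = FALSE))
}

#' Detect the dominant short periodicity of a window
#'
#' For each candidate period p in 1..`max_unit`, the autocorrelation identity
#' `A(p) = #\{i : s[i] == s[i+p]\} / (len - p)` is computed; the smallest p
#' with `A(p) >= purity_floor` is selected.  The motif is the most frequent
#' full-period chunk (reported in canonical rotation).  Period 1
#' (homopolymer) qualifies only for windows of length >= 8.
#'
#' @param window DNA string, length >= 4.
#' @param max_unit largest period considered (default 10).
#' @param purity_floor minimum `A(p)` (default 0.8).
#' @return list with `unit_length`, `motif` (canonical rotation), `purity`
#'   (= `A(p)`), or `NULL` if no period qualifies.
#' @export
detect_periodicity <- function(window, max_unit = 10L, purity_floor = 0.8) {
  n <- nchar(window)
  if (n < 4L) return(NULL)
  enc <- encode_dna(window)
  for (p in seq_len(min(max_unit, n - 1L))) {
    if (p == 1L && n < 8L) next
    if (n < 2L * p) break
    m <- enc[seq_len(n - p)] == enc[seq_len(n - p) + p] &
      enc[seq_len(n - p)] != 0L
    a <- mean(m)
    if (a >= purity_floor) {
      chunk_starts <- seq.int(1L, n - p + 1L, by = p)
      chunks <- substring(window, chunk_starts, chunk_starts + p - 1L)
      motif <- names(sort(table(chunks), decreasing = TRUE))[1L]
      # a motif that is itself periodic (e.g. "AA") belongs to the smaller
      # period, which was already considered and rejected
      if (.min_cyclic_period(motif) < p) next
      return(list(unit_length = p, motif = canonical_motif(motif),
                  purity = a))
    }
  }
  NULL
}

# fraction of positions matching the cyclic extrapolation of `motif` laid down
# from the interval start
.extrapolation_purity <- function(seq_enc, start0, end0, motif) {
  len <- end0 - start0
  p <- nchar(motif)
  menc <- encode_dna(motif)
  tiled <- rep_len(menc, len)
  mean(seq_enc[(start0 + 1L):end0] == tiled)
}

# consensus motif of a region under period p (per-phase majority base)
.consensus_motif <- function(seq_enc, start0, end0, p) {
  len <- end0 - start0
  idx <- (start0 + 1L):end0
  phase <- ((idx - start0 - 1L) %% p) + 1L
  bases <- c("A", "C", "G", "T")
  motif <- vapply(seq_len(p), function(ph) {
    v <- seq_enc[idx[phase == ph]]
    v <- v[v != 0L]
    if (length(v) == 0L) return("N")
    bases[as.integer(names(sort(table(v), decreasing = TRUE))[1L])]
  }, character(1L))
  paste(motif, collapse = "")
}

.empty_tandem_frame <- function() {
  .annotation_row(integer(0), integer(0), character(0), integer(0),
                  numeric(0), character(0))
}

.annotation_row <- function(start, end, motif, unit, purity, category) {
  data.frame(start = start, end = end, motif = motif, unit_length = unit,
             copy_number = (end - start) / unit, purity = purity,
             category = category, stringsAsFactors = FALSE)
}

.categorise_unit <- function(motif, unit, telomeres) {
  canon <- canonical_motif(motif)
  canon_rc <- canonical_motif(revcomp(motif))
  if (unit >= 5L && unit <= 10L &&
      (canon %in% telomeres || canon_rc %in% telomeres)) return("telomeric")
  if (unit <= 6L) return("microsatellite")
  "tandem_array"
}

#' Scan a sequence for low-complexity / short-period tandem arrays
#'
#' For each period p in 1..`max_unit`, positions where the sequence equals
#' itself shifted by p are computed in one vector pass; runs of such matches
#' (allowing short interruptions from substitutions) delimit candidate
#' arrays.  Each candidate is validated against the cyclic extrapolation of
#' its per-phase consensus motif and kept when that purity reaches
#' `purity_floor`, the array holds at least four copies of its unit (eight
#' bases for homopolymers), keeping chance two-copy matches in random
#' sequence out of the annotation.  Smaller periods take precedence where candidates of
#' different periods overlap; abutting annotations with the same canonical
#' motif are merged.  Neighbourhoods of high-frequency k-mers (from the
#' occurrence cap of the seed enumerator) are folded into the candidate set.
#'
#' @param record a [seq_record()].
#' @param high_freq_kmers optional data.frame (`kmer`, `count`) of capped
#'   k-mers; their occurrence neighbourhoods are scanned as well (the direct
#'   period scan already covers periods up to `max_unit`).
#' @param max_unit largest unit length (default 10).
#' @param purity_floor minimum extrapolation purity (default 0.8).
#' @param telomere_motifs motifs (plus rotations/complements) labelled
#'   telomeric when the unit length is 5-10.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   `motif` (canonical), `unit_length`, `copy_number`, `purity`, `category`.
#' @export
scan_low_complexity <- function(record, high_freq_kmers = NULL,
                                max_unit = 10L, purity_floor = 0.8,
                                telomere_motifs = .default_telomere_motifs) {
  empty <- .empty_tandem_frame()
  L <- record$length
  if (L < 8L) return(empty)
  enc <- encode_dna(record$residues)
  telomeres <- .telomere_set(telomere_motifs)
  # a mismatch costs f/(1-f) so that a segment of purity exactly f scores 0:
  # maximal-scoring extension then enforces the purity floor locally and
  # cannot drift into random flank
  mm_cost <- purity_floor / (1 - purity_floor + 1e-9)
  out <- list()
  for (p in seq_len(min(max_unit, L %/% 2L))) {
    m <- enc[seq_len(L - p)] == enc[seq_len(L - p) + p] &
      enc[seq_len(L - p)] != 0L
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= p)  # >= one extra full period
    if (length(runs) == 0L) next
    # chain runs separated by short interruptions (substitution scars)
    run_s <- starts[runs]; run_e <- ends[runs]
    grp <- cumsum(c(1L, (run_s[-1L] - run_e[-length(run_e)] - 1L) > (2L * p + 4L)))
    for (gi in split(seq_along(runs), grp)) {
      # core: the longest uninterrupted run of the chain (a pure stretch);
      # the consensus motif is read from the core alone
      lead <- gi[which.max(run_e[gi] - run_s[gi])]
      core_s <- run_s[lead] - 1L        # 0-based first array base
      core_e <- run_e[lead] + p         # half-open end
      if (core_e - core_s < 2L * p) next
      motif <- .consensus_motif(enc, core_s, core_e, p)
      if (grepl("N", motif, fixed = TRUE)) next
      if (.min_cyclic_period(motif) < p) next  # smaller period handles it
      # scan window: the whole chain plus a little slack on each side
      win_s <- max(0L, run_s[gi[1L]] - 1L - (2L * p + 8L))
      win_e <- min(L, run_e[gi[length(gi)]] + p + (2L * p + 8L))
      ext <- .max_scoring_extension(enc, core_s, core_e, win_s, win_e,
                                    motif, mm_cost)
      start0 <- ext[1L]; end0 <- ext[2L]
      len <- end0 - start0
      if (len < max(8L, 4L * p)) next
      purity <- .extrapolation_purity(enc, start0, end0,
                                      .phase_motif(motif, core_s, start0))
      if (purity < purity_floor) next
      out[[length(out) + 1L]] <-
        .annotation_row(start0, end0, canonical_motif(motif), p, purity,
                        .categorise_unit(motif, p, telomeres))
    }
  }
  ann <- if (length(out)) do.call(rbind, out) else empty
  ann <- .resolve_period_overlaps(ann)
  ann <- .merge_same_motif(ann, enc, purity_floor)
  rownames(ann) <- NULL
  ann
}

# the motif rotated so that its tiling anchored at `new_start` agrees with
# the tiling anchored at `anchor` (both 0-based sequence positions)
.phase_motif <- function(motif, anchor, new_start) {
  p <- nchar(motif)
  shift <- ((new_start - anchor) %% p + p) %% p
  if (shift == 0L) return(motif)
  paste0(substr(motif, shift + 1L, p), substr(motif, 1L, shift))
}

# grow [core_s, core_e) within [win_s, win_e) to the maximal-scoring interval
# under match +1 / mismatch -mm_cost against the motif tiling anchored at
# core_s; each side stops at its running-maximum position (never shrinks the
# core, never starts or ends on a mismatch)
.max_scoring_extension <- function(enc, core_s, core_e, win_s, win_e,
                                   motif, mm_cost) {
  menc <- encode_dna(motif)
  p <- length(menc)
  tile_at <- function(pos0) menc[((pos0 - core_s) %% p) + 1L]
  # rightward from core_e
  right <- core_e
  if (win_e > core_e) {
    idx <- (core_e + 1L):win_e          # R indices of positions core_e..win_e-1
    mv <- enc[idx] == tile_at(idx - 1L) & enc[idx] != 0L
    sc <- cumsum(ifelse(mv, 1, -mm_cost))
    if (max(sc) > 0) right <- core_e + which.max(sc)
  }
  left <- core_s
  if (core_s > win_s) {
    idx <- core_s:(win_s + 1L)          # R indices of positions core_s-1..win_s
    mv <- enc[idx] == tile_at(idx - 1L) & enc[idx] != 0L
    sc <- cumsum(ifelse(mv, 1, -mm_cost))
    if (max(sc) > 0) left <- core_s - which.max(sc)
  }
  c(left, right)
}

.resolve_period_overlaps <- function(ann) {
  if (nrow(ann) <= 1L) return(ann)
  ann <- ann[order(ann$unit_length, ann$start), , drop = FALSE]
  keep <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    ov <- FALSE
    if (any(keep)) {
      kk <- which(keep)
      inter <- pmin(ann$end[kk], ann$end[i]) - pmax(ann$start[kk], ann$start[i])
      ov <- any(inter > 0.5 * (ann$end[i] - ann$start[i]))
    }
    keep[i] <- !ov
  }
  ann <- ann[keep, , drop = FALSE]
  ann[order(ann$start), , drop = FALSE]
}

.merge_same_motif <- function(ann, enc, purity_floor) {
  if (nrow(ann) <= 1L) return(ann)
  ann <- ann[order(ann$start), , drop = FALSE]
  res <- ann[1L, , drop = FALSE]
  for (i in seq.int(2L, nrow(ann))) {
    last <- nrow(res)
    gap <- ann$start[i] - res$end[last]
    if (ann$motif[i] == res$motif[last] &&
        gap <= ann$unit_length[i]) {
      s <- res$start[last]; e <- ann$end[i]
      p <- res$unit_length[last]
      purity <- .extrapolation_purity(enc, s, e, .consensus_motif(enc, s, e, p))
      if (purity >= purity_floor) {
        res[last, c("start", "end", "copy_number", "purity")] <-
          list(s, e, (e - s) / p, purity)
        next
      }
    }
    res <- rbind(res, ann[i, , drop = FALSE])
  }
  res
}

#' Classify the genomic arrangement of a cluster
#'
#' `tandem_array` when at least two same-orientation members are consecutive
#' with an inter-block gap no larger than `gap_limit` (default half the median
#' member length -- relative, because absolute gaps are meaningless across
#' scales); `higher_order` when such a tandem unit itself contains at least
#' two internal sub-repeats (segment-pair intervals lying strictly inside a
#' member); otherwise `dispersed`.
#'
#' @param cluster a `repeat_cluster`.
#' @param blocks block table the cluster refers to.
#' @param pairs optional segment-pair table used to find internal sub-repeats.
#' @param gap_limit absolute gap limit in bases; `NULL` for the relative
#'   default.
#' @return one of "tandem_array", "higher_order", "dispersed".
#' @export
classify_cluster_arrangement <- function(cluster, blocks, pairs = NULL,
                                         gap_limit = NULL) {
  mem <- cluster$members
  if (nrow(mem) < 2L) return("dispersed")
  b <- blocks[match(mem$block_id, blocks$id), , drop = FALSE]
  ord <- order(b$start)
  b <- b[ord, , drop = FALSE]
  mori <- mem$orientation[ord]
  lens <- b$end - b$start
  if (is.null(gap_limit)) gap_limit <- 0.5 * stats::median(lens)
  gaps <- b$start[-1L] - b$end[-nrow(b)]
  same <- mori[-1L] == mori[-length(mori)]
  tandem <- any(gaps <= gap_limit & same)
  if (!tandem) return("dispersed")
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    for (i in seq_len(nrow(b))) {
      inside_a <- pairs$a_start > b$start[i] & pairs$a_end < b$end[i] &
        (pairs$a_end - pairs$a_start) < (b$end[i] - b$start[i])
      inside_b <- pairs$b_start > b$start[i] & pairs$b_end < b$end[i] &
        (pairs$b_end - pairs$b_start) < (b$end[i] - b$start[i])
      if (sum(inside_a) + sum(inside_b) >= 2L) return("higher_order")
    }
  }
  "tandem_array"
}
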