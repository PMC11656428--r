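# Grouping homologous repeat blocks into clusters.
#
# Two sources of homology evidence connect blocks: (i) a surviving segment
# pair whose two intervals fall in different blocks (direct evidence from
# seed-and-extend, identity >= the homology floor by construction), and
# (ii) the shared-k-mer similarity between the block sequences.  Quick mode
# takes connected components of this graph (single linkage); profile mode
# emits one cluster per homology relationship, seeded from each source block
# in genomic order, and never merges overlapping clusters.

#' Shared-k-mer similarity between two sequences
#'
#' `|K(x) intersect K(y union rc(y))| / min(|K(x)|, |K(y)|)` where `K(.)` is
#' the set of distinct N-free k-mers.  The min denominator makes a short
#' element embedded in a longer one score high (a containment-style measure),
#' so nested and overlapping blocks read as homologous.  Orientation is
#' forward when the same-strand intersection is at least as large as the
#' reverse-complement intersection.
#'
#' @param x,y DNA strings.
#' @param k k-mer length.
#' @return list with `similarity` (0..1) and `orientation`
#'   ("forward"/"inverted").  Either string shorter than `k` gives
#'   similarity 0.
#' @export
kmer_similarity <- function(x, y, k) {
  if (nchar(x) < k || nchar(y) < k)
    return(list(similarity = 0, orientation = "forward"))
  kx <- .kmer_set(x, k)
  ky <- .kmer_set(y, k)
  kyrc <- .kmer_set(revcomp(y), k)
  if (length(kx) == 0L || length(ky) == 0L)
    return(list(similarity = 0, orientation = "forward"))
  fwd <- sum(kx %in% ky)
  inv <- sum(kx %in% kyrc)
  both <- sum(kx %in% ky | kx %in% kyrc)
  list(similarity = both / min(length(kx), length(ky)),
       orientation = if (fwd >= inv) "forward" else "inverted")
}

.kmer_set <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(character(0))
  km <- substring(s, seq_len(n), seq_len(n) + k - 1L)
  unique(km[!grepl("N", km, fixed = TRUE)])
}

# ---------------------------------------------------------------------------
# homology graph over blocks

# map each pair side to the block with the largest overlap (NA if none)
.side_to_block <- function(starts, ends, blocks) {
  if (nrow(blocks) == 0L || length(starts) == 0L)
    return(rep(NA_integer_, length(starts)))
  side_ir <- IRanges::IRanges(start = starts + 1L, end = pmax(ends, starts + 1L))
  block_ir <- IRanges::IRanges(start = blocks$start + 1L, end = blocks$end)
  hits <- IRanges::findOverlaps(side_ir, block_ir)
  q <- S4Vectors_queryHits(hits); s <- S4Vectors_subjectHits(hits)
  ov <- pmin(ends[q], blocks$end[s]) - pmax(starts[q], blocks$start[s])
  res <- rep(NA_integer_, length(starts))
  ord <- order(q, -ov)
  q <- q[ord]; s <- s[ord]
  first <- !duplicated(q)
  res[q[first]] <- s[first]
  res
}

# edges: data.frame(i, j, orientation, weight), i < j block ids;
# also returns per-block "self" flag (block supported by an internal pair)
.homology_graph <- function(blocks, pairs, record, k, homology_floor) {
  n <- nrow(blocks)
  self_flag <- logical(n)
  edges <- data.frame(i = integer(0), j = integer(0),
                      orientation = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(list(edges = edges, self = self_flag))
  if (nrow(pairs) > 0L) {
    ba <- .side_to_block(pairs$a_start, pairs$a_end, blocks)
    bb <- .side_to_block(pairs$b_start, pairs$b_end, blocks)
    ok <- !is.na(ba) & !is.na(bb)
    same <- ok & ba == bb
    self_flag[unique(ba[same])] <- TRUE
    cross <- ok & ba != bb
    if (any(cross)) {
      edges <- data.frame(i = pmin(ba[cross], bb[cross]),
                          j = pmax(ba[cross], bb[cross]),
                          orientation = pairs$orientation[cross],
                          weight = pairs$identity[cross],
                          stringsAsFactors = FALSE)
    }
  }
  # shared-k-mer edges between all block pairs
  if (n >= 2L) {
    seqs <- substring(record$residues, blocks$start + 1L, blocks$end)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        sim <- kmer_similarity(seqs[i], seqs[j], k)
        if (sim$similarity >= homology_floor) {
          edges <- rbind(edges, data.frame(
            i = i, j = j, orientation = sim$orientation,
            weight = sim$similarity, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (nrow(edges) > 0L) {
    # keep the best-supported orientation/weight per block pair
    edges <- edges[order(edges$i, edges$j, -edges$weight), , drop = FALSE]
    edges <- edges[!duplicated(edges[, c("i", "j")]), , drop = FALSE]
    rownames(edges) <- NULL
  }
  list(edges = edges, self = self_flag)
}

# union-find
.uf_new <- function(n) seq_len(n)
.uf_find <- function(p, x) { while (p[x] != x) x <- p[x]; x }
.uf_union <- function(p, a, b) {
  ra <- .uf_find(p, a); rb <- .uf_find(p, b)
  if (ra != rb) p[max(ra, rb)] <- min(ra, rb)
  p
}

# orientation of each member relative to `rep_id`, propagated over edges
.propagate_orientation <- function(members, rep_id, edges) {
  ori <- setNames(rep(NA_character_, length(members)), members)
  ori[as.character(rep_id)] <- "forward"
  queue <- rep_id
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    inc <- which(edges$i == v | edges$j == v)
    for (e in inc) {
      w <- if (edges$i[e] == v) edges$j[e] else edges$i[e]
      wk <- as.character(w)
      if (!wk %in% names(ori) || !is.na(ori[wk])) next
      flip <- edges$orientation[e] == "inverted"
      vo <- ori[as.character(v)]
      ori[wk] <- if (xor(vo == "inverted", flip)) "inverted" else "forward"
      queue <- c(queue, w)
    }
  }
  ori[is.na(ori)] <- "forward"
  ori
}

# similarity of a member to the representative: direct k-mer similarity, or
# the best edge weight linking it into the cluster when the k-mer measure is
# weaker (diverged copies connected by a segment pair)
.member_similarity <- function(member, rep_id, edges, seqs, k) {
  if (member == rep_id) return(1)
  sim <- kmer_similarity(seqs[member], seqs[rep_id], k)$similarity
  inc <- which(edges$i == member | edges$j == member)
  if (length(inc) > 0L) sim <- max(sim, max(edges$weight[inc]))
  sim
}

.make_cluster <- function(id, member_ids, orientations, sims, rep_id,
                          group = id) {
  structure(list(id = id,
                 members = data.frame(block_id = member_ids,
                                      orientation = orientations,
                                      similarity = sims,
                                      stringsAsFactors = FALSE),
                 representative_block_id = rep_id,
                 group = group),
            class = "repeat_cluster")
}

#' @export
print.repeat_cluster <- function(x, ...) {
  cat(sprintf("<repeat_cluster> id=%d group=%d  %d member(s), rep block %d\n",
              x$id, x$group, nrow(x$members), x$representative_block_id))
  invisible(x)
}

#' Quick-mode clustering (transitive / single linkage)
#'
#' Blocks joined by any homology edge fall into one cluster (connected
#' components).  Reported clusters have at least two members; a singleton
#' survives only when it is internally tandem (supported by a segment pair
#' lying wholly inside the block) -- other singletons are masked but not
#' reported as clusters.  Cluster ids follow the leftmost member coordinate.
#'
#' @param blocks data.frame from [merge_blocks()].
#' @param record the [seq_record()] the blocks lie on.
#' @param pairs data.frame of segment pairs supporting the blocks.
#' @param k k-mer length for the similarity measure.
#' @param homology_floor minimum similarity/identity (default 0.60).
#' @return list of `repeat_cluster` objects (quick-mode clusters partition the
#'   reported blocks).
#' @export
cluster_quick <- function(blocks, record, pairs, k, homology_floor = 0.60) {
  n <- nrow(blocks)
  if (n == 0L) return(list())
  g <- .homology_graph(blocks, pairs, record, k, homology_floor)
  p <- .uf_new(n)
  if (nrow(g$edges) > 0L)
    for (e in seq_len(nrow(g$edges)))
      p <- .uf_union(p, g$edges$i[e], g$edges$j[e])
  roots <- vapply(seq_len(n), function(x) .uf_find(p, x), integer(1L))
  comps <- split(seq_len(n), roots)
  seqs <- substring(record$residues, blocks$start + 1L, blocks$end)

  clusters <- list()
  for (comp in comps) {
    if (length(comp) == 1L && !g$self[comp]) next  # dropped, still masked
    lens <- blocks$end[comp] - blocks$start[comp]
    rep_id <- comp[order(-lens, blocks$start[comp])][1L]
    sub_edges <- g$edges[g$edges$i %in% comp & g$edges$j %in% comp, ,
                         drop = FALSE]
    ori <- .propagate_orientation(comp, rep_id, sub_edges)
    sims <- vapply(comp, .member_similarity, numeric(1L),
                   rep_id = rep_id, edges = sub_edges, seqs = seqs, k = k)
    ord <- order(blocks$start[comp])
    clusters[[length(clusters) + 1L]] <-
      .make_cluster(0L, comp[ord], unname(ori[as.character(comp)][ord]),
                    sims[ord], rep_id)
  }
  .number_clusters(clusters, blocks)
}

#' Profile-mode clustering (per-relationship, no inter-cluster merging)
#'
#' Each block is visited in genomic order as a source; its not-yet-covered
#' homology edges define one cluster (the source plus the blocks those edges
#' reach).  Overlapping clusters are never merged, so one block may appear in
#' several clusters.  When a source has members in both orientations, the
#' forward members and the inverted members are emitted as two linked
#' clusters sharing a group id.
#'
#' @inheritParams cluster_quick
#' @return list of `repeat_cluster` objects; every quick-mode cluster is a
#'   union of profile-mode clusters on the same input.
#' @export
cluster_profile <- function(blocks, record, pairs, k, homology_floor = 0.60) {
  n <- nrow(blocks)
  if (n == 0L) return(list())
  g <- .homology_graph(blocks, pairs, record, k, homology_floor)
  seqs <- substring(record$residues, blocks$start + 1L, blocks$end)
  edges <- g$edges
  used <- rep(FALSE, nrow(edges))
  clusters <- list()
  group <- 0L
  for (src in order(blocks$start)) {
    inc <- which(!used & (edges$i == src | edges$j == src))
    if (length(inc) == 0L) {
      if (g$self[src] && !.block_in_any(src, clusters)) {
        group <- group + 1L
        clusters[[length(clusters) + 1L]] <-
          .make_cluster(0L, src, "forward", 1, src, group = group)
      }
      next
    }
    used[inc] <- TRUE
    nb <- ifelse(edges$i[inc] == src, edges$j[inc], edges$i[inc])
    nb_ori <- edges$orientation[inc]
    nb_sim <- edges$weight[inc]
    # collapse multi-edges to one entry per neighbour (best weight first)
    o <- order(-nb_sim)
    nb <- nb[o]; nb_ori <- nb_ori[o]; nb_sim <- nb_sim[o]
    first <- !duplicated(nb)
    nb <- nb[first]; nb_ori <- nb_ori[first]; nb_sim <- nb_sim[first]

    group <- group + 1L
    fwd <- nb_ori == "forward"
    fwd_ids <- c(src, nb[fwd])
    fwd_oris <- c("forward", nb_ori[fwd])
    fwd_sims <- c(1, nb_sim[fwd])
    ordf <- order(blocks$start[fwd_ids])
    clusters[[length(clusters) + 1L]] <-
      .make_cluster(0L, fwd_ids[ordf], fwd_oris[ordf], fwd_sims[ordf],
                    src, group = group)
    if (any(!fwd)) {
      inv_ids <- nb[!fwd]; inv_sims <- nb_sim[!fwd]
      ordi <- order(blocks$start[inv_ids])
      clusters[[length(clusters) + 1L]] <-
        .make_cluster(0L, inv_ids[ordi], rep("inverted", length(inv_ids)),
                      inv_sims[ordi], src, group = group)
    }
  }
  .number_clusters(clusters, blocks, keep_groups = TRUE)
}

.block_in_any <- function(b, clusters) {
  any(vapply(clusters, function(cl) b %in% cl$members$block_id, logical(1L)))
}

# assign final cluster ids by leftmost member coordinate (stable)
.number_clusters <- function(clusters, blocks, keep_groups = FALSE) {
  if (length(clusters) == 0L) return(clusters)
  leftmost <- vapply(clusters, function(cl)
    min(blocks$start[cl$members$block_id]), numeric(1L))
  ord <- order(leftmost, vapply(clusters, function(cl) cl$group, integer(1L)))
  clusters <- clusters[ord]
  old_groups <- vapply(clusters, function(cl) cl$group, integer(1L))
  new_group <- match(old_groups, unique(old_groups))
  for (i in seq_along(clusters)) {
    clusters[[i]]$id <- i
    clusters[[i]]$group <- if (keep_groups) new_group[i] else i
  }
  clusters
}
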