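# Deterministic synthetic-genome generator with planted repeats and known
# ground truth, plus detection scoring.  Backgrounds are uniform i.i.d. over
# A/C/G/T; divergence is substitution-only (no indels), matching the ungapped
# extension model.

#' Describe one repeat family to plant
#'
#' @param family_id integer or string naming the family.
#' @param unit either a DNA string (the ancestral unit) or an integer length
#'   (a random unit of that length is drawn).
#' @param copies number of copies to plant (>= 1).
#' @param orientations vector of "forward"/"inverted", recycled to `copies`.
#' @param divergence per-copy substitution rate in \[0, 0.4\]; each copy is
#'   independently mutated from the ancestral unit, so the expected pairwise
#'   identity of two copies is `(1-d)^2 + d^2/3`.
#' @param arrangement "dispersed" (random well-separated positions), "tandem"
#'   (consecutive copies separated by `spacer` bases), or
#'   `list(nested_in = <family_id>)` to embed this family's copies inside the
#'   host family's ancestral unit.
#' @param spacer gap between tandem copies (default 0).
#' @return list of class `plant_spec`.
#' @export
plant_spec <- function(family_id, unit, copies = 2L,
                       orientations = "forward", divergence = 0,
                       arrangement = "dispersed", spacer = 0L) {
  stopifnot(copies >= 1L, divergence >= 0, divergence <= 0.4)
  structure(list(family_id = family_id, unit = unit,
                 copies = as.integer(copies),
                 orientations = rep_len(orientations, copies),
                 divergence = divergence, arrangement = arrangement,
                 spacer = as.integer(spacer)),
            class = "plant_spec")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_dna <- function(s, d) {
  if (d <= 0) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(v)) < d & v != "N")
  if (length(hit) > 0L) {
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  }
  paste(v, collapse = "")
}

#' Generate a synthetic genome with planted repeats
#'
#' Background sequence is drawn uniformly from A/C/G/T with the given seed;
#' repeat copies are mutated independently from each family's ancestral unit
#' and written at randomised positions that keep at least `min_gap` background
#' bases between planted elements (tandem arrangements keep their copies
#' consecutive; nested families are embedded inside their host's unit before
#' the host is planted).  The same seed always reproduces the same genome and
#' truth table.
#'
#' @param specs list of [plant_spec()] objects.
#' @param genome_length total genome length; `NULL` sizes the genome to hold
#'   the planted material plus `flank_length` background per element.
#' @param seed integer RNG seed.
#' @param flank_length background per planted element when `genome_length` is
#'   `NULL` (default 1000).
#' @param min_gap minimum background distance between planted elements
#'   (default 300).
#' @return list with `record` (a [seq_record()]) and `truth`, a data.frame
#'   (`family`, `copy`, `start`, `end`, `orientation`) in 0-based half-open
#'   coordinates.
#' @export
generate_genome <- function(specs, genome_length = NULL, seed = 1L,
                            flank_length = 1000L, min_gap = 300L) {
  stopifnot(all(vapply(specs, inherits, logical(1L), "plant_spec")))
  set.seed(seed)

  # resolve ancestral units (nested families are embedded in their hosts)
  ids <- vapply(specs, function(s) as.character(s$family_id), character(1L))
  units <- setNames(vector("list", length(specs)), ids)
  for (i in seq_along(specs)) {
    u <- specs[[i]]$unit
    units[[i]] <- if (is.character(u)) normalize_residues(u)
                  else .random_dna(as.integer(u))
  }
  nested_offsets <- list()
  for (i in seq_along(specs)) {
    arr <- specs[[i]]$arrangement
    if (is.list(arr) && !is.null(arr$nested_in)) {
      host <- as.character(arr$nested_in)
      if (!host %in% ids) stop("generation error: unknown host family ",
                               host, call. = FALSE)
      hu <- units[[host]]
      su <- units[[i]]
      need <- specs[[i]]$copies * (nchar(su) + 10L)
      if (need + 20L > nchar(hu))
        stop("generation error: nested family does not fit in host unit",
             call. = FALSE)
      # embed copies at evenly spread offsets inside the host unit
      offs <- integer(specs[[i]]$copies)
      slot <- (nchar(hu) - 10L) %/% specs[[i]]$copies
      for (ci in seq_len(specs[[i]]$copies)) {
        off <- (ci - 1L) * slot + 5L
        sub <- if (specs[[i]]$orientations[ci] == "inverted") revcomp(su)
               else su
        substr(hu, off + 1L, off + nchar(su)) <- sub
        offs[ci] <- off
      }
      units[[host]] <- hu
      nested_offsets[[ids[i]]] <- offs
    }
  }

  top <- which(vapply(specs, function(s) !is.list(s$arrangement),
                      logical(1L)))
  # per planted element (a dispersed copy, or a whole tandem array)
  elements <- list()
  for (i in top) {
    sp <- specs[[i]]
    u <- units[[ids[i]]]
    if (identical(sp$arrangement, "tandem")) {
      copies <- character(sp$copies)
      for (ci in seq_len(sp$copies)) {
        cp <- .mutate_dna(u, sp$divergence)
        if (sp$orientations[ci] == "inverted") cp <- revcomp(cp)
        copies[ci] <- cp
      }
      spacers <- replicate(sp$copies - 1L, .random_dna(sp$spacer))
      seqtxt <- paste0(copies[1L],
                       paste0(spacers, copies[-1L], collapse = ""))
      elements[[length(elements) + 1L]] <-
        list(family = ids[i], seq = seqtxt, tandem = TRUE,
             copy_len = nchar(u), spacer = sp$spacer,
             orientations = sp$orientations)
    } else {
      for (ci in seq_len(sp$copies)) {
        cp <- .mutate_dna(u, sp$divergence)
        if (sp$orientations[ci] == "inverted") cp <- revcomp(cp)
        elements[[length(elements) + 1L]] <-
          list(family = ids[i], seq = cp, tandem = FALSE,
               copy_len = nchar(cp), spacer = 0L,
               orientations = sp$orientations[ci])
      }
    }
  }

  total_planted <- sum(vapply(elements, function(e) nchar(e$seq), numeric(1L)))
  if (is.null(genome_length))
    genome_length <- as.integer(total_planted +
                                flank_length * (length(elements) + 1L))
  if (total_planted + min_gap * (length(elements) + 1L) > genome_length)
    stop("generation error: planted material does not fit the genome length",
         call. = FALSE)

  genome <- .random_dna(genome_length)
  # place elements left to right with randomised gaps >= min_gap
  lens <- vapply(elements, function(e) nchar(e$seq), integer(1L))
  slack <- genome_length - sum(lens) - min_gap * (length(elements) + 1L)
  extra <- if (length(elements) > 0L) {
    w <- stats::runif(length(elements) + 1L)
    floor(slack * w / sum(w))
  } else numeric(0)
  truth <- list()
  cursor <- 0L
  copy_counter <- new.env(parent = emptyenv())
  for (e in seq_along(elements)) {
    el <- elements[[e]]
    cursor <- cursor + min_gap + as.integer(extra[e])
    start <- cursor
    substr(genome, start + 1L, start + nchar(el$seq)) <- el$seq
    if (el$tandem) {
      step <- el$copy_len + el$spacer
      for (ci in seq_along(el$orientations)) {
        s <- start + (ci - 1L) * step
        cnt <- (get0(el$family, copy_counter, ifnotfound = 0L)) + 1L
        assign(el$family, cnt, copy_counter)
        truth[[length(truth) + 1L]] <-
          data.frame(family = el$family, copy = cnt, start = s,
                     end = s + el$copy_len,
                     orientation = el$orientations[ci],
                     stringsAsFactors = FALSE)
      }
    } else {
      cnt <- (get0(el$family, copy_counter, ifnotfound = 0L)) + 1L
      assign(el$family, cnt, copy_counter)
      truth[[length(truth) + 1L]] <-
        data.frame(family = el$family, copy = cnt, start = start,
                   end = start + nchar(el$seq),
                   orientation = el$orientations,
                   stringsAsFactors = FALSE)
    }
    cursor <- cursor + nchar(el$seq)
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(family = character(0), copy = integer(0),
                           start = integer(0), end = integer(0),
                           orientation = character(0),
                           stringsAsFactors = FALSE)

  # nested families: record their positions inside every host copy
  for (nid in names(nested_offsets)) {
    host <- as.character(specs[[match(nid, ids)]]$arrangement$nested_in)
    sub_len <- nchar(units[[nid]])
    hrows <- which(truth$family == host)
    for (hr in hrows) {
      for (off in nested_offsets[[nid]]) {
        pos <- if (truth$orientation[hr] == "forward")
          truth$start[hr] + off
        else truth$end[hr] - off - sub_len
        cnt <- (get0(nid, copy_counter, ifnotfound = 0L)) + 1L
        assign(nid, cnt, copy_counter)
        truth <- rbind(truth, data.frame(
          family = nid, copy = cnt, start = pos, end = pos + sub_len,
          orientation = truth$orientation[hr], stringsAsFactors = FALSE))
      }
    }
  }
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(record = seq_record("synthetic", genome), truth = truth)
}

#' Write a ground-truth table as BED-like TSV
#'
#' 0-based half-open, columns chrom/start/end/name/score/strand.
#'
#' @param truth truth data.frame from [generate_genome()].
#' @param record the generated [seq_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, record, path) {
  bed <- data.frame(chrom = record$id, start = truth$start, end = truth$end,
                    name = paste0(truth$family, ".", truth$copy),
                    score = 0L,
                    strand = ifelse(truth$orientation == "forward", "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Score detected blocks against planted truth
#'
#' A planted copy is recovered when some reported block overlaps it
#' reciprocally at `min_reciprocal` (default 80%) of both lengths.  Precision
#' is the fraction of reported blocks that recover some copy; recall the
#' fraction of copies recovered; `boundary_error` the mean absolute endpoint
#' offset (both ends) over recovered copies and their best-matching block.
#'
#' @param truth truth data.frame from [generate_genome()].
#' @param blocks block data.frame from [merge_blocks()] (or a repeat report's
#'   `$blocks`).
#' @param min_reciprocal reciprocal overlap threshold (default 0.8).
#' @return list with `precision`, `recall`, `boundary_error`, `recovered`
#'   (logical per truth row).
#' @export
score_detection <- function(truth, blocks, min_reciprocal = 0.8) {
  nt <- nrow(truth); nb <- nrow(blocks)
  recovered <- rep(FALSE, nt)
  block_hit <- rep(FALSE, nb)
  berr <- rep(NA_real_, nt)
  if (nt > 0L && nb > 0L) {
    for (i in seq_len(nt)) {
      inter <- pmin(truth$end[i], blocks$end) - pmax(truth$start[i], blocks$start)
      rec <- inter >= min_reciprocal * (truth$end[i] - truth$start[i]) &
        inter >= min_reciprocal * (blocks$end - blocks$start)
      if (any(rec)) {
        recovered[i] <- TRUE
        block_hit[rec] <- TRUE
        best <- which(rec)[which.max(inter[rec])]
        berr[i] <- (abs(blocks$start[best] - truth$start[i]) +
                      abs(blocks$end[best] - truth$end[i])) / 2
      }
    }
  }
  list(precision = if (nb == 0L) NA_real_ else mean(block_hit),
       recall = if (nt == 0L) NA_real_ else mean(recovered),
       boundary_error = if (any(recovered)) mean(berr[recovered]) else NA_real_,
       recovered = recovered)
}
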