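# Result serialisation: GFF3 of clustered repeat blocks, TSV coverage
# summary, and the per-cluster repeat-profile PNG (one cluster per row, blue
# forward / red inverted).

#' Assemble a repeat report for one sequence
#'
#' @param record the analysed [seq_record()].
#' @param blocks block table from [merge_blocks()].
#' @param clusters list of `repeat_cluster` objects.
#' @param tandem tandem annotation table from [scan_low_complexity()].
#' @param pairs deduplicated segment-pair table.
#' @param config the [scan_config()] used.
#' @return object of class `repeat_report`.
#' @export
repeat_report <- function(record, blocks, clusters, tandem, pairs, config) {
  structure(list(record_id = record$id,
                 description = record$description,
                 sequence_length = record$length,
                 blocks = blocks,
                 clusters = clusters,
                 tandem = tandem,
                 pairs = pairs,
                 coverage_percent = coverage_fraction(blocks, record$length),
                 params = config),
            class = "repeat_report")
}

#' @export
print.repeat_report <- function(x, ...) {
  cat(sprintf(
    "<repeat_report> %s (%d bp): %d block(s), %d cluster(s), %d tandem annotation(s), %.2f%% covered\n",
    x$record_id, x$sequence_length, nrow(x$blocks), length(x$clusters),
    nrow(x$tandem), x$coverage_percent))
  invisible(x)
}

.gff_feature_type <- function(orientation, arrangement) {
  if (orientation == "inverted") return("inverted_repeat")
  if (arrangement %in% c("tandem_array", "higher_order")) return("tandem_repeat")
  "dispersed_repeat"
}

.tandem_feature_type <- function(category) {
  switch(category,
         microsatellite = "microsatellite",
         telomeric = "telomeric_repeat",
         "tandem_repeat")
}

#' Write a repeat report as GFF3
#'
#' One feature line per cluster member plus one per tandem annotation,
#' 9 tab-delimited columns, `##gff-version 3` header.  Internal 0-based
#' half-open intervals `[s, e)` become 1-based inclusive `s+1 .. e` here and
#' only here.  Strand is `+` for forward members, `-` for inverted; score is
#' the member similarity to its cluster representative (tandem annotations
#' carry their purity).  Attributes: `ID=rpt<n>;Cluster=<cid>;Group=<gid>`
#' with `Motif=<m>` on tandem features.
#'
#' @param report a [repeat_report()].
#' @param path output path.
#' @param source_name value of the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff <- function(report, path, source_name = "repeatscan") {
  rows <- list()
  blocks <- report$blocks
  for (cl in report$clusters) {
    arrangement <- classify_cluster_arrangement(cl, blocks, report$pairs)
    for (mi in seq_len(nrow(cl$members))) {
      b <- blocks[match(cl$members$block_id[mi], blocks$id), ]
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = report$record_id, source = source_name,
        type = .gff_feature_type(cl$members$orientation[mi], arrangement),
        start = b$start + 1L, end = b$end,
        score = sprintf("%.3f", cl$members$similarity[mi]),
        strand = if (cl$members$orientation[mi] == "inverted") "-" else "+",
        phase = ".",
        attr_tail = sprintf("Cluster=%d;Group=%d", cl$id, cl$group),
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(report$tandem) > 0L) {
    for (ti in seq_len(nrow(report$tandem))) {
      tr <- report$tandem[ti, ]
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = report$record_id, source = source_name,
        type = .tandem_feature_type(tr$category),
        start = tr$start + 1L, end = tr$end,
        score = sprintf("%.3f", tr$purity), strand = "+", phase = ".",
        attr_tail = sprintf("Motif=%s", tr$motif),
        stringsAsFactors = FALSE)
    }
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop(sprintf(
                    "I/O error opening '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(rows) > 0L) {
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$start, tab$end), , drop = FALSE]
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\tID=rpt%d;%s",
                     tab$seqid, tab$source, tab$type, tab$start, tab$end,
                     tab$score, tab$strand, tab$phase,
                     seq_len(nrow(tab)), tab$attr_tail)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write the per-record coverage summary
#'
#' Tab-separated with header: record id, length, number of blocks, number of
#' clusters, coverage percent (2 decimals), parameter string.  Accepts one
#' report or a list of reports (one row each, input order).
#'
#' @param reports a [repeat_report()] or list thereof.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(reports, path) {
  if (inherits(reports, "repeat_report")) reports <- list(reports)
  rows <- vapply(reports, function(r) {
    cfg <- r$params
    par <- sprintf("k=%d;initial=%d;min=%d;quick=%s",
                   cfg$kmer, cfg$initial_length, cfg$min_length,
                   tolower(as.character(cfg$quick)))
    sprintf("%s\t%d\t%d\t%d\t%.2f\t%s",
            r$record_id, r$sequence_length, nrow(r$blocks),
            length(r$clusters), r$coverage_percent, par)
  }, character(1L))
  writeLines(c("record\tlength\tblocks\tclusters\tcoverage_percent\tparams",
               rows), path)
  invisible(path)
}

#' Render the repeat-profile image
#'
#' One cluster per row in id order below a coordinate scale bar; every member
#' is drawn as a filled rectangle over its scaled interval -- pure blue
#' (0,0,255) for forward orientation, pure red (255,0,0) for inverted --
#' on a white background, minimum drawn width 1 px.
#'
#' @param report a [repeat_report()].
#' @param path output PNG path.
#' @param width_px image width in pixels (>= 100).
#' @param row_px height of each cluster row (default 8).
#' @return `path`, invisibly.
#' @export
render_profile <- function(report, path, width_px = 1024L, row_px = 8L) {
  stopifnot(width_px >= 100L)
  width_px <- as.integer(width_px); row_px <- as.integer(row_px)
  scale_h <- 12L
  n_cl <- length(report$clusters)
  h <- scale_h + max(1L, n_cl) * row_px
  img <- array(1, dim = c(h, width_px, 3L))  # white
  L <- max(1L, report$sequence_length)

  # scale bar: axis line plus ticks every ~1/10 of the sequence
  img[scale_h - 2L, , ] <- 0
  for (f in seq(0, 1, by = 0.1)) {
    x <- min(width_px, max(1L, 1L + as.integer(floor(f * (width_px - 1L)))))
    img[(scale_h - 6L):(scale_h - 2L), x, ] <- 0
  }

  blocks <- report$blocks
  for (ci in seq_along(report$clusters)) {
    cl <- report$clusters[[ci]]
    y0 <- scale_h + (ci - 1L) * row_px + 2L
    y1 <- scale_h + ci * row_px - 1L
    for (mi in seq_len(nrow(cl$members))) {
      b <- blocks[match(cl$members$block_id[mi], blocks$id), ]
      x0 <- 1L + as.integer(floor(b$start / L * width_px))
      x1 <- as.integer(ceiling(b$end / L * width_px))
      x0 <- min(max(x0, 1L), width_px)
      x1 <- min(max(x1, x0), width_px)  # minimum width 1 px
      col <- if (cl$members$orientation[mi] == "inverted")
        c(1, 0, 0) else c(0, 0, 1)
      for (ch in 1:3) img[y0:y1, x0:x1, ch] <- col[ch]
    }
  }
  png::writePNG(img, target = path)
  invisible(path)
}
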