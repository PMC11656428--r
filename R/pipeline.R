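# End-to-end analysis of one or more sequences: index -> seeds -> extension
# -> filter/merge -> cluster -> tandem scan -> outputs.

#' Run configuration
#'
#' Defaults follow the method's standard settings: k-mer length 12 (floor 5),
#' initial pair length filter 50, minimum repeat block 100, quick clustering,
#' inverted search on, homology floor 60%, periodicity purity floor 0.8.
#' A k-mer under 18 on sequences above 10 Mb triggers a warning (short seeds
#' on large genomes are slow and noisy), but is not refused.
#'
#' @param kmer k-mer seed length (>= 5, default 12).
#' @param initial_length minimum aligned length of a segment pair (default 50).
#' @param min_length minimum merged block length (default 100).
#' @param quick quick (transitive) clustering instead of profile mode?
#' @param search_inverted search the reverse-complement strand?
#' @param homology_floor minimum identity/similarity (default 0.60).
#' @param purity_floor minimum tandem purity (default 0.8).
#' @param occurrence_cap k-mer multiplicity cap for pair enumeration
#'   (default 1000).
#' @param xdrop X-drop threshold for extension (default 10).
#' @param max_unit largest tandem unit scanned (default 10).
#' @param merge_gap block merge gap (default 0).
#' @param telomere_motifs telomere-like motif list.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(kmer = 12L, initial_length = 50L, min_length = 100L,
                        quick = TRUE, search_inverted = TRUE,
                        homology_floor = 0.60, purity_floor = 0.8,
                        occurrence_cap = 1000L, xdrop = 10L,
                        max_unit = 10L, merge_gap = 0L,
                        telomere_motifs = .default_telomere_motifs) {
  kmer <- as.integer(kmer)
  if (is.na(kmer) || kmer < 5L)
    stop("parameter error: k-mer length must be at least 5", call. = FALSE)
  if (homology_floor <= 0 || homology_floor > 1)
    stop("parameter error: homology_floor must be in (0, 1]", call. = FALSE)
  structure(list(kmer = kmer,
                 initial_length = as.integer(initial_length),
                 min_length = as.integer(min_length),
                 quick = isTRUE(quick),
                 search_inverted = isTRUE(search_inverted),
                 homology_floor = homology_floor,
                 purity_floor = purity_floor,
                 occurrence_cap = as.integer(occurrence_cap),
                 xdrop = as.integer(xdrop),
                 max_unit = as.integer(max_unit),
                 merge_gap = as.integer(merge_gap),
                 telomere_motifs = telomere_motifs),
            class = "scan_config")
}

#' Analyse one sequence record
#'
#' Runs the full detection chain on a single [seq_record()].  Sequences
#' shorter than the k-mer length yield an empty report rather than an error,
#' so directory batches do not abort on tiny contigs.
#'
#' @param record a [seq_record()].
#' @param config a [scan_config()].
#' @param verbose log per-stage counts via [message()]?
#' @return a [repeat_report()].
#' @export
scan_sequence <- function(record, config = scan_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (config$kmer < 18L && record$length > 1e7)
    warning(sprintf(
      "k-mer %d is short for a %d bp sequence; 18+ is recommended for large genomes",
      config$kmer, record$length), call. = FALSE)

  eparams <- extend_params(xdrop = config$xdrop,
                           homology_floor = config$homology_floor)
  fparams <- filter_params(initial_string_length = config$initial_length,
                           string_length_filter = config$min_length,
                           merge_gap = config$merge_gap)

  if (record$length < config$kmer) {
    say("%s: shorter than k, empty report", record$id)
    empty_pairs <- extend_seed_pairs(record,
                                     data.frame(pos_a = integer(0),
                                                pos_b = integer(0),
                                                orientation = character(0),
                                                k = integer(0)), eparams)
    return(repeat_report(record, merge_blocks(empty_pairs, record$length,
                                              fparams),
                         list(), .empty_tandem_frame(), empty_pairs, config))
  }

  index <- build_kmer_index(record, config$kmer)
  seeds <- enumerate_seed_pairs(index, record,
                                search_inverted = config$search_inverted,
                                occurrence_cap = config$occurrence_cap)
  say("%s: %d seed pair(s)", record$id, nrow(seeds))
  pairs <- extend_seed_pairs(record, seeds, eparams)
  pairs <- filter_pairs(pairs, fparams)
  pairs <- dedupe_pairs(pairs)
  say("%s: %d segment pair(s) after filtering", record$id, nrow(pairs))
  blocks <- merge_blocks(pairs, record$length, fparams)
  say("%s: %d repeat block(s)", record$id, nrow(blocks))
  clusters <- if (config$quick)
    cluster_quick(blocks, record, pairs, config$kmer, config$homology_floor)
  else
    cluster_profile(blocks, record, pairs, config$kmer, config$homology_floor)
  say("%s: %d cluster(s)", record$id, length(clusters))
  tandem <- scan_low_complexity(record, attr(seeds, "high_freq"),
                                max_unit = config$max_unit,
                                purity_floor = config$purity_floor,
                                telomere_motifs = config$telomere_motifs)
  say("%s: %d tandem annotation(s)", record$id, nrow(tandem))
  repeat_report(record, blocks, clusters, tandem, pairs, config)
}

#' Run the repeat scan over a FASTA file or directory
#'
#' Analyses every record and, when `output_dir` is given, writes per record:
#' `<id>.masked.fasta` (soft-masked sequence), `<id>.gff` (clustered repeat
#' blocks), `<id>.png` (repeat profile) and a shared `summary.tsv`.
#'
#' @param input FASTA file, directory of FASTA files, or a list of
#'   [seq_record()] objects.
#' @param config a [scan_config()].
#' @param output_dir output directory (created if missing); `NULL` for no
#'   file output.
#' @param verbose log per-stage counts?
#' @return list of [repeat_report()] objects, invisibly when writing files.
#' @export
run_repeat_scan <- function(input, config = scan_config(), output_dir = NULL,
                            verbose = FALSE) {
  records <- if (is.character(input)) read_fasta(input)
             else if (inherits(input, "seq_record")) list(input)
             else input
  stopifnot(all(vapply(records, inherits, logical(1L), "seq_record")))
  reports <- lapply(records, scan_sequence, config = config,
                    verbose = verbose)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir))
      dir.create(output_dir, recursive = TRUE)
    for (i in seq_along(reports)) {
      rp <- reports[[i]]
      stem <- file.path(output_dir, gsub("[^A-Za-z0-9._-]", "_", rp$record_id))
      write_masked_fasta(mask_from_blocks(records[[i]], rp$blocks),
                         paste0(stem, ".masked.fasta"))
      write_gff(rp, paste0(stem, ".gff"))
      render_profile(rp, paste0(stem, ".png"))
    }
    write_summary(reports, file.path(output_dir, "summary.tsv"))
    return(invisible(reports))
  }
  reports
}
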