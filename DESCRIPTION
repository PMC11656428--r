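Package: repeatscan
Title: De Novo Detection, Clustering and Visualisation of Genomic Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Alignment-free de novo discovery of repeated sequences in DNA.
    Exact k-mer seeds shared between two loci (on the same strand or between a
    locus and the reverse complement of another) are extended to maximal
    ungapped homologous segment pairs under an X-drop rule that tolerates
    nucleotide substitutions. Segment pairs are projected onto the genome,
    merged into boundary-defined repeat blocks, length-filtered, and grouped
    into clusters of homologous blocks either transitively ("quick" mode) or
    per homology relationship ("profile" mode). Perfect and imperfect
    microsatellites, telomere-like motifs and tandem arrays are annotated by
    periodicity analysis. Results are written as a soft-masked FASTA, a GFF3
    table of clustered repeat blocks, a coverage summary and a per-cluster
    repeat-profile PNG. A deterministic synthetic-genome generator with planted
    repeats supports benchmarking against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
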