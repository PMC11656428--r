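# Periodicity detection, microsatellite / telomere annotation, and tandem
# arrangement classification.

test_that("perfect periodicity is detected with purity 1", {
  r <- detect_periodicity(strrep("AC", 10))
  expect_equal(r$unit_length, 2L)
  expect_equal(r$motif, "AC")
  expect_equal(r$purity, 1.0)
})

test_that("autocorrelation purity of an imperfect array is counted exactly", {
  # (ACG) x 7 with substitutions at 0-based offsets 5 and 8: the two scars
  # break offsets {2,5} and {5,8} of the lag-3 comparison, so 15 of the 18
  # comparisons match
  v <- strsplit(strrep("ACG", 7), "")[[1L]]
  v[6] <- "T"; v[9] <- "A"
  r <- detect_periodicity(paste(v, collapse = ""))
  expect_equal(r$unit_length, 3L)
  expect_equal(r$motif, "ACG")
  expect_equal(r$purity, 15 / 18)
})

test_that("a random window yields no periodicity call at floor 0.8", {
  set.seed(77)
  w <- rand_dna(30)
  # independent check that no lag reaches the floor for this fixture
  chars <- strsplit(w, "")[[1L]]
  for (p in 1:10) {
    a <- mean(chars[seq_len(30 - p)] == chars[seq_len(30 - p) + p])
    expect_lt(a, 0.8)
  }
  expect_null(detect_periodicity(w))
})

test_that("homopolymers need at least 8 bases", {
  expect_null(detect_periodicity("AAAAAA"))
  r <- detect_periodicity("AAAAAAAA")
  expect_equal(r$unit_length, 1L)
  expect_equal(r$motif, "A")
})

test_that("periodicity is strand-symmetric up to reverse complement", {
  set.seed(78)
  for (motif in c("AC", "ACG", "AATG", "TTAGGG")) {
    w <- strrep(motif, 8)
    f <- detect_periodicity(w)
    r <- detect_periodicity(revcomp(w))
    expect_equal(r$unit_length, f$unit_length)
    expect_equal(r$purity, f$purity)
    expect_equal(r$motif, canonical_motif(revcomp(f$motif)))
  }
})

test_that("planted perfect arrays of unit 1..10 are recovered exactly", {
  set.seed(79)
  for (p in 1:10) {
    motif <- if (p == 1) "G" else rand_dna(p)
    n <- if (p == 1) 12 else 6
    arr <- strrep(motif, n)
    g <- generate_genome(list(plant_spec("ms", arr, copies = 1L)),
                         genome_length = 2500L, seed = 790 + p)
    tr <- g$truth
    ann <- scan_low_complexity(g$record)
    hit <- ann[ann$unit_length == p & ann$start <= tr$start + 2 &
                 ann$end >= tr$end - 2, , drop = FALSE]
    expect_equal(nrow(hit), 1L, label = paste("unit", p))
    expect_equal(hit$purity, 1.0)
    expect_equal(hit$motif, canonical_motif(motif))
    # boundaries within 2 bp unless the flank happens to continue the motif
    expect_lte(abs(hit$start - tr$start), p + 2)
    expect_lte(abs(hit$end - tr$end), p + 2)
  }
})

test_that("imperfect arrays at 10% substitution keep purity >= 0.8", {
  set.seed(80)
  v <- strsplit(strrep("AC", 40), "")[[1L]]
  at <- sample(seq_along(v), 8)          # 10% of 80 positions
  v[at] <- vapply(v[at], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  g <- generate_genome(list(plant_spec("im", paste(v, collapse = ""),
                                       copies = 1L)),
                       genome_length = 2500L, seed = 80)
  tr <- g$truth
  ann <- scan_low_complexity(g$record)
  hit <- ann[ann$unit_length == 2 & ann$end > tr$start & ann$start < tr$end, ,
             drop = FALSE]
  expect_equal(nrow(hit), 1L)
  expect_gte(hit$purity, 0.8)
  expect_equal(hit$motif, "AC")
  # the annotation covers most of the planted array
  expect_gte(min(hit$end, tr$end) - max(hit$start, tr$start),
             0.8 * (tr$end - tr$start))
})

test_that("telomeric motifs are labelled telomeric, not microsatellite", {
  g <- generate_genome(list(plant_spec("tel", strrep("TTAGGG", 20),
                                       copies = 1L)),
                       genome_length = 2500L, seed = 81)
  ann <- scan_low_complexity(g$record)
  hit <- ann[ann$unit_length == 6, , drop = FALSE]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$category, "telomeric")
  # flanks may continue the motif by a base or two
  expect_gte(hit$copy_number, 20)
  expect_lt(hit$copy_number, 21)
  # the reverse-complement strand is recognised too
  g2 <- generate_genome(list(plant_spec("tel", revcomp(strrep("TTAGGG", 20)),
                                        copies = 1L)),
                        genome_length = 2500L, seed = 82)
  ann2 <- scan_low_complexity(g2$record)
  expect_equal(ann2$category[ann2$unit_length == 6], "telomeric")
})

test_that("cluster arrangements classify as tandem, dispersed, higher order", {
  blocks <- data.frame(id = 1:3,
                       start = c(0L, 210L, 420L),
                       end = c(200L, 410L, 620L),
                       max_identity = 1)
  cl <- structure(list(id = 1L, group = 1L,
                       members = data.frame(block_id = 1:3,
                                            orientation = "forward",
                                            similarity = 1),
                       representative_block_id = 1L),
                  class = "repeat_cluster")
  expect_equal(classify_cluster_arrangement(cl, blocks), "tandem_array")

  far <- blocks; far$start <- c(0L, 50000L, 100000L)
  far$end <- far$start + 200L
  expect_equal(classify_cluster_arrangement(cl, far), "dispersed")

  # tandem whose unit contains two internal sub-repeat intervals
  pairs <- data.frame(a_start = c(20L, 230L), a_end = c(60L, 270L),
                      b_start = c(120L, 330L), b_end = c(160L, 370L),
                      orientation = "forward", matches = 40L,
                      aligned_length = 40L, identity = 1)
  expect_equal(classify_cluster_arrangement(cl, blocks, pairs),
               "higher_order")

  # opposite orientations in alternation do not make a tandem array
  cl$members$orientation <- c("forward", "inverted", "forward")
  expect_equal(classify_cluster_arrangement(cl, blocks), "dispersed")
})
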