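# Shared-k-mer similarity and the two clustering regimes.

empty_pairs <- function() {
  data.frame(a_start = integer(0), a_end = integer(0), b_start = integer(0),
             b_end = integer(0), orientation = character(0),
             matches = integer(0), aligned_length = integer(0),
             identity = numeric(0))
}

make_blocks <- function(...) {
  iv <- rbind(...)
  out <- data.frame(id = seq_len(nrow(iv)), start = iv[, 1], end = iv[, 2],
                    max_identity = 1)
  out$pair_idx <- rep(list(integer(0)), nrow(iv))
  out
}

test_that("k-mer similarity matches hand-counted sets and rc symmetry", {
  x <- "ACGTACGTACGTACGT"
  y <- "ACGTACGTACGTTTTT"
  # K(x) = {ACGTACGT, CGTACGTA, GTACGTAC, TACGTACG} (4 distinct), all of
  # which occur in y, so the containment-style score is 4/min(4,8) = 1
  s <- kmer_similarity(x, y, 8L)
  expect_equal(s$similarity, 1.0)
  expect_equal(s$orientation, "forward")

  expect_equal(kmer_similarity(x, x, 8L)$similarity, 1.0)

  set.seed(91)
  z <- rand_dna(60)
  s2 <- kmer_similarity(z, revcomp(z), 10L)
  expect_equal(s2$similarity, 1.0)
  expect_equal(s2$orientation, "inverted")

  expect_equal(kmer_similarity("ACG", z, 10L)$similarity, 0)
})

test_that("quick mode is single linkage; profile mode never merges chains", {
  # A = X+Y, B = Y+Z, C = Z+W with Y, Z the shared halves:
  # sim(A,B) and sim(B,C) clear the floor, sim(A,C) is ~0
  set.seed(51)
  X <- rand_dna(100); Y <- rand_dna(200); Z <- rand_dna(200); W <- rand_dna(100)
  g1 <- rand_dna(150); g2 <- rand_dna(150); g3 <- rand_dna(150)
  s <- paste0(g1, X, Y, g2, Y, Z, g3, Z, W)
  rec <- seq_record("s", s)
  off_a <- 150L; off_b <- 150L + 300L + 150L; off_c <- off_b + 400L + 150L
  blocks <- make_blocks(c(off_a, off_a + 300L),
                        c(off_b, off_b + 400L),
                        c(off_c, off_c + 300L))
  stopifnot(kmer_similarity(substr(s, off_a + 1, off_a + 300),
                            substr(s, off_b + 1, off_b + 400), 12L)$similarity
            >= 0.6)

  quick <- cluster_quick(blocks, rec, empty_pairs(), 12L)
  expect_length(quick, 1L)
  expect_equal(sort(quick[[1]]$members$block_id), 1:3)

  prof <- cluster_profile(blocks, rec, empty_pairs(), 12L)
  memberships <- lapply(prof, function(cl) sort(cl$members$block_id))
  expect_length(prof, 2L)
  expect_true(any(vapply(memberships, identical, logical(1), c(1L, 2L))))
  expect_true(any(vapply(memberships, identical, logical(1), c(2L, 3L))))
  # refinement: the union of profile clusters is the quick cluster
  expect_equal(sort(unique(unlist(memberships))),
               sort(quick[[1]]$members$block_id))
})

test_that("planted families cluster with the planted copy numbers", {
  specs <- list(
    plant_spec("f1", 600L, copies = 3L, orientations = "forward"),
    plant_spec("f2", 500L, copies = 2L,
               orientations = c("forward", "inverted")))
  g <- generate_genome(specs, genome_length = 15000L, seed = 71)
  rep <- scan_sequence(g$record, scan_config())
  expect_length(rep$clusters, 2L)
  sizes <- sort(vapply(rep$clusters, function(cl) nrow(cl$members),
                       integer(1)))
  expect_equal(sizes, c(2L, 3L))
  # the inverted copy is recorded with inverted orientation
  oris <- unlist(lapply(rep$clusters, function(cl) cl$members$orientation))
  expect_equal(sum(oris == "inverted"), 1L)
})

test_that("profile mode splits a single inverted pair into linked clusters", {
  set.seed(6199)   # unit drawn independently of the background seed
  unit <- rand_dna(400)
  g <- generate_genome(list(plant_spec("f", unit, copies = 2L,
                                       orientations = c("forward",
                                                        "inverted"))),
                       genome_length = 6000L, seed = 61)
  rep <- scan_sequence(g$record, scan_config(quick = FALSE))
  expect_length(rep$clusters, 2L)
  expect_equal(rep$clusters[[1]]$group, rep$clusters[[2]]$group)
  oris <- lapply(rep$clusters, function(cl) unique(cl$members$orientation))
  expect_setequal(unlist(oris), c("forward", "inverted"))
})

test_that("reverse-complementing the genome flips every orientation", {
  specs <- list(plant_spec("f", 500L, copies = 3L,
                           orientations = c("forward", "forward",
                                            "inverted")))
  g <- generate_genome(specs, genome_length = 10000L, seed = 81)
  fwd_rep <- scan_sequence(g$record, scan_config())
  rc_rep <- scan_sequence(seq_record("s", revcomp(g$record$residues)),
                          scan_config())
  L <- g$record$length
  # block footprints mirror exactly
  expect_equal(sort(L - fwd_rep$blocks$end), sort(rc_rep$blocks$start))
  expect_equal(sort(L - fwd_rep$blocks$start), sort(rc_rep$blocks$end))
  # cluster structure is isomorphic: same number, same member counts,
  # same multiset of relative orientations
  expect_length(rc_rep$clusters, length(fwd_rep$clusters))
  count_rel <- function(rep) sort(vapply(rep$clusters, function(cl)
    sum(cl$members$orientation == "inverted"), integer(1)))
  expect_equal(count_rel(rc_rep), count_rel(fwd_rep))
})
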