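# Ungapped X-drop extension of seeds into maximal segment pairs.

S20 <- "GATTACAGATCAGGCCATAG"  # 20 bp unit used throughout

test_that("an exact duplication extends to the full planted copy", {
  rec <- seq_record("s", paste0(S20, strrep("T", 10), S20))
  p <- extend_pair(rec, 0L, 30L, "forward", k = 8L)
  expect_equal(p$a_start, 0L); expect_equal(p$a_end, 20L)
  expect_equal(p$b_start, 30L); expect_equal(p$b_end, 50L)
  expect_equal(p$identity, 1.0)
  expect_equal(p$matches, 20L)
})

test_that("a single substitution is absorbed with identity 19/20", {
  second <- S20
  substr(second, 11, 11) <- "G"   # substitute offset 10 (0-based)
  stopifnot(substr(S20, 11, 11) != "G")
  rec <- seq_record("s", paste0(S20, strrep("T", 10), second))
  # seed must avoid the substituted offset: windows 0..2 of the copy qualify
  p <- extend_pair(rec, 0L, 30L, "forward", k = 8L)
  expect_equal(c(p$a_start, p$a_end, p$b_start, p$b_end),
               c(0L, 20L, 30L, 50L))
  expect_equal(p$matches, 19L)
  expect_equal(p$identity, 0.95)
})

test_that("inverted seeds extend through the reverse complement", {
  rec <- seq_record("s", paste0(S20, strrep("T", 10), revcomp(S20)))
  # rc of the first 8-mer of S20 sits at the far end of the rc copy
  p <- extend_pair(rec, 0L, 42L, "inverted", k = 8L)
  expect_equal(c(p$a_start, p$a_end, p$b_start, p$b_end),
               c(0L, 20L, 30L, 50L))
  expect_equal(p$orientation, "inverted")
  expect_equal(p$identity, 1.0)
})

test_that("pairs below the homology floor return NULL", {
  unit <- "GATTACAGATCAGGCCATAGCAGCATTACG"   # 30 bp
  second <- strsplit(unit, "")[[1L]]
  for (off in c(11L, 16L, 21L))               # three substitutions
    second[off] <- setdiff(c("A", "C", "G", "T"), second[off])[1L]
  rec <- seq_record("s", paste0(unit, strrep("T", 10),
                                paste(second, collapse = "")))
  # full extension reaches identity 27/30 = 0.9
  ok <- extend_pair(rec, 0L, 40L, "forward", k = 8L,
                    params = extend_params(homology_floor = 0.85))
  expect_equal(ok$identity, 0.9)
  expect_null(extend_pair(rec, 0L, 40L, "forward", k = 8L,
                          params = extend_params(homology_floor = 0.95)))
})

test_that("extension stops at N and never shrinks below the seed", {
  rec <- seq_record("s", paste0(S20, "N", strrep("T", 9), S20, "N", "ACGT"))
  p <- extend_pair(rec, 0L, 30L, "forward", k = 8L)
  expect_equal(c(p$a_start, p$a_end), c(0L, 20L))
  # seed window is always inside the result
  expect_true(p$a_start <= 0L && p$a_end >= 8L)
  expect_true(p$b_start <= 30L && p$b_end >= 38L)
})

test_that("extension agrees with the scalar oracle walk on random seeds", {
  set.seed(31)
  for (rep_i in 1:20) {
    unit <- rand_dna(30)
    second <- strsplit(unit, "")[[1L]]
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      at <- sample(seq_along(second), nmut)
      second[at] <- vapply(second[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    }
    s <- paste0(rand_dna(25), unit, rand_dna(18),
                paste(second, collapse = ""), rand_dna(25))
    rec <- seq_record("s", s)
    idx <- build_kmer_index(rec, 8L)
    seeds <- enumerate_seed_pairs(idx, rec)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (si in seq_len(nrow(seeds))) {
      got <- extend_pair(rec, seeds$pos_a[si], seeds$pos_b[si],
                         seeds$orientation[si], 8L)
      want <- oracle_extend(chars, seeds$pos_a[si], seeds$pos_b[si],
                            seeds$orientation[si], 8L)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(c(got$a_start, got$a_end, got$b_start, got$b_end),
                     c(want$a_start, want$a_end, want$b_start, want$b_end))
        expect_equal(got$matches, want$matches)
      }
    }
  }
})

test_that("identity is mirror-invariant under reverse complement", {
  set.seed(33)
  unit <- rand_dna(40)
  s <- paste0(rand_dna(30), unit, rand_dna(30), unit, rand_dna(20))
  rec <- seq_record("s", s)
  rc_rec <- seq_record("s", revcomp(s))
  L <- rec$length
  pr <- dedupe_pairs(extend_seed_pairs(rec, enumerate_seed_pairs(
    build_kmer_index(rec, 12L), rec)))
  pr_rc <- dedupe_pairs(extend_seed_pairs(rc_rec, enumerate_seed_pairs(
    build_kmer_index(rc_rec, 12L), rc_rec)))
  expect_equal(sort(pr$identity), sort(pr_rc$identity))
  # footprints mirror: [s,e) -> [L-e, L-s)
  mirror <- sort(c(L - pr$a_end, L - pr$b_end))
  expect_equal(sort(c(pr_rc$a_start, pr_rc$b_start)), mirror)
})

test_that("dedupe keeps maximal pairs only and sorts the result", {
  # spacer free of internal repeats so the only pairs come from the two copies
  rec <- seq_record("s", paste0(S20, "CGTAGCATGC", S20))
  seeds <- enumerate_seed_pairs(build_kmer_index(rec, 8L), rec,
                                search_inverted = FALSE)
  pairs <- extend_seed_pairs(rec, seeds)
  dd <- dedupe_pairs(pairs)
  expect_equal(nrow(dd), 1L)        # many seeds, one maximal pair
  expect_equal(c(dd$a_start, dd$a_end, dd$b_start, dd$b_end),
               c(0L, 20L, 30L, 50L))

  # disjoint pairs both survive, sorted by a_start then b_start
  p1 <- data.frame(a_start = 50L, a_end = 70L, b_start = 100L, b_end = 120L,
                   orientation = "forward", matches = 20L,
                   aligned_length = 20L, identity = 1)
  p2 <- data.frame(a_start = 0L, a_end = 20L, b_start = 30L, b_end = 50L,
                   orientation = "forward", matches = 20L,
                   aligned_length = 20L, identity = 1)
  dd2 <- dedupe_pairs(rbind(p1, p2))
  expect_equal(dd2$a_start, c(0L, 50L))

  # strict containment: only the container remains
  small <- data.frame(a_start = 2L, a_end = 10L, b_start = 32L, b_end = 40L,
                      orientation = "forward", matches = 8L,
                      aligned_length = 8L, identity = 1)
  big <- data.frame(a_start = 0L, a_end = 20L, b_start = 30L, b_end = 50L,
                    orientation = "forward", matches = 20L,
                    aligned_length = 20L, identity = 1)
  expect_equal(nrow(dedupe_pairs(rbind(small, big))), 1L)
  expect_equal(dedupe_pairs(rbind(small, big))$a_end, 20L)
})
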