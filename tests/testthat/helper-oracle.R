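# Independent brute-force reference implementation used as an oracle.
# Deliberately naive: character loops over every window pair, no index
# structures, no diagonal shortcuts, no vectorised walks.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# scalar X-drop walk; matchfun(t) returns TRUE/FALSE/NA for step t
oracle_walk <- function(matchfun, maxsteps, xdrop = 10L) {
  cs <- 0L; rmax <- 0L
  best_score <- 0L; best_t <- 0L; best_m <- 0L
  m_so_far <- 0L
  t <- 0L
  while (t < maxsteps) {
    t <- t + 1L
    mm <- matchfun(t)
    if (is.na(mm)) break
    cs <- cs + if (mm) 1L else -2L
    if (mm) m_so_far <- m_so_far + 1L
    if (cs > best_score) { best_score <- cs; best_t <- t; best_m <- m_so_far }
    rmax <- max(rmax, cs)
    if (rmax - cs >= xdrop) break
  }
  c(best_t, best_m)
}

# extend one seed; chars is the split character vector (1-based), 0-based seed
oracle_extend <- function(chars, a, b, orientation, k, xdrop = 10L,
                          floor = 0.6) {
  L <- length(chars)
  ch <- function(p0) chars[p0 + 1L]  # 0-based accessor
  eq <- function(x, y) {
    if (x == "N" || y == "N") NA else x == y
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  if (orientation == "forward") {
    gap <- b - a - k
    lw <- oracle_walk(function(t) eq(ch(a - t), ch(b - t)),
                      max(0L, min(a, gap)), xdrop)
    rw <- oracle_walk(function(t) eq(ch(a + k - 1L + t), ch(b + k - 1L + t)),
                      max(0L, min(L - (a + k), L - (b + k), gap - lw[1L])),
                      xdrop)
    res <- c(a - lw[1L], a + k + rw[1L], b - lw[1L], b + k + rw[1L])
  } else {
    rw <- oracle_walk(function(t) eq(ch(a + k - 1L + t), comp[[ch(b - t)]]),
                      max(0L, min(L - (a + k), (b - a - k) %/% 2L)), xdrop)
    lw <- oracle_walk(function(t) eq(ch(a - t), comp[[ch(b + k - 1L + t)]]),
                      max(0L, min(a, L - (b + k))), xdrop)
    res <- c(a - lw[1L], a + k + rw[1L], b - rw[1L], b + k + lw[1L])
  }
  aligned <- res[2L] - res[1L]
  matches <- k + lw[2L] + rw[2L]
  if (matches / aligned < floor) return(NULL)
  list(a_start = res[1L], a_end = res[2L], b_start = res[3L], b_end = res[4L],
       matches = matches, aligned = aligned)
}

# every seed pair by double loop over all windows
oracle_seeds <- function(chars, k, inverted = TRUE, cap = 1000L) {
  L <- length(chars)
  n <- L - k + 1L
  if (n < 1L) return(list())
  win <- vapply(seq_len(n), function(i)
    paste(chars[i:(i + k - 1L)], collapse = ""), character(1L))
  ok <- !vapply(seq_len(n), function(i) any(chars[i:(i + k - 1L)] == "N"),
                logical(1L))
  counts <- table(win[ok])
  seeds <- list()
  min_sep <- as.integer(ceiling(k / 2))
  for (i in seq_len(n)) {
    if (!ok[i]) next
    for (j in seq_len(n)) {
      if (!ok[j]) next
      if (j > i && win[i] == win[j] &&
          counts[[win[i]]] <= cap) {
        seeds[[length(seeds) + 1L]] <- list(a = i - 1L, b = j - 1L,
                                            orientation = "forward")
      }
      if (inverted && j >= i && (j - i) >= min_sep &&
          win[i] == oracle_revcomp(win[j]) &&
          counts[[win[i]]] <= cap && counts[[win[j]]] <= cap) {
        seeds[[length(seeds) + 1L]] <- list(a = i - 1L, b = j - 1L,
                                            orientation = "inverted")
      }
    }
  }
  seeds
}

# full naive pipeline down to the masked position set (0-based positions)
oracle_masked_positions <- function(seq_string, k, initial, min_len,
                                    inverted = TRUE, xdrop = 10L,
                                    floor = 0.6, cap = 1000L) {
  chars <- strsplit(seq_string, "", fixed = TRUE)[[1L]]
  seeds <- oracle_seeds(chars, k, inverted = inverted, cap = cap)
  covered <- logical(length(chars))
  for (s in seeds) {
    e <- oracle_extend(chars, s$a, s$b, s$orientation, k,
                       xdrop = xdrop, floor = floor)
    if (is.null(e) || e$aligned < initial) next
    covered[(e$a_start + 1L):e$a_end] <- TRUE
    covered[(e$b_start + 1L):e$b_end] <- TRUE
  }
  # merge touching runs, then drop runs shorter than min_len
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  pos <- integer(0)
  for (i in which(keep)) pos <- c(pos, (starts[i]:ends[i]) - 1L)
  pos
}

# random DNA string helper for tests
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
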