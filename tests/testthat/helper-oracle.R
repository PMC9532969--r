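# Brute-force repeat oracle, independent of the package's seed-and-extend
# finder. For every rotation offset it compares the genome with a shifted
# copy of itself (forward) or of its reverse complement (inverted) and reads
# maximal runs of agreement off an rle; each run is one maximal exact match.
# O(L^2), fine for the <= 3 kb genomes it is used on.

oracle_encode <- function(seq) {
  v <- utf8ToInt(seq)
  out <- integer(length(v))
  out[v == 65L] <- 1L; out[v == 67L] <- 2L
  out[v == 71L] <- 3L; out[v == 84L] <- 4L
  out
}

# maximal circular TRUE-runs of eq (logical length L) as start0/len vectors;
# runs are the gaps between consecutive FALSE positions in circular order
oracle_runs <- function(eq, L, min_len) {
  w <- which(!eq)
  if (!length(w)) return(NULL)  # fully periodic; not exercised by fixtures
  lens <- diff(c(w, w[1L] + L)) - 1L
  keep <- lens >= min_len
  if (!any(keep)) return(NULL)
  list(start0 = w[keep] %% L, len = lens[keep])
}

canonical_match <- function(s1, s2, m, orient, L) {
  s1 <- s1 %% L; s2 <- s2 %% L
  if (s1 > s2) { tmp <- s1; s1 <- s2; s2 <- tmp }
  paste(s1, s2, m, orient, sep = ":")
}

oracle_repeats <- function(genome, min_len = 30L) {
  L <- genome$length
  x <- oracle_encode(genome$seq)
  z <- rev(c(0L, 4L, 3L, 2L, 1L)[x + 1L])  # encoded reverse complement
  x2 <- c(x, x); z2 <- c(z, z)
  valid <- x != 0L
  keys <- character(0)
  for (d in seq_len(L - 1L)) {
    eq <- x == x2[(d + 1L):(d + L)] & valid
    runs <- oracle_runs(eq, L, min_len)
    if (is.null(runs)) next
    for (t in seq_along(runs$start0)) {
      keys <- c(keys, canonical_match(runs$start0[t], runs$start0[t] + d,
                                      runs$len[t], "F", L))
    }
  }
  for (cc in 0:(L - 1L)) {
    eq <- x == z2[(cc + 1L):(cc + L)] & valid
    runs <- oracle_runs(eq, L, min_len)
    if (is.null(runs)) next
    for (t in seq_along(runs$start0)) {
      i <- runs$start0[t]; m <- runs$len[t]
      j <- (L - i - cc - m) %% L
      keys <- c(keys, canonical_match(i, j, m, "R", L))
    }
  }
  sort(unique(keys))
}

# the finder's matches in the same canonical representation
finder_match_keys <- function(rs) {
  mt <- rs$matches
  L <- rs$genome_length
  if (!nrow(mt)) return(character(0))
  sort(unique(vapply(seq_len(nrow(mt)), function(i) {
    canonical_match(mt$start1[i], mt$start2[i], mt$length[i],
                    mt$orientation[i], L)
  }, "")))
}

# small random circle with optional planted repeats, built independently of
# generate_genome so finder tests do not lean on the simulator
random_circle <- function(L, seed, gc = 0.5) {
  set.seed(seed)
  circular_genome(paste0("rnd", seed),
                  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                               prob = c((1 - gc) / 2, (1 - gc) / 2,
                                        gc / 2, gc / 2)),
                        collapse = ""))
}

plant_pair <- function(L, rep_len, seed, orientation = "direct",
                       pos = c(0.1, 0.55), origin_span = FALSE) {
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  unit <- sample(c("A", "C", "G", "T"), rep_len, replace = TRUE)
  p1 <- round(pos[1] * L); p2 <- round(pos[2] * L)
  if (origin_span) p2 <- L - round(rep_len / 2)
  second <- if (orientation == "inverted")
    rev(chartr("ACGT", "TGCA", unit)) else unit
  bases[((p1 + seq_len(rep_len) - 1L) %% L) + 1L] <- unit
  bases[((p2 + seq_len(rep_len) - 1L) %% L) + 1L] <- second
  circular_genome("planted", paste(bases, collapse = ""))
}
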