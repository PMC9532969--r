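test_that("planted direct and inverted pairs are recovered with correct class", {
  g <- plant_pair(2000, 150, seed = 11, orientation = "direct",
                  pos = c(0.1, 0.6))
  rs <- find_repeats(g, 30)
  # chance 1-2 bp boundary extensions are possible on a random background,
  # so compare against the brute-force oracle rather than the planted length
  expect_identical(finder_match_keys(rs), oracle_repeats(g, 30))
  big <- rs$units[rs$units$length >= 140, ]
  expect_identical(nrow(big), 1L)
  pp <- classify_pairs(rs)
  expect_identical(pp$orientation[pp$unit_id == big$unit_id], "direct")
  cp <- rs$copies[rs$copies$unit_id == big$unit_id, ]
  expect_identical(cp$strand, c("+", "+"))
  expect_identical(genome_subseq(g, cp$start[1] %% g$length,
                                 cp$end[1] %% g$length, cp$strand[1]),
                   big$sequence)

  gi <- plant_pair(2000, 150, seed = 12, orientation = "inverted",
                   pos = c(0.1, 0.6))
  ri <- find_repeats(gi, 30)
  expect_identical(finder_match_keys(ri), oracle_repeats(gi, 30))
  bigi <- ri$units[ri$units$length >= 140, ]
  cpi <- ri$copies[ri$copies$unit_id == bigi$unit_id, ]
  expect_setequal(cpi$strand, c("+", "-"))
  ppi <- classify_pairs(ri)
  expect_identical(ppi$orientation[ppi$unit_id == bigi$unit_id], "inverted")
  # each copy read on its strand equals the canonical unit sequence
  for (k in 1:2) {
    expect_identical(genome_subseq(gi, cpi$start[k] %% gi$length,
                                   cpi$end[k] %% gi$length, cpi$strand[k]),
                     bigi$sequence)
  }
})

test_that("repeats straddling the origin are found with wrap-aware coordinates", {
  g <- plant_pair(2400, 120, seed = 13, origin_span = TRUE)
  rs <- find_repeats(g, 30)
  expect_identical(finder_match_keys(rs), oracle_repeats(g, 30))
  big <- rs$units[rs$units$length >= 110, ]
  expect_identical(nrow(big), 1L)
  cp <- rs$copies[rs$copies$unit_id == big$unit_id, ]
  expect_true(any(cp$end > g$length))  # one copy wraps
})

test_that("rotation invariance: rotating the genome rotates the repeats", {
  g <- plant_pair(2200, 100, seed = 14)
  rs <- find_repeats(g, 30)
  for (k in c(57, 1111)) {
    rk <- find_repeats(rotate_genome(g, k), 30)
    # shift detected coordinates back and compare canonical match sets
    mt <- rk$matches
    shifted <- vapply(seq_len(nrow(mt)), function(i) {
      canonical_match(mt$start1[i] + k, mt$start2[i] + k, mt$length[i],
                      mt$orientation[i], g$length)
    }, "")
    expect_setequal(shifted, finder_match_keys(rs))
  }
})

test_that("strand symmetry: the reverse-complemented genome has the same repeats", {
  g <- plant_pair(2100, 90, seed = 15, orientation = "inverted")
  rs <- find_repeats(g, 30)
  grc <- circular_genome("rc", rev_comp(g$seq))
  rsrc <- find_repeats(grc, 30)
  expect_identical(rs$units$length, rsrc$units$length)
  expect_identical(vapply(rs$units$sequence, nchar, 1L, USE.NAMES = FALSE),
                   vapply(rsrc$units$sequence, nchar, 1L, USE.NAMES = FALSE))
  # mirror rc coordinates back onto the forward genome
  L <- g$length
  mt <- rsrc$matches
  mirrored <- vapply(seq_len(nrow(mt)), function(i) {
    s1 <- (L - mt$end1[i]) %% L
    s2 <- (L - mt$end2[i]) %% L
    canonical_match(s1, s2, mt$length[i], mt$orientation[i], L)
  }, "")
  expect_setequal(mirrored, finder_match_keys(rs))
})

test_that("raising min_len never adds a unit and guards reject bad input", {
  g <- plant_pair(2000, 100, seed = 16)
  lens <- c(30L, 50L, 80L, 101L)
  n <- vapply(lens, function(ml) nrow(find_repeats(g, ml)$units), 1L)
  expect_true(all(diff(n) <= 0))
  expect_error(find_repeats(g, 7), "min_len")
  expect_error(find_repeats(circular_genome("s", "ACGT"), 30), "shorter")
  gN <- circular_genome("n", strrep("N", 500))
  expect_warning(rn <- find_repeats(gN, 30), "no repeats|unambiguous")
  expect_identical(nrow(rn$units), 0L)
})

test_that("a repeat-free genome yields an empty unit list", {
  # random 500-mers essentially never share a 30-mer; verify via the oracle
  g <- random_circle(500, seed = 17)
  expect_identical(oracle_repeats(g, 30), character(0))
  expect_identical(nrow(find_repeats(g, 30)$units), 0L)
})

test_that("overlapping units are classified with mutual overlap_bp", {
  cfg <- sim_config(genome_length = 8000, n_pairs = 10, seed = 18,
                    repeats = list(list(length = 120, orientation = "direct"),
                                   list(length = 110, orientation = "direct",
                                        overlap_bp = 3)))
  sim <- generate_genome(cfg)
  pp <- sim$pairs
  expect_identical(nrow(pp), 2L)
  expect_identical(pp$overlap_bp, c(3L, 3L))
  expect_identical(pp$overlap_partner, rev(pp$pair_id))
})

test_that("repeat summary unions copy intervals and computes GC", {
  g0 <- random_circle(500, seed = 19)
  s0 <- repeat_summary(g0, find_repeats(g0, 30))
  expect_identical(s0$repetitive_bp, 0L)
  expect_identical(s0$repeat_fraction, 0)

  gx <- circular_genome("x", "ATGC")
  rx <- mitorecomb:::repeat_set(gx, 30L, mitorecomb:::empty_matches())
  expect_identical(repeat_summary(gx, rx)$gc_content, 0.5)

  # per-base oracle on a planted genome
  g <- plant_pair(2000, 150, seed = 20)
  rs <- find_repeats(g, 30)
  mask <- logical(g$length)
  for (i in seq_len(nrow(rs$copies))) {
    mask[(seq.int(rs$copies$start[i], rs$copies$end[i] - 1L) %% g$length) + 1L] <- TRUE
  }
  s <- repeat_summary(g, rs)
  expect_identical(s$repetitive_bp, sum(mask))
  expect_equal(s$repeat_fraction, sum(mask) / g$length)
})
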