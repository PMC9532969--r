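# deterministic toy circle: R + X + R2 + Y with controlled boundary bases so
# the planted pair is exactly maximal
toy_layout <- function(seed, orientation = "direct", L = 1200L,
                       rep_len = 120L) {
  set.seed(seed)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  R <- paste0("A", rnd(rep_len - 2L), "A")
  gap <- (L - 2L * rep_len) %/% 2L
  X <- paste0("C", rnd(gap - 2L), "C")   # boundary bases differ from Y's
  Y <- paste0("G", rnd(L - 2L * rep_len - gap - 2L), "G")
  second <- if (orientation == "inverted") rev_comp(R) else R
  g <- circular_genome("toy", paste0(R, X, second, Y))
  pair <- data.frame(
    pair_id = "P1", unit_id = "P1", length = rep_len,
    orientation = orientation,
    a_start = 0L, a_end = rep_len, a_strand = "+",
    b_start = rep_len + gap, b_end = 2L * rep_len + gap,
    b_strand = if (orientation == "inverted") "-" else "+",
    overlap_bp = 0L, overlap_partner = NA_character_, assessable = TRUE)
  list(genome = g, pair = pair, R = R, gap = gap, L = L, rep_len = rep_len)
}

sub1 <- function(s, from0, to0) substr(s, from0 + 1L, to0)  # 0-based helper

test_that("direct-pair conformations match hand-assembled strings", {
  ly <- toy_layout(31)
  fl <- 300L
  cs <- build_conformations(ly$genome, ly$pair, fl)
  m <- cs$members
  g <- ly$genome$seq
  b <- ly$pair$b_start
  up_a <- sub1(paste0(g, g), ly$L - fl, ly$L)  # wraps through origin
  dn_a <- sub1(g, ly$rep_len, ly$rep_len + fl)
  up_b <- sub1(g, b - fl, b)
  dn_b <- sub1(g, b + ly$rep_len, b + ly$rep_len + fl)
  expect_identical(m$sequence[m$label == "aa"], paste0(up_a, ly$R, dn_a))
  expect_identical(m$sequence[m$label == "bb"], paste0(up_b, ly$R, dn_b))
  expect_identical(m$sequence[m$label == "ab"], paste0(up_a, ly$R, dn_b))
  expect_identical(m$sequence[m$label == "ba"], paste0(up_b, ly$R, dn_a))
  expect_identical(unique(m$left_junction), fl)
  expect_identical(unique(m$right_junction), fl + ly$rep_len)
  expect_identical(sort(m$kind), c("recombined", "recombined",
                                   "reference", "reference"))
})

test_that("conformation algebra: exchanging flanks twice restores the references", {
  ly <- toy_layout(32)
  cs <- build_conformations(ly$genome, ly$pair, 250L)
  m <- cs$members
  seqs <- stats::setNames(m$sequence, m$label)
  lj <- m$left_junction[1]; rj <- m$right_junction[1]
  swap_right <- function(x, y) paste0(substr(x, 1, rj), substring(y, rj + 1))
  # ab from aa and bb, then swapping right flanks back regenerates aa
  expect_identical(swap_right(seqs["aa"], seqs["bb"]), unname(seqs["ab"]))
  expect_identical(swap_right(seqs["ab"], seqs["ba"]), unname(seqs["aa"]))
  # every recombined member shares its up flank with one reference and its
  # down flank with the other; no reference member mixes
  up <- function(x) unname(substr(x, 1, lj))
  dn <- function(x) unname(substring(x, rj + 1))
  expect_identical(up(seqs["ab"]), up(seqs["aa"]))
  expect_identical(dn(seqs["ab"]), dn(seqs["bb"]))
  expect_identical(up(seqs["ba"]), up(seqs["bb"]))
  expect_identical(dn(seqs["ba"]), dn(seqs["aa"]))
  expect_false(dn(seqs["aa"]) == dn(seqs["bb"]))
})

test_that("inverted-pair conformations follow the copy-a reading convention", {
  ly <- toy_layout(33, orientation = "inverted")
  fl <- 200L
  cs <- build_conformations(ly$genome, ly$pair, fl)
  m <- cs$members
  g <- ly$genome$seq
  b <- ly$pair$b_start
  up_a <- sub1(paste0(g, g), ly$L - fl, ly$L)
  # ab = leftFlank(a) + repeat + revcomp(leftFlank(b))
  left_b <- sub1(g, b - fl, b)
  expect_identical(m$sequence[m$label == "ab"],
                   paste0(up_a, ly$R, rev_comp(left_b)))
  # bb is the copy-b locus read on the minus strand
  right_b <- sub1(g, b + ly$rep_len, b + ly$rep_len + fl)
  expect_identical(m$sequence[m$label == "bb"],
                   paste0(rev_comp(right_b), ly$R, rev_comp(left_b)))
})

test_that("zero flank degenerates to the bare repeat with a warning", {
  ly <- toy_layout(34)
  expect_warning(cs <- build_conformations(ly$genome, ly$pair, 0L),
                 "flank_len = 0")
  expect_identical(unique(cs$members$sequence), ly$R)
})

test_that("flanks truncate where another repeat copy begins", {
  # gap between copy_a's end and copy_b's start is 480; a 500 bp flank must
  # stop at the other copy's boundary
  ly <- toy_layout(35)
  cs <- build_conformations(ly$genome, ly$pair, 500L)
  m <- cs$members
  # both single-copy gaps on this toy circle are 480 bp, so each 500 bp
  # flank stops 20 bp short
  expect_identical(m$down_trunc[m$label == "aa"], 500L - ly$gap)
  expect_identical(m$up_trunc[m$label == "aa"], 500L - ly$gap)
  expect_identical(nchar(m$sequence[m$label == "aa"]),
                   ly$gap + ly$rep_len + ly$gap)
})

test_that("overlapping pairs yield 3+3 conformation sets with distinct members", {
  cfg <- sim_config(genome_length = 8000, n_pairs = 10, seed = 36,
                    repeats = list(list(length = 120, orientation = "direct"),
                                   list(length = 110, orientation = "direct",
                                        overlap_bp = 3)))
  sim <- generate_genome(cfg)
  sets <- build_overlap_conformations(sim$genome, sim$pairs[1, ],
                                      sim$pairs[2, ], 300L)
  for (s in sets) {
    expect_identical(nrow(s$members), 6L)
    expect_identical(sum(s$members$kind == "reference"), 3L)
    expect_identical(sum(s$members$kind == "recombined"), 3L)
    expect_false(anyDuplicated(s$members$sequence) > 0)
  }
  # overlap_bp == 0 falls back to two ordinary 2+2 sets
  cfg0 <- sim_config(genome_length = 9000, n_pairs = 10, seed = 37,
                     repeats = list(list(length = 120, orientation = "direct"),
                                    list(length = 110, orientation = "direct")))
  sim0 <- generate_genome(cfg0)
  fb <- build_overlap_conformations(sim0$genome, sim0$pairs[1, ],
                                    sim0$pairs[2, ], 100L)
  expect_identical(vapply(fb, function(s) nrow(s$members), 1L), c(4L, 4L))
})

test_that("direct-repeat recombination splits the circle conservatively", {
  # hand layout: A(500) R(100) B(300) R(100), products B+R (400) and A+R (600)
  set.seed(39)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  A <- rnd(500); R <- rnd(100); B <- rnd(300)
  g <- circular_genome("hand", paste0(A, R, B, R))
  pair <- data.frame(pair_id = "P", length = 100, orientation = "direct",
                     a_start = 500L, a_end = 600L, a_strand = "+",
                     b_start = 900L, b_end = 1000L, b_strand = "+")
  gp <- recombine_genome(g, pair)
  lens <- sort(vapply(gp$products, `[[`, 1L, "length"))
  expect_identical(lens, c(400L, 600L))
  expect_identical(sum(lens), g$length)
  # each product contains exactly one copy of the repeat
  for (p in gp$products) {
    hits <- gregexpr(R, paste0(p$seq, substr(p$seq, 1, 99)), fixed = TRUE)[[1]]
    expect_identical(sum(hits > 0), 1L)
  }
  # base multiset is conserved for the direct split
  cnt <- function(s) table(strsplit(s, "")[[1]])
  expect_identical(cnt(paste0(gp$products[[1]]$seq, gp$products[[2]]$seq)),
                   cnt(g$seq))
  # round trip: rejoining regenerates a rotation of the parent
  rj <- rejoin_circles(gp)
  expect_true(mitorecomb:::is_rotation(rj$seq, g$seq))
})

test_that("inverted-repeat recombination preserves length and AT/GC balance", {
  ly <- toy_layout(40, orientation = "inverted")
  gp <- recombine_genome(ly$genome, ly$pair)
  expect_length(gp$products, 1L)
  p <- gp$products[[1]]
  expect_identical(p$length, ly$genome$length)
  cnt <- function(s) table(factor(strsplit(s, "")[[1]], c("A", "C", "G", "T")))
  c0 <- cnt(ly$genome$seq); c1 <- cnt(p$seq)
  expect_identical(c0[["G"]] + c0[["C"]], c1[["G"]] + c1[["C"]])
  expect_identical(c0[["A"]] + c0[["T"]], c1[["A"]] + c1[["T"]])
  expect_false(p$seq == ly$genome$seq)  # the segment between copies flipped
  # applying the isomerisation twice returns the parent
  rs2 <- find_repeats(p, 30)
  pp2 <- classify_pairs(rs2)
  big <- pp2[which.max(pp2$length), ]
  back <- recombine_genome(p, big)$products[[1]]
  expect_true(mitorecomb:::is_rotation(back$seq, ly$genome$seq))
})

test_that("assessability follows the fragment-anchor rule", {
  expect_false(assessable_by_short_reads(16366, 150, 300)$assessable)
  expect_true(assessable_by_short_reads(111, 150, 300)$assessable)
  expect_true(assessable_by_short_reads(237, 150, 300)$assessable)
  # boundary: repeat as long as the insert cannot anchor both flanks
  expect_false(assessable_by_short_reads(300, 150, 300)$assessable)
  expect_true(assessable_by_short_reads(250, 150, 300)$assessable)
  expect_false(assessable_by_short_reads(251, 150, 300)$assessable)
  expect_match(assessable_by_short_reads(16366, 150, 300)$reason,
               "unassessable")
})
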