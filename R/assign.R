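# Internal gapless alignment machinery. Targets (conformation members and
# decoys) are indexed by exact k-mers; a read is placed by looking up seeds
# at fixed offsets, scoring every candidate diagonal over the full overlap
# with the target (clipping only at target ends), and keeping the placement
# with the most matching bases subject to the mismatch-rate ceiling. No
# gaps: the simulator's error model is substitution-only and the filters
# (aligned length, junction anchors) are then exact.

SEED_K <- 20L

index_target <- function(seq) {
  n <- nchar(seq)
  enc <- encode_bases(seq)
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (n >= SEED_K) {
    starts <- 1:(n - SEED_K + 1L)
    kms <- substring(seq, starts, starts + SEED_K - 1L)
    keep <- !grepl("[^ACGT]", kms)
    tab <- split(starts[keep], kms[keep])
    for (nm in names(tab)) assign(nm, tab[[nm]], envir = env)
  }
  list(enc = enc, len = n, idx = env)
}

# seed strings and offsets for one read orientation
read_seeds <- function(rseq, rl) {
  offs <- unique(c(seq(1L, max(1L, rl - SEED_K + 1L), by = SEED_K),
                   max(1L, rl - SEED_K + 1L)))
  list(offs = offs, seeds = substring(rseq, offs, offs + SEED_K - 1L))
}

# best gapless placement of an encoded read on one indexed target;
# returns NULL when nothing acceptable
best_placement <- function(sd, renc, target, max_mismatch_rate) {
  rl <- length(renc)
  offs <- sd$offs; seeds <- sd$seeds
  diags <- integer(0)
  for (s in seq_along(seeds)) {
    hits <- target$idx[[seeds[s]]]
    if (!is.null(hits)) diags <- c(diags, hits - offs[s] + 1L)
  }
  if (!length(diags)) return(NULL)
  diags <- unique(diags)
  best <- NULL
  for (D in diags) {
    ts <- max(1L, D); te <- min(target$len, D + rl - 1L)
    alen <- te - ts + 1L
    if (alen <= 0L) next
    rs <- ts - D + 1L
    a <- target$enc[ts:te]; b <- renc[rs:(rs + alen - 1L)]
    nmatch <- sum(a == b & a != 0L)
    if ((alen - nmatch) > max_mismatch_rate * alen) next
    if (is.null(best) || nmatch > best$score) {
      best <- list(score = nmatch, start = ts, end = te, aligned_len = alen)
    }
  }
  best
}

# best placement over both read orientations; `m` is a list with the
# precomputed seeds and encodings of one mate in both orientations
best_placement2 <- function(m, target, max_mismatch_rate) {
  p1 <- best_placement(m$sd_f, m$enc_f, target, max_mismatch_rate)
  p2 <- best_placement(m$sd_r, m$enc_r, target, max_mismatch_rate)
  if (is.null(p1)) return(p2)
  if (is.null(p2)) return(p1)
  if (p2$score > p1$score) p2 else p1
}

prep_mate <- function(s) {
  enc <- encode_bases(s)
  rc <- rev_comp(s)
  list(enc_f = enc, enc_r = rev(comp_code(enc)),
       sd_f = read_seeds(s, length(enc)), sd_r = read_seeds(rc, length(enc)))
}

#' Assign read pairs to conformation members
#'
#' Implements the support-counting rules for recombination assessment. A
#' pair supports a member iff (i) its summed best-placement score is strictly
#' higher on that member than on every other member and every decoy; (ii)
#' each mate aligns over at least `min_aln` bases there (suppressing
#' short spurious placements of nuclear-homolog reads); and (iii) the pair is
#' discriminative: jointly the mates cover both flank-repeat junctions with
#' at least `min_anchor` aligned bases beyond each junction into flank
#' sequence. Score ties across members are counted ambiguous, never
#' resolved randomly; pairs whose best placement is on a decoy are counted
#' decoy-filtered.
#'
#' @param reads a [read_pairs()] data frame.
#' @param confs a `conformation_set` (4 members for an ordinary pair, 6 for
#'   an overlapping pair; all members are scored jointly).
#' @param decoys optional list of [circular_genome()] (e.g. the plastid
#'   genome) absorbing contaminant reads.
#' @param min_aln minimum aligned length per mate in bp.
#' @param min_anchor minimum aligned bases beyond each junction into flank.
#' @param max_mismatch_rate maximum fraction of mismatched bases per
#'   alignment.
#' @return An object of class `assignment_counts`: list with `pair_id`,
#'   `counts` (named integer vector over member labels), `kinds` (named
#'   vector mapping labels to reference/recombined), `n_ambiguous`,
#'   `n_filtered_short`, `n_filtered_decoy`, `n_unmapped`, `n_total`.
#' @export
assign_read_pairs <- function(reads, confs, decoys = NULL, min_aln = 100L,
                              min_anchor = 25L, max_mismatch_rate = 0.02) {
  stopifnot(inherits(confs, "conformation_set"))
  mem <- confs$members
  labels <- mem$label
  counts <- stats::setNames(integer(length(labels)), labels)
  kinds <- stats::setNames(mem$kind, labels)
  out <- function(na, ns, nd, nu) {
    structure(list(pair_id = confs$pair_id, counts = counts, kinds = kinds,
                   n_ambiguous = na, n_filtered_short = ns,
                   n_filtered_decoy = nd, n_unmapped = nu,
                   n_total = if (is.null(reads)) 0L else nrow(reads)),
              class = "assignment_counts")
  }
  if (is.null(reads) || nrow(reads) == 0L) return(out(0L, 0L, 0L, 0L))

  rl_max <- max(nchar(reads$mate1), nchar(reads$mate2))
  if (rl_max > min(nchar(mem$sequence)))
    stop("reads longer than conformation members; rebuild with larger flank_len")

  targets <- lapply(mem$sequence, index_target)
  dec <- list()
  if (!is.null(decoys)) {
    if (inherits(decoys, "circular_genome")) decoys <- list(decoys)
    dec <- lapply(decoys, function(d) {
      s <- if (d$circular) paste0(d$seq, substr(d$seq, 1L, rl_max - 1L)) else d$seq
      index_target(s)
    })
  }

  n_amb <- n_short <- n_decoy <- n_unmap <- 0L
  nm <- length(targets)
  for (r in seq_len(nrow(reads))) {
    mp1 <- prep_mate(reads$mate1[r])
    mp2 <- prep_mate(reads$mate2[r])

    p1 <- vector("list", nm); p2 <- vector("list", nm)
    score <- numeric(nm)
    for (t in seq_len(nm)) {
      p1[t] <- list(best_placement2(mp1, targets[[t]], max_mismatch_rate))
      p2[t] <- list(best_placement2(mp2, targets[[t]], max_mismatch_rate))
      score[t] <- (if (is.null(p1[[t]])) 0 else p1[[t]]$score) +
                  (if (is.null(p2[[t]])) 0 else p2[[t]]$score)
    }
    dscore <- 0
    for (d in dec) {
      q1 <- best_placement2(mp1, d, max_mismatch_rate)
      q2 <- best_placement2(mp2, d, max_mismatch_rate)
      sd <- (if (is.null(q1)) 0 else q1$score) +
            (if (is.null(q2)) 0 else q2$score)
      if (sd > dscore) dscore <- sd
    }

    smax <- max(score)
    if (smax == 0 && dscore == 0) { n_unmap <- n_unmap + 1L; next }
    if (dscore > smax) { n_decoy <- n_decoy + 1L; next }
    if (dscore == smax || sum(score == smax) > 1L) { n_amb <- n_amb + 1L; next }
    w <- which.max(score)
    a1 <- p1[[w]]; a2 <- p2[[w]]
    if (is.null(a1) || is.null(a2) ||
        a1$aligned_len < min_aln || a2$aligned_len < min_aln) {
      n_short <- n_short + 1L; next
    }
    lj <- mem$left_junction[w]; rj <- mem$right_junction[w]  # 0-based offsets
    cover_left <- function(p) p$start <= lj - min_anchor + 1L && p$end > lj
    cover_right <- function(p) p$end >= rj + min_anchor && p$start <= rj
    if ((cover_left(a1) || cover_left(a2)) &&
        (cover_right(a1) || cover_right(a2))) {
      counts[labels[w]] <- counts[labels[w]] + 1L
    } else {
      n_amb <- n_amb + 1L
    }
  }
  out(n_amb, n_short, n_decoy, n_unmap)
}

#' @export
print.assignment_counts <- function(x, ...) {
  cat(sprintf("<assignment_counts> pair %s (%d read pairs)\n", x$pair_id,
              x$n_total))
  print(x$counts)
  cat(sprintf("ambiguous %d | short-filtered %d | decoy-filtered %d | unmapped %d\n",
              x$n_ambiguous, x$n_filtered_short, x$n_filtered_decoy,
              x$n_unmapped))
  invisible(x)
}
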