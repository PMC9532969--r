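# Reading-frame flank of a repeat copy: "up" is the single-copy sequence that
# precedes the copy and "down" the sequence that follows it, both written in
# the copy's own reading direction (so for a '-' copy they are reverse
# complements of the genomic neighbourhood). All four conformation members of
# a pair are assembled from these, which fixes the orientation convention:
# every member reads in the direction of copy_a.
copy_flank <- function(genome, start, end, strand, side, len) {
  L <- genome$length
  if (len == 0L) return("")
  if (strand == "+") {
    if (side == "up") genome_subseq(genome, (start - len) %% L, start %% L)
    else genome_subseq(genome, end %% L, (end + len) %% L)
  } else {
    if (side == "up") rev_comp(genome_subseq(genome, end %% L, (end + len) %% L))
    else rev_comp(genome_subseq(genome, (start - len) %% L, start %% L))
  }
}

# max flank length on one genomic side of a copy before running into another
# repeat copy (keeps flanks single-copy). `side` is genomic: "left" grows
# from `start` downwards, "right" from `end` upwards.
usable_flank <- function(L, start, end, side, len, other_intervals) {
  if (len == 0L || !length(other_intervals)) return(len)
  covered <- logical(L)
  for (iv in other_intervals) {
    covered[(seq.int(iv[1L], iv[2L] - 1L) %% L) + 1L] <- TRUE
  }
  n <- 0L
  for (o in seq_len(len)) {
    pos <- if (side == "left") (start - o) %% L else (end + o - 1L) %% L
    if (covered[pos + 1L]) break
    n <- o
  }
  n
}

#' Build reference and recombined conformations for a repeat pair
#'
#' For a non-overlapping pair the set has four members: references `aa` and
#' `bb` (each copy with its own flanks) and recombined `ab` and `ba`
#' (flank-exchanged). Each member is `upstream flank + repeat + downstream
#' flank`, written in the reading direction of copy `a`; for inverted pairs
#' copy `b`'s context is reverse-complemented into that frame. Flanks are
#' truncated where single-copy sequence runs into another repeat copy, and
#' the truncation is recorded.
#'
#' @param genome a [circular_genome()].
#' @param pair one row of a `repeat_pairs` data frame (see
#'   [classify_pairs()]), or a list with the same fields.
#' @param flank_len flank length in bp; 300 mirrors the insert size of the
#'   short-read libraries these conformations are probed with.
#' @param repeats optional `repeat_set` used to truncate flanks against all
#'   other repeat copies; without it, flanks are truncated only against the
#'   pair's own two copies.
#' @return An object of class `conformation_set`: list with `pair_id`,
#'   `flank_len`, `repeat_length`, `orientation` and `members`, a data frame
#'   with `label`, `kind` (`reference`/`recombined`), `sequence`,
#'   `left_junction`/`right_junction` (0-based offsets of the flank-repeat
#'   boundaries within the member) and the truncation applied to each flank.
#' @export
build_conformations <- function(genome, pair, flank_len = 300L,
                                repeats = NULL) {
  pair <- as.list(pair)
  L <- genome$length
  rlen <- pair$a_end - pair$a_start
  if (flank_len == 0L)
    warning("flank_len = 0: members are the bare repeat; ",
            "conformations are indistinguishable")

  own <- list(c(pair$a_start %% L, pair$a_end),
              c(pair$b_start %% L, pair$b_end))
  others <- own
  if (!is.null(repeats)) {
    cp <- repeats$copies
    for (i in seq_len(nrow(cp))) {
      iv <- c(cp$start[i] %% L, cp$end[i])
      if (!any(vapply(own, function(o) identical(o, iv), TRUE)))
        others[[length(others) + 1L]] <- iv
    }
  }

  flank_of <- function(start, end, strand, side) {
    excl <- Filter(function(iv) !(iv[1L] == start %% L && iv[2L] == end),
                   others)
    gside <- if ((strand == "+") == (side == "up")) "left" else "right"
    n <- usable_flank(L, start %% L, end %% L, gside, flank_len, excl)
    if (flank_len > 0L && n == 0L)
      stop("flanks not single-copy at pair ", pair$pair_id,
           ": another repeat copy abuts the ", side,
           " flank; try a smaller flank_len")
    list(seq = copy_flank(genome, start, end, strand, side, n),
         trunc = flank_len - n)
  }

  up_a <- flank_of(pair$a_start, pair$a_end, pair$a_strand, "up")
  dn_a <- flank_of(pair$a_start, pair$a_end, pair$a_strand, "down")
  up_b <- flank_of(pair$b_start, pair$b_end, pair$b_strand, "up")
  dn_b <- flank_of(pair$b_start, pair$b_end, pair$b_strand, "down")
  R <- genome_subseq(genome, pair$a_start %% L, pair$a_end %% L,
                     pair$a_strand)

  member <- function(label, kind, up, dn) {
    data.frame(label = label, kind = kind,
               sequence = paste0(up$seq, R, dn$seq),
               left_junction = nchar(up$seq),
               right_junction = nchar(up$seq) + rlen,
               up_trunc = up$trunc, down_trunc = dn$trunc,
               partner_context = NA_character_)
  }
  members <- rbind(member("aa", "reference", up_a, dn_a),
                   member("bb", "reference", up_b, dn_b),
                   member("ab", "recombined", up_a, dn_b),
                   member("ba", "recombined", up_b, dn_a))
  structure(list(pair_id = pair$pair_id, flank_len = flank_len,
                 repeat_length = rlen, orientation = pair$orientation,
                 members = members),
            class = "conformation_set")
}

#' @export
print.conformation_set <- function(x, ...) {
  cat(sprintf("<conformation_set> pair %s (%s, %d bp repeat, flank %d): %d members\n",
              x$pair_id, x$orientation, x$repeat_length, x$flank_len,
              nrow(x$members)))
  print(x$members[, c("label", "kind", "left_junction", "right_junction")])
  invisible(x)
}

#' Conformations for two repeat pairs sharing overlapping copies
#'
#' When one copy of a pair shares genomic bases with one copy of another pair,
#' the flank of the overlapped copy on the shared side is not single-copy: it
#' runs through the partner repeat, and what follows the partner copy depends
#' on whether the partner pair itself is in its reference or recombined
#' state. Each pair therefore has three reference and three recombined
#' conformations: the affected flank is enumerated through both partner exit
#' contexts.
#'
#' @param genome a [circular_genome()].
#' @param pair1,pair2 rows of a `repeat_pairs` data frame whose copies share
#'   `overlap_bp > 0` bases. With `overlap_bp == 0` this falls back to two
#'   independent [build_conformations()] calls (2+2 members each).
#' @param flank_len flank length in bp.
#' @return list of two `conformation_set` objects (for `pair1` and `pair2`),
#'   each with 3 reference + 3 recombined members whose `partner_context`
#'   column records which partner state the affected flank assumes.
#' @export
build_overlap_conformations <- function(genome, pair1, pair2,
                                        flank_len = 300L) {
  pair1 <- as.list(pair1); pair2 <- as.list(pair2)
  L <- genome$length
  ov <- overlap_geometry(L, pair1, pair2)
  if (is.null(ov)) {
    return(list(build_conformations(genome, pair1, flank_len),
                build_conformations(genome, pair2, flank_len)))
  }
  list(overlap_set(genome, pair1, pair2, flank_len),
       overlap_set(genome, pair2, pair1, flank_len))
}

# which copy of p overlaps which copy of q; NULL when none
overlap_geometry <- function(L, p, q) {
  ivs <- function(x) list(a = c(x$a_start, x$a_end, x$a_strand),
                          b = c(x$b_start, x$b_end, x$b_strand))
  cover <- function(iv) (seq.int(as.integer(iv[1L]),
                                 as.integer(iv[2L]) - 1L)) %% L
  for (cp in c("a", "b")) for (cq in c("a", "b")) {
    ip <- ivs(p)[[cp]]; iq <- ivs(q)[[cq]]
    shared <- length(intersect(cover(ip), cover(iq)))
    if (shared > 0L) {
      if (shared >= min(as.integer(ip[2L]) - as.integer(ip[1L]),
                        as.integer(iq[2L]) - as.integer(iq[1L])))
        stop("overlap spans an entire repeat copy: unsupported")
      return(list(p_copy = cp, q_copy = cq, overlap = shared))
    }
  }
  NULL
}

# 3+3 conformation set for `pair`, whose copy ov$p_copy overlaps the partner
# pair's copy ov$q_copy.
overlap_set <- function(genome, pair, partner, flank_len) {
  L <- genome$length
  ov <- overlap_geometry(L, pair, partner)
  rlen <- pair$a_end - pair$a_start

  cpf <- function(p, which) list(start = p[[paste0(which, "_start")]],
                                 end = p[[paste0(which, "_end")]],
                                 strand = p[[paste0(which, "_strand")]])
  c1 <- cpf(pair, ov$p_copy)                       # overlapped copy of pair
  c2 <- cpf(partner, ov$q_copy)                    # overlapping partner copy
  o2 <- cpf(partner, if (ov$q_copy == "a") "b" else "a")  # partner's other copy
  other <- cpf(pair, if (ov$p_copy == "a") "b" else "a")

  # genomic side of c1 on which c2 lies (positions mod L; the overlap is at
  # one end of c1 because the overlap spans neither copy entirely)
  right_overlap <- ((c2$end - c1$end) %% L) < ((c1$start - c2$start) %% L)

  # two continuations of c1's flank on the overlapped genomic side, both as
  # genome-forward strings starting (right) or ending (left) at c1's boundary
  if (right_overlap) {
    rest <- (c2$end - c1$end) %% L       # partner bases beyond c1's end
    v_ref <- genome_subseq(genome, c1$end %% L, (c1$end + flank_len) %% L)
    exit <- if (c2$strand == "+")
      copy_flank(genome, o2$start, o2$end, o2$strand, "down", flank_len)
    else
      rev_comp(copy_flank(genome, o2$start, o2$end, o2$strand, "up", flank_len))
    v_alt <- substr(paste0(genome_subseq(genome, c1$end %% L,
                                         (c1$end + rest) %% L), exit),
                    1L, flank_len)
  } else {
    rest <- (c1$start - c2$start) %% L   # partner bases before c1's start
    v_ref <- genome_subseq(genome, (c1$start - flank_len) %% L, c1$start %% L)
    exit <- if (c2$strand == "+")
      copy_flank(genome, o2$start, o2$end, o2$strand, "up", flank_len)
    else
      rev_comp(copy_flank(genome, o2$start, o2$end, o2$strand, "down", flank_len))
    pre <- paste0(exit, genome_subseq(genome, (c1$start - rest) %% L,
                                      c1$start %% L))
    v_alt <- substr(pre, nchar(pre) - flank_len + 1L, nchar(pre))
  }

  # map the genomic side to c1's reading frame
  affected_side <- if ((c1$strand == "+") == right_overlap) "down" else "up"
  to_frame <- function(v) {
    if (c1$strand == "+") v else rev_comp(v)
  }
  var_ref <- to_frame(v_ref); var_alt <- to_frame(v_alt)

  up_c1 <- copy_flank(genome, c1$start, c1$end, c1$strand, "up", flank_len)
  dn_c1 <- copy_flank(genome, c1$start, c1$end, c1$strand, "down", flank_len)
  up_ot <- copy_flank(genome, other$start, other$end, other$strand, "up",
                      flank_len)
  dn_ot <- copy_flank(genome, other$start, other$end, other$strand, "down",
                      flank_len)

  # label the overlapped copy by its role in the pair ("a" or "b")
  oc <- ov$p_copy; on <- if (oc == "a") "b" else "a"
  mk <- function(label, kind, up, dn, ctx) {
    data.frame(label = label, kind = kind, sequence = paste0(up, R, dn),
               left_junction = nchar(up),
               right_junction = nchar(up) + rlen,
               up_trunc = flank_len - nchar(up),
               down_trunc = flank_len - nchar(dn),
               partner_context = ctx)
  }
  R <- genome_subseq(genome, pair$a_start %% L, pair$a_end %% L,
                     pair$a_strand)

  ref_lab <- paste0(oc, oc); oth_lab <- paste0(on, on)
  rec1 <- paste0(on, oc); rec2 <- paste0(oc, on)  # recombined labels
  if (affected_side == "down") {
    members <- rbind(
      mk(oth_lab, "reference", up_ot, dn_ot, NA_character_),
      mk(paste0(ref_lab, "1"), "reference", up_c1, var_ref, "reference"),
      mk(paste0(ref_lab, "2"), "reference", up_c1, var_alt, "recombined"),
      mk(paste0(rec1, "1"), "recombined", up_ot, var_ref, "reference"),
      mk(paste0(rec1, "2"), "recombined", up_ot, var_alt, "recombined"),
      mk(rec2, "recombined", up_c1, dn_ot, NA_character_))
  } else {
    members <- rbind(
      mk(oth_lab, "reference", up_ot, dn_ot, NA_character_),
      mk(paste0(ref_lab, "1"), "reference", var_ref, dn_c1, "reference"),
      mk(paste0(ref_lab, "2"), "reference", var_alt, dn_c1, "recombined"),
      mk(paste0(rec2, "1"), "recombined", var_ref, dn_ot, "reference"),
      mk(paste0(rec2, "2"), "recombined", var_alt, dn_ot, "recombined"),
      mk(rec1, "recombined", up_ot, dn_c1, NA_character_))
  }
  # members were assembled in the overlapped copy's frame for its own flanks;
  # when the overlapped copy is "a" the recombined labels above already match
  # the aa/bb/ab/ba convention, and likewise for "b".
  structure(list(pair_id = pair$pair_id, flank_len = flank_len,
                 repeat_length = rlen, orientation = pair$orientation,
                 members = members),
            class = "conformation_set")
}

#' Predict whole-genome recombination products of a repeat pair
#'
#' Recombination between a direct pair splits the circle into two subgenomic
#' circles, each retaining one copy of the repeat; their lengths sum to the
#' parent's. Recombination between an inverted pair yields a single isomeric
#' circle of identical length with the segment between the copies
#' reverse-complemented.
#'
#' @param genome a [circular_genome()].
#' @param pair one row of a `repeat_pairs` data frame.
#' @return An object of class `genome_product`: list with `event`
#'   (`pair_id`, `orientation`) and `products`, a list of
#'   [circular_genome()]s. Direct products are linearised with the retained
#'   repeat copy at position 0.
#' @export
recombine_genome <- function(genome, pair) {
  pair <- as.list(pair)
  L <- genome$length
  ca <- (seq.int(pair$a_start, pair$a_end - 1L)) %% L
  cb <- (seq.int(pair$b_start, pair$b_end - 1L)) %% L
  if (length(intersect(ca, cb)) > 0L)
    stop("repeat copies overlap each other: recombination unsupported")
  rlen <- pair$a_end - pair$a_start

  if (pair$orientation == "direct") {
    p1 <- genome_subseq(genome, pair$a_start %% L, pair$b_start %% L)
    p2 <- genome_subseq(genome, pair$b_start %% L, pair$a_start %% L)
    products <- list(
      circular_genome(sprintf("%s|%s|product1", genome$id, pair$pair_id), p1),
      circular_genome(sprintf("%s|%s|product2", genome$id, pair$pair_id), p2))
  } else {
    rot <- rotate_genome(genome, pair$a_start %% L)
    s2 <- (pair$b_start - pair$a_start) %% L
    e2 <- s2 + (pair$b_end - pair$b_start)
    seq <- paste0(substr(rot$seq, 1L, rlen),
                  rev_comp(substr(rot$seq, rlen + 1L, s2)),
                  substr(rot$seq, s2 + 1L, L))
    products <- list(
      circular_genome(sprintf("%s|%s|isomer", genome$id, pair$pair_id), seq))
  }
  structure(list(event = list(pair_id = pair$pair_id,
                              orientation = pair$orientation,
                              repeat_length = rlen),
                 products = products),
            class = "genome_product")
}

#' @export
print.genome_product <- function(x, ...) {
  cat(sprintf("<genome_product> pair %s (%s): %d product(s) of %s bp\n",
              x$event$pair_id, x$event$orientation, length(x$products),
              paste(vapply(x$products, `[[`, 1L, "length"),
                    collapse = " + ")))
  invisible(x)
}

#' Rejoin the two subgenomic circles of a direct-repeat split
#'
#' The inverse of the direct-repeat decomposition: fusing the two product
#' circles at their shared repeat copy regenerates a rotation of the parent
#' circle.
#'
#' @param product a `genome_product` from [recombine_genome()] with
#'   `orientation == "direct"`.
#' @return a [circular_genome()].
#' @export
rejoin_circles <- function(product) {
  stopifnot(inherits(product, "genome_product"),
            product$event$orientation == "direct",
            length(product$products) == 2L)
  circular_genome(paste0(product$products[[1L]]$id, "+rejoined"),
                  paste0(product$products[[1L]]$seq,
                         product$products[[2L]]$seq))
}

#' Can a repeat pair be assessed with short paired-end reads?
#'
#' A read pair discriminates conformations only if its mates jointly anchor
#' in the single-copy flanks on both sides of the repeat. That requires the
#' repeat to fit inside one sequenced fragment with room for an anchor at
#' each end: assessable iff
#' `repeat_length <= insert_size - 2 * min_anchor`. Very large repeats (the
#' ~16 kb class) fail this and need long-range approaches instead.
#'
#' @param repeat_length repeat length in bp.
#' @param read_len read length in bp (informational; the binding constraint
#'   is the fragment span).
#' @param insert_size fragment length in bp.
#' @param min_anchor required aligned bases beyond each junction.
#' @return list with `assessable` (logical) and `reason`.
#' @export
assessable_by_short_reads <- function(repeat_length, read_len = 150L,
                                      insert_size = 300L, min_anchor = 25L) {
  ok <- repeat_length <= insert_size - 2L * min_anchor
  list(assessable = ok,
       reason = if (ok) "repeat fits within one fragment with flank anchors"
                else "short-read-unassessable: no fragment can anchor both junction flanks")
}
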