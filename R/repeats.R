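#' Find maximal exact repeats in a circular genome
#'
#' Detects every maximal exact repeated substring of length `>= min_len`, in
#' forward and reverse-complement orientation, honouring circularity (repeats
#' straddling the linearisation origin are found). Detection is k-mer seeding
#' on the wrapped sequence followed by bidirectional maximal extension, with
#' deduplication by canonical coordinates; the result is the literal set of
#' maximal exact pairwise matches, grouped into repeat units.
#'
#' A unit is a set of genomic copies sharing one canonical sequence; units are
#' numbered `R1, R2, ...` by descending length, ties broken by leftmost start.
#' Bases outside A/C/G/T never seed or extend a match.
#'
#' @param genome a [circular_genome()].
#' @param min_len minimum repeat length in bp (default 30, the conventional
#'   floor for organellar repeat surveys).
#' @return An object of class `repeat_set`: a list with `genome_id`,
#'   `genome_length`, `min_len`, `units` (data frame: `unit_id`, `length`,
#'   `copy_count`, `sequence`), `copies` (data frame: `unit_id`, `copy`,
#'   `start`, `end`, `strand`; `end` may exceed the genome length for copies
#'   wrapping the origin) and `matches` (the underlying maximal pairwise
#'   matches, used by the unit grouping and exposed for verification).
#' @seealso [classify_pairs()], [repeat_summary()]
#' @export
find_repeats <- function(genome, min_len = 30L) {
  stopifnot(inherits(genome, "circular_genome"))
  if (min_len < 8L) stop("min_len < 8 refused: seeding degenerates")
  L <- genome$length
  if (L < 2L * min_len)
    stop("genome shorter than 2*min_len; nothing can repeat")
  enc <- encode_bases(genome$seq)
  empty <- repeat_set(genome, min_len, empty_matches())
  if (all(enc == 0L)) {
    warning("genome contains no unambiguous bases; no repeats reported")
    return(empty)
  }

  k <- min(31L, min_len)
  # one k-mer per circular position
  doubled <- paste0(genome$seq, substr(genome$seq, 1L, k - 1L))
  starts0 <- 0:(L - 1L)
  kmers <- substring(doubled, starts0 + 1L, starts0 + k)
  valid <- !grepl("[^ACGT]", kmers)
  pos_by_kmer <- split(starts0[valid], kmers[valid])

  matches <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  add_match <- function(s1, s2, m, orient) {
    s1 <- s1 %% L; s2 <- s2 %% L
    if (orient == "F" && s1 == s2) return(invisible())
    if (s1 > s2) { tmp <- s1; s1 <- s2; s2 <- tmp }
    key <- paste(s1, s2, m, orient, sep = ":")
    if (!is.null(seen[[key]])) return(invisible())
    assign(key, TRUE, envir = seen)
    matches[[length(matches) + 1L]] <<-
      data.frame(start1 = s1, end1 = s1 + m, start2 = s2, end2 = s2 + m,
                 length = m, orientation = orient)
    invisible()
  }
  at <- function(i) enc[(i %% L) + 1L]

  # ---- forward (direct) matches -------------------------------------------
  multi <- pos_by_kmer[lengths(pos_by_kmer) >= 2L]
  if (length(multi)) {
    di <- dj <- integer(0)
    for (p in multi) {
      cmb <- utils::combn(p, 2L)
      di <- c(di, cmb[1L, ]); dj <- c(dj, cmb[2L, ])
    }
    d <- (dj - di) %% L
    for (dg in split(seq_along(d), d)) {
      i <- sort(di[dg])
      reps <- i[c(TRUE, diff(i) > 1L)]
      for (i0 in reps) {
        j0 <- (i0 + d[dg[1L]]) %% L
        # extend right
        m <- k
        while (m < L && at(i0 + m) != 0L && at(i0 + m) == at(j0 + m)) m <- m + 1L
        # extend left
        while (m < L && at(i0 - 1L) != 0L && at(i0 - 1L) == at(j0 - 1L)) {
          i0 <- i0 - 1L; j0 <- j0 - 1L; m <- m + 1L
        }
        if (m >= min_len) add_match(i0, j0, m, "F")
      }
    }
  }

  # ---- inverted (reverse-complement) matches ------------------------------
  rc_kmers <- rev_comp(names(pos_by_kmer))
  hit <- rc_kmers %in% names(pos_by_kmer)
  if (any(hit)) {
    ii <- jj <- integer(0)
    for (idx in which(hit)) {
      pi <- pos_by_kmer[[idx]]
      pj <- pos_by_kmer[[rc_kmers[idx]]]
      grid <- expand.grid(i = pi, j = pj)
      keep <- grid$i <= grid$j   # unordered; palindromic self-seed allowed
      ii <- c(ii, grid$i[keep]); jj <- c(jj, grid$j[keep])
    }
    if (length(ii)) {
      a <- (ii + jj) %% L
      for (ag in split(seq_along(a), a)) {
        ord <- order(ii[ag])
        iv <- ii[ag][ord]; jv <- jj[ag][ord]
        reps <- c(TRUE, diff(iv) > 1L)
        for (t in which(reps)) {
          i0 <- iv[t]; j0 <- jv[t]; m <- k
          # copy1 [i0,i0+m) == revcomp(copy2 [j0,j0+m))
          # grow copy1 right / copy2 left
          while (m < L && at(i0 + m) != 0L &&
                 at(i0 + m) == comp_code(at(j0 - 1L))) {
            j0 <- j0 - 1L; m <- m + 1L
          }
          # grow copy1 left / copy2 right
          while (m < L && at(i0 - 1L) != 0L &&
                 at(i0 - 1L) == comp_code(at(j0 + m))) {
            i0 <- i0 - 1L; m <- m + 1L
          }
          if (m >= min_len) add_match(i0, j0, m, "R")
        }
      }
    }
  }

  mt <- if (length(matches)) do.call(rbind, matches) else empty_matches()
  repeat_set(genome, min_len, mt)
}

empty_matches <- function() {
  data.frame(start1 = integer(0), end1 = integer(0), start2 = integer(0),
             end2 = integer(0), length = integer(0),
             orientation = character(0))
}

# internal: group maximal pairwise matches into repeat units. Matches sharing
# an identical copy interval belong to one unit; strands are propagated over
# the match graph (forward match = same strand, inverted = flipped). Families
# whose pairwise-maximal lengths disagree are left as separate 2-copy units.
repeat_set <- function(genome, min_len, matches) {
  L <- genome$length
  n <- nrow(matches)
  units <- data.frame(unit_id = character(0), length = integer(0),
                      copy_count = integer(0), sequence = character(0))
  copies <- data.frame(unit_id = character(0), copy = integer(0),
                       start = integer(0), end = integer(0),
                       strand = character(0))
  if (n > 0L) {
    ikey <- function(s, e) paste(s, e, sep = "-")
    k1 <- ikey(matches$start1, matches$end1)
    k2 <- ikey(matches$start2, matches$end2)
    all_iv <- unique(c(k1, k2))
    parent <- seq_along(all_iv); names(parent) <- all_iv
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n)) {
      a <- find(match(k1[i], all_iv)); b <- find(match(k2[i], all_iv))
      if (a != b) parent[b] <- a
    }
    comp <- vapply(seq_along(all_iv), function(i) find(i), 1L)
    groups <- split(seq_along(all_iv), comp)

    unit_list <- list()
    for (g in groups) {
      ivs <- all_iv[g]
      midx <- which(k1 %in% ivs | k2 %in% ivs)
      lens <- unique(matches$length[midx])
      if (length(lens) > 1L) {
        # inconsistent family: keep each match as its own unit
        for (mi in midx) {
          unit_list[[length(unit_list) + 1L]] <-
            list(ivs = c(k1[mi], k2[mi]), midx = mi)
        }
      } else {
        unit_list[[length(unit_list) + 1L]] <- list(ivs = ivs, midx = midx)
      }
    }

    built <- lapply(unit_list, function(u) {
      iv <- unique(u$ivs)
      parts <- do.call(rbind, strsplit(iv, "-", fixed = TRUE))
      st <- as.integer(parts[, 1L]); en <- as.integer(parts[, 2L])
      ord <- order(st, en)
      st <- st[ord]; en <- en[ord]; iv <- iv[ord]
      # strand propagation from the reference copy (leftmost, '+')
      strand <- rep(NA_character_, length(iv)); strand[1L] <- "+"
      repeat {
        progressed <- FALSE
        for (mi in u$midx) {
          a <- match(paste(matches$start1[mi], matches$end1[mi], sep = "-"), iv)
          b <- match(paste(matches$start2[mi], matches$end2[mi], sep = "-"), iv)
          if (is.na(a) || is.na(b)) next
          flip <- matches$orientation[mi] == "R"
          if (!is.na(strand[a]) && is.na(strand[b])) {
            strand[b] <- if (flip) flip_strand(strand[a]) else strand[a]
            progressed <- TRUE
          } else if (!is.na(strand[b]) && is.na(strand[a])) {
            strand[a] <- if (flip) flip_strand(strand[b]) else strand[b]
            progressed <- TRUE
          }
        }
        if (!progressed) break
      }
      strand[is.na(strand)] <- "+"
      seq0 <- genome_subseq(genome, st[1L] %% L, en[1L] %% L, strand[1L])
      list(start = st, end = en, strand = strand,
           length = en[1L] - st[1L], sequence = seq0)
    })

    ord <- order(-vapply(built, `[[`, 1L, "length"),
                 vapply(built, function(b) min(b$start), 1L))
    built <- built[ord]
    ids <- paste0("R", seq_along(built))
    units <- do.call(rbind, lapply(seq_along(built), function(i) {
      data.frame(unit_id = ids[i], length = built[[i]]$length,
                 copy_count = length(built[[i]]$start),
                 sequence = built[[i]]$sequence)
    }))
    copies <- do.call(rbind, lapply(seq_along(built), function(i) {
      b <- built[[i]]
      data.frame(unit_id = ids[i], copy = seq_along(b$start),
                 start = b$start, end = b$end, strand = b$strand)
    }))
  }
  structure(list(genome_id = genome$id, genome_length = L, min_len = min_len,
                 units = units, copies = copies, matches = matches),
            class = "repeat_set")
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' @export
print.repeat_set <- function(x, ...) {
  cat(sprintf("<repeat_set> %s (%s bp): %d unit(s), %d copie(s), min_len %d\n",
              x$genome_id, format(x$genome_length, big.mark = ","),
              nrow(x$units), nrow(x$copies), x$min_len))
  if (nrow(x$units)) print(utils::head(x$units, 10L))
  invisible(x)
}

#' Classify repeat copy pairs as direct or inverted
#'
#' Every two-copy unit yields one pair; units with more copies yield all
#' unordered copy pairs. A pair is `direct` when both copies lie on the same
#' strand relative to the canonical unit sequence, `inverted` otherwise.
#' Overlap with copies of other pairs (the shared-bases special case that
#' produces 3+3 conformation sets) is recorded, as is assessability by
#' short reads at the given read geometry.
#'
#' @param repeats a `repeat_set` from [find_repeats()].
#' @param read_len,insert_size,min_anchor read geometry used for the
#'   assessability call; see [assessable_by_short_reads()].
#' @return data frame of class `repeat_pairs` with one row per pair:
#'   `pair_id`, `unit_id`, `length`, `orientation`, copy coordinates
#'   (`a_start`, `a_end`, `a_strand`, `b_start`, `b_end`, `b_strand`),
#'   `overlap_bp`, `overlap_partner`, `assessable`.
#' @export
classify_pairs <- function(repeats, read_len = 150L, insert_size = 300L,
                           min_anchor = 25L) {
  stopifnot(inherits(repeats, "repeat_set"))
  L <- repeats$genome_length
  cp <- repeats$copies
  rows <- list()
  for (u in repeats$units$unit_id) {
    uc <- cp[cp$unit_id == u, , drop = FALSE]
    if (nrow(uc) < 2L) next
    prs <- utils::combn(nrow(uc), 2L)
    multi <- ncol(prs) > 1L
    for (j in seq_len(ncol(prs))) {
      a <- uc[prs[1L, j], ]; b <- uc[prs[2L, j], ]
      pid <- if (multi) sprintf("%s.%d", u, j) else u
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = pid, unit_id = u,
        length = repeats$units$length[repeats$units$unit_id == u],
        orientation = if (a$strand == b$strand) "direct" else "inverted",
        a_start = a$start, a_end = a$end, a_strand = a$strand,
        b_start = b$start, b_end = b$end, b_strand = b$strand,
        overlap_bp = 0L, overlap_partner = NA_character_,
        assessable = NA)
    }
  }
  if (!length(rows)) {
    out <- data.frame(pair_id = character(0), unit_id = character(0),
                      length = integer(0), orientation = character(0),
                      a_start = integer(0), a_end = integer(0),
                      a_strand = character(0), b_start = integer(0),
                      b_end = integer(0), b_strand = character(0),
                      overlap_bp = integer(0),
                      overlap_partner = character(0), assessable = logical(0))
    class(out) <- c("repeat_pairs", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)

  covered <- function(s, e) (seq.int(s, e - 1L)) %% L
  for (i in seq_len(nrow(out))) {
    best <- 0L; partner <- NA_character_
    ci <- list(covered(out$a_start[i], out$a_end[i]),
               covered(out$b_start[i], out$b_end[i]))
    # palindromic / tandem self-overlap of the pair's own copies
    self_ov <- length(intersect(ci[[1L]], ci[[2L]]))
    if (self_ov > 0L) { best <- self_ov; partner <- out$pair_id[i] }
    for (j in seq_len(nrow(out))) {
      if (j == i) next
      cj <- list(covered(out$a_start[j], out$a_end[j]),
                 covered(out$b_start[j], out$b_end[j]))
      ov <- max(length(intersect(ci[[1L]], cj[[1L]])),
                length(intersect(ci[[1L]], cj[[2L]])),
                length(intersect(ci[[2L]], cj[[1L]])),
                length(intersect(ci[[2L]], cj[[2L]])))
      if (ov > best) { best <- ov; partner <- out$pair_id[j] }
    }
    out$overlap_bp[i] <- best
    out$overlap_partner[i] <- partner
  }
  out$assessable <- vapply(out$length, function(l) {
    assessable_by_short_reads(l, read_len, insert_size, min_anchor)$assessable
  }, TRUE)
  rownames(out) <- NULL
  class(out) <- c("repeat_pairs", "data.frame")
  out
}

#' Genome-wide repeat summary
#'
#' Repetitive bp is the size of the union of all copy intervals: a base that
#' belongs to two or more copies is counted once. GC content is computed over
#' unambiguous bases only.
#'
#' @param genome a [circular_genome()].
#' @param repeats a `repeat_set` from [find_repeats()].
#' @return list with `n_units`, `n_copies`, `repetitive_bp`,
#'   `repeat_fraction`, `gc_content`, `genome_length`.
#' @export
repeat_summary <- function(genome, repeats) {
  stopifnot(inherits(genome, "circular_genome"),
            inherits(repeats, "repeat_set"))
  L <- genome$length
  mask <- logical(L)
  cp <- repeats$copies
  if (nrow(cp)) {
    for (i in seq_len(nrow(cp))) {
      mask[(seq.int(cp$start[i], cp$end[i] - 1L) %% L) + 1L] <- TRUE
    }
  }
  enc <- encode_bases(genome$seq)
  acgt <- sum(enc != 0L)
  gc <- if (acgt > 0L) sum(enc == 2L | enc == 3L) / acgt else NA_real_
  list(n_units = nrow(repeats$units), n_copies = nrow(repeats$copies),
       repetitive_bp = sum(mask), repeat_fraction = sum(mask) / L,
       gc_content = gc, genome_length = L)
}
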