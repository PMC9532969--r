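#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' sequencing design the package targets: 150 bp paired-end reads at a
#' 300 bp insert, on a mitogenome-like background of ~43% GC. All
#' randomness in [generate_genome()] and [simulate_reads()] flows from the
#' single `seed`.
#'
#' @param genome_length circle length in bp.
#' @param repeats list of planted repeat specs, each a list with `length`
#'   (bp), `orientation` (`"direct"`/`"inverted"`) and optional `overlap_bp`
#'   (shared bases between this unit's second copy and the previous unit's
#'   second copy, producing the 3+3 special case).
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment length distribution in bp.
#' @param n_pairs number of read pairs to simulate.
#' @param error_rate per-base substitution probability (substitutions only;
#'   the assignment engine is gapless).
#' @param recombined_fraction molar fraction `f` of recombined molecules in
#'   the sampled population; under symmetric discriminability this equals
#'   the expected assignment frequency.
#' @param decoy_fraction fraction of read pairs drawn from a plastid-like
#'   decoy circle.
#' @param decoy_length decoy circle length in bp.
#' @param gc background GC content.
#' @param min_len repeat-detection floor used when verifying the planted
#'   genome.
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 10000L,
                       repeats = list(list(length = 200L,
                                           orientation = "direct")),
                       read_length = 150L, insert_mean = 300L,
                       insert_sd = 30, n_pairs = 5000L, error_rate = 0,
                       recombined_fraction = 0.5, decoy_fraction = 0,
                       decoy_length = 3000L, gc = 0.43, min_len = 30L,
                       seed = 1L) {
  stopifnot(recombined_fraction >= 0, recombined_fraction <= 1,
            decoy_fraction >= 0, decoy_fraction <= 1,
            error_rate >= 0, error_rate < 1, gc > 0, gc < 1)
  for (r in repeats) {
    stopifnot(is.numeric(r$length),
              r$orientation %in% c("direct", "inverted"))
  }
  structure(list(genome_length = as.integer(genome_length),
                 repeats = repeats, read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 n_pairs = as.integer(n_pairs), error_rate = error_rate,
                 recombined_fraction = recombined_fraction,
                 decoy_fraction = decoy_fraction,
                 decoy_length = as.integer(decoy_length),
                 gc = gc, min_len = as.integer(min_len),
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_seq <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Generate a circular genome with planted repeats
#'
#' Builds a uniform-random background at the configured GC and plants each
#' repeat as two copies (the second reverse-complemented for inverted
#' pairs), with optional copy overlap between consecutive units. Boundary
#' bases flanking each copy are forced to differ between the copies so the
#' planted repeat is maximal exactly as specified, and the result is
#' verified in closed loop with [find_repeats()]: if any accidental repeat
#' of `min_len` or more appears in the background (or a planted repeat is
#' not recovered exactly), the genome is regenerated, up to a bounded number
#' of retries.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [circular_genome()]), `repeats` (the
#'   verified `repeat_set`), `pairs` (ground-truth `repeat_pairs` data frame
#'   from [classify_pairs()]) and `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  specs <- config$repeats
  tot_rep <- sum(vapply(specs, function(r) as.integer(r$length), 1L))
  if (length(specs) && L < 4L * tot_rep)
    stop("genome_length must be at least 4x total planted repeat length")

  for (attempt in seq_len(25L)) {
    g <- try(plant_once(config), silent = TRUE)
    if (inherits(g, "try-error")) next
    rs <- suppressWarnings(find_repeats(g$genome, config$min_len))
    if (planted_ok(rs, g$truth)) {
      pairs <- classify_pairs(rs, read_len = config$read_length,
                              insert_size = config$insert_mean)
      return(list(genome = g$genome, repeats = rs, pairs = pairs,
                  config = config))
    }
  }
  stop("could not generate a genome free of accidental repeats after 25 tries")
}

# one planting attempt; returns genome plus the intended copy intervals
plant_once <- function(config) {
  L <- config$genome_length
  specs <- config$repeats
  if (!length(specs)) {
    return(list(genome = circular_genome("sim", random_seq(L, config$gc)),
                truth = list()))
  }
  unit_seqs <- lapply(specs, function(r) random_seq(r$length, config$gc))

  # assemble placement blocks: first copies are standalone; second copies
  # are chained into one block when overlap_bp links consecutive units
  blocks <- list()   # each: list(seq, members = list(list(unit, start_off, strand)))
  for (i in seq_along(specs)) {
    blocks[[length(blocks) + 1L]] <-
      list(seq = unit_seqs[[i]],
           members = list(list(unit = i, off = 0L, strand = "+")))
  }
  i <- 1L
  while (i <= length(specs)) {
    ov <- if (i > 1L && !is.null(specs[[i]]$overlap_bp))
      as.integer(specs[[i]]$overlap_bp) else 0L
    second <- function(u) {
      s <- unit_seqs[[u]]
      if (specs[[u]]$orientation == "inverted") rev_comp(s) else s
    }
    if (ov > 0L) {
      # append to previous block: overlap the previous unit's second copy
      prev <- blocks[[length(blocks)]]
      if (specs[[i]]$orientation != "direct" ||
          specs[[i - 1L]]$orientation != "direct")
        stop("overlap planting supports direct units")
      s2 <- second(i)
      base <- prev$seq
      if (substr(s2, 1L, ov) != substr(base, nchar(base) - ov + 1L,
                                       nchar(base))) {
        # force the overlap: rewrite the unit's first ov bases to match the
        # previous unit's tail (and patch its first copy to stay identical)
        head_ov <- substr(base, nchar(base) - ov + 1L, nchar(base))
        unit_seqs[[i]] <- paste0(head_ov, substr(unit_seqs[[i]], ov + 1L,
                                                 nchar(unit_seqs[[i]])))
        blocks[[i]]$seq <- unit_seqs[[i]]
        s2 <- unit_seqs[[i]]
      }
      prev$members[[length(prev$members) + 1L]] <-
        list(unit = i, off = nchar(prev$seq) - ov, strand = "+")
      prev$seq <- paste0(prev$seq, substr(s2, ov + 1L, nchar(s2)))
      blocks[[length(blocks)]] <- prev
    } else {
      blocks[[length(blocks) + 1L]] <-
        list(seq = second(i),
             members = list(list(
               unit = i, off = 0L,
               strand = if (specs[[i]]$orientation == "inverted") "-" else "+")))
    }
    i <- i + 1L
  }

  blk_len <- vapply(blocks, function(b) nchar(b$seq), 1L)
  nb <- length(blocks)
  spare <- L - sum(blk_len)
  if (spare < nb * 40L) stop("not enough background between blocks")
  gap <- rep(spare %/% nb, nb)
  gap[nb] <- gap[nb] + spare %% nb

  pieces <- character(0)
  truth <- list()
  pos <- 0L
  for (b in seq_len(nb)) {
    bg <- random_seq(gap[b], config$gc)
    pieces <- c(pieces, bg, blocks[[b]]$seq)
    start <- pos + gap[b]
    for (m in blocks[[b]]$members) {
      u <- m$unit
      truth[[length(truth) + 1L]] <-
        list(unit = u, start = start + m$off,
             end = start + m$off + nchar(unit_seqs[[u]]),
             strand = m$strand)
    }
    pos <- start + nchar(blocks[[b]]$seq)
  }
  seq <- paste(pieces, collapse = "")
  stopifnot(nchar(seq) == L)

  # force maximality: a base just outside one copy must differ from the base
  # the other copy would extend into; only background (unplanted) bases may
  # be rewritten
  seqv <- strsplit(seq, "")[[1]]
  planted <- logical(L)
  for (t in truth)
    planted[(seq.int(t$start, t$end - 1L) %% L) + 1L] <- TRUE
  units <- split(truth, vapply(truth, `[[`, 1L, "unit"))
  for (tu in units) {
    if (length(tu) < 2L) next
    seqv <- break_extension(seqv, L, tu[[1L]], tu[[2L]], planted)
  }
  list(genome = circular_genome("sim", paste(seqv, collapse = "")),
       truth = truth)
}

# rewrite a background base so the exact match between copies a and b cannot
# extend past the planted boundaries; errors when both candidate bases are
# planted (the closed-loop verification then retries with a fresh genome)
break_extension <- function(seqv, L, a, b, planted) {
  at <- function(p) seqv[(p %% L) + 1L]
  is_bg <- function(p) !planted[(p %% L) + 1L]
  put <- function(p, avoid) {
    if (!is_bg(p)) stop("terminator base is planted")
    seqv[(p %% L) + 1L] <<- setdiff(c("A", "C", "G", "T"), avoid)[1L]
  }
  comp1 <- function(x) chartr("ACGT", "TGCA", x)
  # (pa, pb): positions whose equality (under `tr` applied to pb) would let
  # the match extend; rewrite whichever side is background
  fix <- function(pa, pb, tr = identity) {
    if (tr(at(pb)) != at(pa)) return(invisible())
    if (is_bg(pb)) put(pb, c(at(pb), tr(at(pa))))
    else put(pa, c(at(pa), tr(at(pb))))
    invisible()
  }
  if (a$strand == b$strand) {
    fix(a$start - 1L, b$start - 1L)
    fix(a$end, b$end)
  } else {
    # b on '-': left extension of a pairs with right extension of b
    fix(a$start - 1L, b$end, comp1)
    fix(a$end, b$start - 1L, comp1)
  }
  seqv
}

# does the detected repeat set match the planted truth exactly?
planted_ok <- function(rs, truth) {
  if (!length(truth)) return(nrow(rs$units) == 0L)
  exp_units <- split(truth, vapply(truth, `[[`, 1L, "unit"))
  exp_units <- Filter(function(u) length(u) >= 2L, exp_units)
  if (nrow(rs$units) != length(exp_units)) return(FALSE)
  key <- function(s, e) paste(s, e, sep = "-")
  got <- rs$copies
  for (u in exp_units) {
    ek <- sort(vapply(u, function(x) key(x$start, x$end), ""))
    hit <- FALSE
    for (uid in unique(got$unit_id)) {
      gc_ <- got[got$unit_id == uid, ]
      gk <- sort(key(gc_$start, gc_$end))
      if (identical(gk, ek)) { hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Simulate paired-end reads from a conformation mixture
#'
#' Draws sequenced fragments from a molecule population in which a fraction
#' `f` of molecules are the recombination products of `pair` (from
#' [recombine_genome()]) and `1 - f` are the reference circle; fragments are
#' uniform on each molecule, with lengths `Normal(insert_mean, insert_sd)`
#' truncated to `[read_length, molecule length]`. Mate 1 is the first
#' `read_length` bases of the fragment and mate 2 the reverse complement of
#' the last, i.e. standard FR orientation; fragment strand is random.
#' Substitution errors are applied per base at `error_rate`. Optionally a
#' fraction of contaminant pairs is drawn from a plastid-like decoy circle.
#'
#' @param genome a [circular_genome()] (the reference circle).
#' @param pair one row of a `repeat_pairs` data frame; must be assessable at
#'   the configured read geometry when `f > 0`.
#' @param f molar fraction of recombined molecules, in `[0, 1]`.
#' @param config a [sim_config()]; supplies geometry, error rate, decoy
#'   fraction and the seed.
#' @param decoy optional [circular_genome()] used for contaminant pairs;
#'   generated from the config when omitted but required
#'   (`decoy_fraction > 0`).
#' @return list of class `sim_reads`: `reads` (a [read_pairs()] data frame),
#'   `truth` (data frame with the source class of every pair:
#'   `reference`, `recombined` or `decoy`) and `decoy` (the decoy genome or
#'   `NULL`).
#' @export
simulate_reads <- function(genome, pair, f, config, decoy = NULL) {
  stopifnot(inherits(config, "sim_config"), f >= 0, f <= 1)
  pair <- as.list(pair)
  set.seed(config$seed + 1L)
  rl <- config$read_length
  if (f > 0) {
    ok <- assessable_by_short_reads(pair$a_end - pair$a_start,
                                    rl, config$insert_mean)
    if (!ok$assessable)
      stop("recombined reads requested for an unassessable pair: ",
           ok$reason)
  }
  prods <- if (f > 0) recombine_genome(genome, pair)$products else list()
  dc <- config$decoy_fraction
  if (dc > 0 && is.null(decoy)) {
    decoy <- circular_genome("decoy",
                             random_seq(config$decoy_length, config$gc))
  }

  n <- config$n_pairs
  classes <- sample(c("reference", "recombined", "decoy"), n, replace = TRUE,
                    prob = c((1 - dc) * (1 - f), (1 - dc) * f, dc))
  prod_len <- vapply(prods, `[[`, 1L, "length")

  m1 <- m2 <- character(n)
  for (i in seq_len(n)) {
    mol <- switch(classes[i],
      reference = genome,
      recombined = if (length(prods) == 1L) prods[[1L]] else
        prods[[sample.int(length(prods), 1L, prob = prod_len)]],
      decoy = decoy)
    flen <- min(max(rl, round(stats::rnorm(1L, config$insert_mean,
                                           config$insert_sd))),
                mol$length - 1L)
    start <- sample.int(mol$length, 1L) - 1L
    frag <- genome_subseq(mol, start, (start + flen) %% mol$length)
    if (stats::runif(1L) < 0.5) frag <- rev_comp(frag)
    m1[i] <- substr(frag, 1L, rl)
    m2[i] <- rev_comp(substr(frag, flen - rl + 1L, flen))
  }
  if (config$error_rate > 0) {
    m1 <- add_errors(m1, config$error_rate)
    m2 <- add_errors(m2, config$error_rate)
  }
  ids <- sprintf("sim_%06d", seq_len(n))
  structure(list(reads = read_pairs(ids, m1, m2),
                 truth = data.frame(id = ids, source = classes),
                 decoy = decoy),
            class = "sim_reads")
}

# independent per-base substitutions; the substituted base is always
# different from the original
add_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(v)) < rate)
    for (h in hit) {
      v[h] <- sample(setdiff(c("A", "C", "G", "T"), v[h]), 1L)
    }
    paste(v, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("<sim_reads> %d pairs: %s\n", nrow(x$reads),
              paste(names(table(x$truth$source)), table(x$truth$source),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
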