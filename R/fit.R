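#' Estimate repeat-mediated recombination frequencies from paired-end reads
#'
#' The package's top-level fitting function. It runs the whole pipeline on
#' one circular genome: detect maximal exact repeats, classify copy pairs as
#' direct or inverted, build the reference and recombined local
#' conformations (with the 3+3 construction for overlapping pairs), assign
#' read pairs to conformations under the alignment-length, junction-anchor
#' and decoy filters, and estimate the per-pair recombination frequency
#' with a Wilson 95% interval. Pairs whose repeat is too long for the read
#' geometry are reported as unassessable rather than estimated.
#'
#' @param genome a [circular_genome()] or path to a FASTA file with one
#'   record.
#' @param reads a [read_pairs()] data frame, or a character vector of two
#'   FASTQ paths.
#' @param decoys optional [circular_genome()], list of them, or decoy FASTA
#'   path (e.g. the plastid genome) absorbing contaminant reads.
#' @param min_repeat_len only repeat pairs at least this long are assessed
#'   (shorter repeats rarely recombine detectably and flood the report).
#' @param detect_min_len detection floor passed to [find_repeats()].
#' @param flank_len flank length for conformation construction.
#' @param insert_size expected fragment length; used for the assessability
#'   rule.
#' @param min_aln,min_anchor,max_mismatch_rate assignment filters; see
#'   [assign_read_pairs()].
#' @return An object of class `recomb_fit` with components `call`,
#'   `genome_id`, `repeats` (the `repeat_set`), `pairs` (the classified
#'   `repeat_pairs`), `counts` (list of `assignment_counts`), `results`
#'   (list of `recomb_result`) and `table` (a `recomb_report` data frame).
#'   Methods: `print`, `summary`, `coef` (frequencies as fractions),
#'   `confint`, `plot`.
#' @examples
#' cfg <- sim_config(genome_length = 4000, n_pairs = 300, seed = 7,
#'                   repeats = list(list(length = 150, orientation = "direct")))
#' sim <- generate_genome(cfg)
#' rds <- simulate_reads(sim$genome, sim$pairs[1, ], f = 0.5, cfg)
#' fit <- recomb_fit(sim$genome, rds$reads, min_repeat_len = 100)
#' coef(fit)
#' @export
recomb_fit <- function(genome, reads, decoys = NULL, min_repeat_len = 100L,
                       detect_min_len = 30L, flank_len = 300L,
                       insert_size = 300L, min_aln = 100L, min_anchor = 25L,
                       max_mismatch_rate = 0.02) {
  cl <- match.call()
  if (is.character(genome)) genome <- read_fasta(genome)[[1L]]
  if (is.character(reads) && length(reads) == 2L)
    reads <- read_fastq_pair(reads[1L], reads[2L])
  if (is.character(decoys)) decoys <- read_fasta(decoys)
  if (inherits(decoys, "circular_genome")) decoys <- list(decoys)

  read_len <- if (nrow(reads)) max(nchar(reads$mate1)) else 150L
  rs <- find_repeats(genome, detect_min_len)
  pairs <- classify_pairs(rs, read_len = read_len,
                          insert_size = insert_size,
                          min_anchor = min_anchor)
  sel <- pairs[pairs$length >= min_repeat_len, , drop = FALSE]

  counts <- list()
  results <- list()
  done_overlap <- character(0)
  for (i in seq_len(nrow(sel))) {
    p <- sel[i, ]
    if (!p$assessable) {
      results[[p$pair_id]] <- list(
        pair_id = p$pair_id, repeat_length = p$length,
        orientation = p$orientation, assessable = FALSE)
      next
    }
    partner_id <- p$overlap_partner
    if (!is.na(partner_id) && partner_id != p$pair_id &&
        partner_id %in% sel$pair_id) {
      if (p$pair_id %in% done_overlap) next
      q <- sel[sel$pair_id == partner_id, ]
      sets <- build_overlap_conformations(genome, p, q, flank_len)
      for (s in sets) {
        pr <- if (s$pair_id == p$pair_id) p else q
        ac <- assign_read_pairs(reads, s, decoys, min_aln, min_anchor,
                                max_mismatch_rate)
        counts[[s$pair_id]] <- ac
        results[[s$pair_id]] <- recombination_frequency(
          ac, repeat_length = pr$length, orientation = pr$orientation)
      }
      done_overlap <- c(done_overlap, p$pair_id, partner_id)
    } else {
      cs <- build_conformations(genome, p, flank_len, repeats = rs)
      ac <- assign_read_pairs(reads, cs, decoys, min_aln, min_anchor,
                              max_mismatch_rate)
      counts[[p$pair_id]] <- ac
      results[[p$pair_id]] <- recombination_frequency(
        ac, repeat_length = p$length, orientation = p$orientation)
    }
  }
  structure(list(call = cl, genome_id = genome$id, repeats = rs,
                 pairs = pairs, counts = counts, results = results,
                 table = report_table(unname(results))),
            class = "recomb_fit")
}

#' @export
print.recomb_fit <- function(x, ...) {
  cat("Repeat-mediated recombination fit\n")
  cat(sprintf("genome: %s | %d repeat pair(s) assessed\n\n", x$genome_id,
              length(x$counts)))
  print(x$table)
  invisible(x)
}

#' @export
summary.recomb_fit <- function(object, ...) {
  res <- Filter(function(r) !identical(r$assessable, FALSE), object$results)
  n_disc <- vapply(res, function(r) r$Nref + r$Nrec, 1)
  cat("Repeat-mediated recombination fit\n")
  cat(sprintf("genome %s: %d repeat unit(s) detected, %d pair(s) assessed, %d unassessable\n",
              object$genome_id, nrow(object$repeats$units), length(res),
              length(object$results) - length(res)))
  if (length(res)) {
    cat(sprintf("discriminative pairs per repeat: median %.0f (range %.0f-%.0f)\n",
                stats::median(n_disc), min(n_disc), max(n_disc)))
    dev <- vapply(res, function(r) abs(r$frequency - 0.5), 1)
    cat(sprintf("largest deviation from equimolar (50%%): %.1f points\n",
                100 * max(dev)))
  }
  cat("\n")
  print(object$table)
  invisible(object)
}

#' @export
coef.recomb_fit <- function(object, ...) {
  res <- Filter(function(r) !identical(r$assessable, FALSE), object$results)
  stats::setNames(vapply(res, `[[`, 1, "frequency"),
                  vapply(res, `[[`, "", "pair_id"))
}

#' @export
confint.recomb_fit <- function(object, parm, level = 0.95, ...) {
  res <- Filter(function(r) !identical(r$assessable, FALSE), object$results)
  m <- t(vapply(res, function(r) {
    if (level != 0.95 && !is.na(r$frequency)) {
      ci <- suppressWarnings(
        stats::prop.test(r$Nrec, r$Nref + r$Nrec, correct = FALSE,
                         conf.level = level))$conf.int
      c(ci[1L], ci[2L])
    } else c(r$ci_low, r$ci_high)
  }, c(0, 0)))
  rownames(m) <- vapply(res, `[[`, "", "pair_id")
  colnames(m) <- sprintf("%g %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
plot.recomb_fit <- function(x, ...) {
  f <- coef(x)
  if (!length(f)) {
    warning("nothing to plot: no assessable pairs")
    return(invisible(x))
  }
  ci <- confint(x)
  idx <- seq_along(f)
  graphics::plot(idx, 100 * f, ylim = c(0, 100), xaxt = "n",
                 xlab = "repeat pair", ylab = "recombination frequency (%)",
                 pch = 19, ...)
  graphics::axis(1, at = idx, labels = names(f))
  graphics::segments(idx, 100 * ci[, 1L], idx, 100 * ci[, 2L])
  graphics::abline(h = 50, lty = 2, col = "grey40")
  invisible(x)
}
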