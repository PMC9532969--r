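#' Recombination frequency of a repeat pair
#'
#' The frequency is the fraction of conformation-discriminating read pairs
#' that support recombined conformations,
#' `(Nab + Nba) / (Nab + Nba + Naa + Nbb)` — equivalently
#' `Nrec / (Nref + Nrec)` when per-member counts are summed by kind, as is
#' done for overlapping pairs with 3+3 member sets. A value near 50%
#' indicates recombinational equilibrium (equimolar stoichiometry of the
#' alternative conformations). A Wilson 95% score interval is attached:
#' count-based proportions need an uncertainty statement and the Wilson
#' interval behaves at the 0 and 1 extremes.
#'
#' @param counts an `assignment_counts` object from [assign_read_pairs()],
#'   or `NULL` if `Naa`/`Nbb`/`Nab`/`Nba` (or `Nref`/`Nrec`) are given
#'   directly.
#' @param Naa,Nbb,Nab,Nba per-conformation support counts.
#' @param Nref,Nrec summed reference/recombined support (used for
#'   overlapping pairs whose member counts are reported summed).
#' @param conf_level confidence level of the Wilson interval.
#' @param pair_id,repeat_length,orientation optional annotation carried into
#'   the result.
#' @return An object of class `recomb_result`: list with `pair_id`,
#'   `repeat_length`, `orientation`, `Nref`, `Nrec`, `frequency` (fraction;
#'   `NA` with a warning when no read supports any conformation), `ci_low`,
#'   `ci_high`, `assessable` and the filter tallies when `counts` was given.
#' @examples
#' r <- recombination_frequency(Naa = 235, Nbb = 206, Nab = 167, Nba = 163)
#' round(100 * r$frequency, 1)  # 42.8
#' @export
recombination_frequency <- function(counts = NULL, Naa = NULL, Nbb = NULL,
                                    Nab = NULL, Nba = NULL, Nref = NULL,
                                    Nrec = NULL, conf_level = 0.95,
                                    pair_id = NA_character_,
                                    repeat_length = NA_integer_,
                                    orientation = NA_character_) {
  tallies <- list()
  if (!is.null(counts)) {
    stopifnot(inherits(counts, "assignment_counts"))
    pair_id <- counts$pair_id
    Nref <- sum(counts$counts[counts$kinds == "reference"])
    Nrec <- sum(counts$counts[counts$kinds == "recombined"])
    if (all(c("aa", "bb", "ab", "ba") %in% names(counts$counts))) {
      Naa <- unname(counts$counts["aa"]); Nbb <- unname(counts$counts["bb"])
      Nab <- unname(counts$counts["ab"]); Nba <- unname(counts$counts["ba"])
    }
    tallies <- counts[c("n_ambiguous", "n_filtered_short",
                        "n_filtered_decoy", "n_unmapped", "n_total")]
  } else if (is.null(Nref) || is.null(Nrec)) {
    stopifnot(!is.null(Naa), !is.null(Nbb), !is.null(Nab), !is.null(Nba))
    Nref <- Naa + Nbb
    Nrec <- Nab + Nba
  }
  if (any(c(Nref, Nrec) < 0)) stop("support counts must be non-negative")
  n <- Nref + Nrec
  if (n == 0) {
    warning("no read pair supports any conformation; frequency is NA")
    freq <- ci <- c(NA_real_, NA_real_)
    res <- list(frequency = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  } else {
    # only the Wilson interval is used; the chi-squared warning concerns the
    # test p-value and is irrelevant here
    ci <- suppressWarnings(stats::prop.test(Nrec, n, correct = FALSE,
                                            conf.level = conf_level))$conf.int
    res <- list(frequency = Nrec / n, ci_low = ci[1L], ci_high = ci[2L])
  }
  structure(c(list(pair_id = pair_id, repeat_length = repeat_length,
                   orientation = orientation,
                   Naa = if (is.null(Naa)) NA_integer_ else Naa,
                   Nbb = if (is.null(Nbb)) NA_integer_ else Nbb,
                   Nab = if (is.null(Nab)) NA_integer_ else Nab,
                   Nba = if (is.null(Nba)) NA_integer_ else Nba,
                   Nref = Nref, Nrec = Nrec),
              res, list(assessable = TRUE), tallies),
            class = "recomb_result")
}

#' @export
print.recomb_result <- function(x, ...) {
  if (is.na(x$frequency)) {
    cat(sprintf("<recomb_result> %s: no supporting read pairs\n", x$pair_id))
  } else {
    cat(sprintf(
      "<recomb_result> %s: %.1f%% recombined (Nref=%d, Nrec=%d, 95%% CI %.1f-%.1f%%)\n",
      x$pair_id, 100 * x$frequency, x$Nref, x$Nrec,
      100 * x$ci_low, 100 * x$ci_high))
  }
  invisible(x)
}

#' Tabulate recombination results across repeat pairs
#'
#' Produces the per-pair report: support counts (per-conformation where
#' available, summed reference/recombined otherwise), frequency as a
#' percentage to one decimal, and the Wilson interval. Pairs flagged
#' unassessable (e.g. repeats far exceeding the fragment span) appear as
#' status rows without a frequency.
#'
#' @param results list of `recomb_result` objects; entries may also be lists
#'   with `pair_id`, `repeat_length`, `orientation` and
#'   `assessable = FALSE` for unassessable pairs.
#' @return data frame of class `recomb_report` with columns `pair`,
#'   `length_bp`, `type`, `Naa`, `Nbb`, `Nab`, `Nba`, `Nref`, `Nrec`,
#'   `frequency_pct`, `ci_low_pct`, `ci_high_pct`, `status`.
#' @export
report_table <- function(results) {
  cols <- function(r) {
    r <- as.list(r)
    assess <- !identical(r$assessable, FALSE)
    g <- function(f, d) if (is.null(r[[f]]) || length(r[[f]]) == 0L) d else r[[f]]
    data.frame(
      pair = g("pair_id", NA_character_),
      length_bp = g("repeat_length", NA_integer_),
      type = g("orientation", NA_character_),
      Naa = g("Naa", NA_integer_), Nbb = g("Nbb", NA_integer_),
      Nab = g("Nab", NA_integer_), Nba = g("Nba", NA_integer_),
      Nref = g("Nref", NA_integer_), Nrec = g("Nrec", NA_integer_),
      frequency_pct = if (assess) round(100 * g("frequency", NA_real_), 1)
                      else NA_real_,
      ci_low_pct = if (assess) round(100 * g("ci_low", NA_real_), 1)
                   else NA_real_,
      ci_high_pct = if (assess) round(100 * g("ci_high", NA_real_), 1)
                    else NA_real_,
      status = if (assess) "assessed" else "unassessable by short reads")
  }
  out <- if (length(results)) do.call(rbind, lapply(results, cols))
         else cols(list())[0L, ]
  rownames(out) <- NULL
  class(out) <- c("recomb_report", "data.frame")
  out
}

#' @export
print.recomb_report <- function(x, ...) {
  cat("Repeat-mediated recombination report\n")
  NextMethod()
  invisible(x)
}
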