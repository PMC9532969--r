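#' Circular genome container
#'
#' Holds a single nucleotide sequence together with a circularity flag.
#' Plant mitogenomes typically map as circles, so all downstream coordinate
#' arithmetic in this package is wrap-aware: positions are 0-based, intervals
#' half-open, and an interval whose end precedes its start runs through the
#' origin.
#'
#' @param id character label for the molecule.
#' @param seq nucleotide string; uppercased on construction. IUPAC codes are
#'   accepted, but anything outside A/C/G/T never matches in repeat seeding
#'   or read alignment.
#' @param circular logical; `TRUE` for the mitogenome use case.
#' @return An object of class `circular_genome` with fields `id`, `seq`,
#'   `length` and `circular`.
#' @examples
#' g <- circular_genome("toy", "ACGTACGT")
#' g$length
#' @export
circular_genome <- function(id, seq, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("genome sequence must contain at least one base")
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", seq)
  if (nchar(bad) > 0L) {
    stop("illegal characters in sequence '", id, "': ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  structure(list(id = id, seq = seq, length = nchar(seq),
                 circular = isTRUE(circular)),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp (%s)\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Reverse complement of nucleotide strings
#'
#' Vectorised over its input; IUPAC ambiguity codes are complemented to their
#' IUPAC counterparts.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @examples
#' rev_comp("ACGT")  # "ACGT"
#' @export
rev_comp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgt", "TGCAYRSWMKVHDBNtgca", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), "",
         USE.NAMES = FALSE)
}

#' Wrap-aware subsequence extraction
#'
#' Extracts `[start, end)` in 0-based half-open coordinates on the forward
#' strand of the deposited sequence. On a circular genome, `start > end`
#' wraps through the origin; the extracted length is always
#' `(end - start) mod length`, so `start == end` yields the empty string.
#'
#' @param genome a [circular_genome()].
#' @param start,end 0-based half-open bounds, each in `[0, 2*length)`.
#' @param strand `"+"` or `"-"`; minus returns the reverse complement.
#' @return nucleotide string.
#' @examples
#' g <- circular_genome("m", "ACGTAC")
#' genome_subseq(g, 4, 2)        # wraps: "ACAC"
#' genome_subseq(g, 1, 3, "-")   # rev comp of "CG"
#' @export
genome_subseq <- function(genome, start, end, strand = "+") {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length
  if (start < 0 || end < 0 || start >= 2 * L || end >= 2 * L)
    stop("start/end must lie in [0, 2*length)")
  s <- start %% L
  e <- end %% L
  if (!genome$circular && s > e)
    stop("start > end on a non-circular genome")
  len <- (e - s) %% L
  if (len == 0L) return("")
  out <- substr(paste0(genome$seq, substr(genome$seq, 1L, len)),
                s + 1L, s + len)
  if (strand == "-") rev_comp(out) else out
}

#' Rotate a circular genome
#'
#' Returns the genome re-linearised so that old position `k` becomes the new
#' origin. Rotation is a no-op on the molecule itself; it only changes the
#' arbitrary linearisation point.
#'
#' @param genome a [circular_genome()].
#' @param k 0-based position to become the new origin.
#' @return a [circular_genome()].
#' @export
rotate_genome <- function(genome, k) {
  stopifnot(inherits(genome, "circular_genome"), genome$circular)
  L <- genome$length
  k <- k %% L
  if (k == 0L) return(genome)
  circular_genome(genome$id,
                  paste0(substr(genome$seq, k + 1L, L),
                         substr(genome$seq, 1L, k)),
                  circular = TRUE)
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA file.
#' @param circular logical; applied to every record (circularity is a
#'   property of the molecule, not of the file format).
#' @return list of [circular_genome()], one per record, in file order. An
#'   empty file yields an empty list with a warning.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (file.size(path) == 0L || !any(nzchar(lines))) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  is_seq <- !startsWith(lines, ">")
  bad <- which(is_seq & grepl("[^ACGTNRYSWKMBDHVacgtnryswkmbdhv ]", lines))
  if (length(bad)) {
    stop("malformed FASTA '", path, "': illegal sequence characters at line ",
         bad[1L], call. = FALSE)
  }
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    circular_genome(ids[i], as.character(set[[i]]), circular = circular)
  })
}

#' Write genomes to a FASTA file
#'
#' @param genomes a [circular_genome()] or list of them.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "circular_genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(set) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Paired-end read container
#'
#' A data frame with one row per read pair. `mate2` is stored in sequencing
#' orientation (as it comes off the machine); the assignment engine
#' reverse-complements internally as needed.
#'
#' @param id character vector of pair identifiers.
#' @param mate1,mate2 character vectors of read sequences.
#' @return data.frame of class `read_pairs` with columns `id`, `mate1`,
#'   `mate2`.
#' @export
read_pairs <- function(id, mate1, mate2) {
  stopifnot(length(id) == length(mate1), length(mate1) == length(mate2))
  if (length(mate1) && (any(!nzchar(mate1)) || any(!nzchar(mate2))))
    stop("read mates must be non-empty")
  structure(data.frame(id = as.character(id), mate1 = toupper(mate1),
                       mate2 = toupper(mate2), stringsAsFactors = FALSE),
            class = c("read_pairs", "data.frame"))
}

#' Read a pair of FASTQ files
#'
#' Files must list mates in matched record order (the usual `_1`/`_2`
#' convention). Base qualities are parsed by the reader but not retained:
#' assignment does not use them.
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return a [read_pairs()] data frame.
#' @export
read_fastq_pair <- function(path1, path2) {
  s1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(s1) != length(s2))
    stop("FASTQ files have different record counts: ",
         length(s1), " vs ", length(s2))
  ids <- sub("\\s.*$", "", names(s1))
  ids <- sub("/[12]$", "", ids)
  read_pairs(ids, as.character(s1), as.character(s2))
}

#' Write paired reads to two FASTQ files
#'
#' Qualities are emitted as a constant high score (`I`, Phred 40), matching
#' the simulator's substitution-only error model.
#'
#' @param reads a [read_pairs()] data frame.
#' @param path1,path2 output FASTQ files.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pair <- function(reads, path1, path2) {
  emit <- function(seqs, ids, path) {
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  }
  emit(reads$mate1, reads$id, path1)
  emit(reads$mate2, reads$id, path2)
  invisible(c(path1, path2))
}

#' Write repeat copies to a BED file
#'
#' BED is 0-based half-open, matching the package's internal convention.
#' Copies that run through the origin are split at the origin into two
#' features with the same name.
#'
#' @param repeats a `repeat_set` from [find_repeats()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(repeats, path) {
  stopifnot(inherits(repeats, "repeat_set"))
  cp <- repeats$copies
  L <- repeats$genome_length
  rows <- lapply(seq_len(nrow(cp)), function(i) {
    s <- cp$start[i] %% L; e <- cp$end[i]
    len <- e - cp$start[i]
    name <- sprintf("%s_%s", cp$unit_id[i], letters[cp$copy[i]])
    if (s + len <= L) {
      data.frame(chrom = repeats$genome_id, start = s, end = s + len,
                 name = name, score = len, strand = cp$strand[i])
    } else {
      data.frame(chrom = repeats$genome_id,
                 start = c(s, 0L), end = c(L, (s + len) %% L),
                 name = name, score = len, strand = cp$strand[i])
    }
  })
  bed <- do.call(rbind, rows)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# internal: integer encoding for fast base comparison; anything outside
# A/C/G/T (including N) gets code 0 and never matches, per the package rule
# that ambiguous bases are mismatch-to-everything.
encode_bases <- function(seq) {
  v <- utf8ToInt(seq)
  out <- integer(length(v))
  out[v == 65L] <- 1L  # A
  out[v == 67L] <- 2L  # C
  out[v == 71L] <- 3L  # G
  out[v == 84L] <- 4L  # T
  out
}

# complement codes under the same encoding (0 stays 0)
comp_code <- function(code) c(0L, 4L, 3L, 2L, 1L)[code + 1L]

# is string a a rotation of string b
is_rotation <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
}
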