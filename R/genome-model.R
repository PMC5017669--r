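#' Build a reference-sequence table
#'
#' References are plain tibbles throughout the package: one row per sequence,
#' with a species tag separating host from each named virus and a role tag
#' separating genome, transcriptome and pre-miRNA sequences. Coordinates on
#' these references are always 1-based, inclusive, and expressed on the plus
#' strand; a minus-strand feature's 5' end is its largest plus-strand
#' coordinate.
#'
#' @param id Character vector of sequence labels.
#' @param sequence Character vector of nucleotide strings over \{A,C,G,T,N\}
#'   (lowercase accepted, U converted to T, other IUPAC letters collapsed
#'   to N with a warning).
#' @param species Species tag per sequence: `"host"` or a virus name.
#' @param role One of `"genome"`, `"transcriptome"`, `"pre_mirna"` per
#'   sequence.
#' @return A tibble with columns `id`, `sequence`, `length`, `species`,
#'   `role`.
#' @examples
#' reference_set("chrTest", "ACGTACGT", species = "host", role = "genome")
#' @export
reference_set <- function(id, sequence, species, role) {
  stopifnot(length(id) == length(sequence), !anyDuplicated(id))
  sequence <- normalize_sequence(sequence)
  role <- match_role(role, length(id))
  species <- rep_len(species, length(id))
  tibble::tibble(
    id = as.character(id),
    sequence = sequence,
    length = nchar(sequence),
    species = species,
    role = role
  )
}

match_role <- function(role, n) {
  role <- rep_len(role, n)
  ok <- role %in% c("genome", "transcriptome", "pre_mirna")
  if (!all(ok)) stop("role must be genome, transcriptome or pre_mirna",
                     call. = FALSE)
  role
}

normalize_sequence <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  sequence <- chartr("U", "T", sequence)
  other <- grepl("[^ACGTN]", sequence)
  if (any(other)) {
    warning(sum(other), " sequence(s) contain non-ACGTN IUPAC letters; ",
            "collapsed to N (N never matches during alignment)",
            call. = FALSE)
    sequence[other] <- gsub("[^ACGTN]", "N", sequence[other])
  }
  if (any(nchar(sequence) == 0)) stop("empty sequence", call. = FALSE)
  sequence
}

#' Load references from a FASTA file
#'
#' Reads a multi-record FASTA and returns a reference tibble (see
#' [reference_set()]). Sequences are uppercased, U is converted to T, and
#' IUPAC ambiguity letters other than N are collapsed to N with a warning.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param species Species tag applied to every record.
#' @param role Role tag applied to every record.
#' @return A reference tibble.
#' @export
read_reference_fasta <- function(path, species = "host", role = "genome") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) stop("FASTA file has no records: ", path,
                              call. = FALSE)
  ids <- sub("\\s.*$", "", names(recs))
  reference_set(ids, as.character(recs), species = species, role = role)
}

#' Write a reference tibble to FASTA
#'
#' @param references Reference tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(references, path) {
  x <- Biostrings::DNAStringSet(references$sequence)
  names(x) <- references$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Reverse complement of nucleotide strings
#'
#' Vectorised; N maps to N.
#'
#' @param seq Character vector over \{A,C,G,T,N\}.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement(c("ACGT", "AAACC"))
#' @export
reverse_complement <- function(seq) {
  check_dna(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Detect terminal repeats of a genome
#'
#' Finds the maximal terminal pair of length at least `min_len` in which the
#' genome's prefix equals its suffix (`identical` relation, a direct terminal
#' repeat) or equals the reverse complement of its suffix
#' (`reverse_complement` relation, an inverted terminal repeat such as the
#' palindromic ~145-nt ITRs flanking parvovirus genomes). Both relations are
#' reported when both hold. The relation is verified by direct substring
#' comparison on the reference.
#'
#' @param genome A one-row reference tibble (or a reference tibble; the
#'   first row is used).
#' @param min_len Minimum repeat length to report (>= 10).
#' @return A tibble with columns `ref_id`, `start_a`, `end_a`, `start_b`,
#'   `end_b`, `relation`; zero rows if no terminal relation of length
#'   `min_len` or more exists. Intervals are 1-based inclusive and of equal
#'   width.
#' @export
annotate_terminal_repeats <- function(genome, min_len = 50) {
  stopifnot(is.data.frame(genome), nrow(genome) >= 1, min_len >= 10)
  s <- genome$sequence[[1]]
  id <- genome$id[[1]]
  L <- nchar(s)
  max_k <- L %/% 2L
  out <- list()
  if (max_k >= min_len) {
    for (rel in c("identical", "reverse_complement")) {
      for (k in seq(max_k, min_len)) {
        prefix <- substr(s, 1L, k)
        suffix <- substr(s, L - k + 1L, L)
        hit <- if (rel == "identical") prefix == suffix
               else prefix == reverse_complement(suffix)
        if (hit) {
          out[[length(out) + 1L]] <- tibble::tibble(
            ref_id = id, start_a = 1L, end_a = k,
            start_b = L - k + 1L, end_b = L, relation = rel)
          break
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(ref_id = character(), start_a = integer(),
                          end_a = integer(), start_b = integer(),
                          end_b = integer(), relation = character()))
  }
  dplyr::bind_rows(out)
}
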