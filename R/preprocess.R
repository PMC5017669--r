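#' Trim the 3' sequencing adapter from reads
#'
#' Scans each read left to right for the first position at which a prefix of
#' the adapter matches the window running from that position towards the
#' read end: the overlap must be at least `min_overlap` bases with at most
#' `max_mm` mismatches, and the window is truncated at the read end so that
#' partial adapter read-through at the 3' end is still recognised.
#' Everything from the match position onward is removed; reads with no
#' qualifying match are returned unchanged. Trimming never lengthens a read
#' and is idempotent when the trimmed read holds no further adapter match.
#'
#' @param reads Tibble with a `sequence` column (other columns pass
#'   through).
#' @param adapter 3' adapter; must be at least `min_overlap` long.
#' @param min_overlap Minimum read/adapter overlap (nt).
#' @param max_mm Maximum mismatches tolerated in the overlap.
#' @return The input tibble with `sequence` trimmed (possibly to "").
#' @export
trim_adapter <- function(reads, adapter = TRUSEQ_3P_ADAPTER,
                         min_overlap = 8, max_mm = 1) {
  stopifnot(is.data.frame(reads), nchar(adapter) >= min_overlap)
  keep <- cpp_trim_lengths(reads$sequence, adapter, as.integer(min_overlap),
                           as.integer(max_mm))
  dplyr::mutate(reads, sequence = substr(.data$sequence, 1L, keep))
}

#' Discard reads below a minimum length
#'
#' Reads shorter than `min_len` (after adapter trimming) are discarded; the
#' boundary is inclusive, so a `min_len`-nt read is kept. The discarded
#' count feeds the summary table's ">= 16 nt" accounting.
#'
#' @param reads Tibble with a `sequence` column.
#' @param min_len Minimum kept length (nt).
#' @return List with `kept` (tibble) and `n_discarded` (integer).
#' @export
filter_min_length <- function(reads, min_len = 16) {
  stopifnot(min_len >= 1)
  ok <- nchar(reads$sequence) >= min_len
  list(kept = reads[ok, , drop = FALSE], n_discarded = sum(!ok))
}

#' Collapse identical read sequences
#'
#' Exact-sequence deduplication preserving total multiplicity; output is
#' ordered lexicographically by sequence so collapsing is deterministic.
#' Downstream read counts are always re-expanded by multiplicity, so
#' reported numbers are read counts, not unique-sequence counts.
#'
#' @param reads Tibble with a `sequence` column.
#' @return Tibble with `sequence` and `count`, counts summing to
#'   `nrow(reads)`.
#' @export
collapse_reads <- function(reads) {
  dplyr::arrange(dplyr::count(reads, .data$sequence, name = "count"),
                 .data$sequence)
}

#' Run the full preprocessing stage
#'
#' Adapter trimming, minimum-length filtering and collapsing in one call,
#' with the per-stage read accounting needed by the summary renderer. The
#' conservation invariant `n_input = n_discarded + sum(counts)` is checked
#' before returning.
#'
#' @inheritParams trim_adapter
#' @inheritParams filter_min_length
#' @return An object of class `srna_preprocess`: a list with `collapsed`
#'   (sequence/count tibble), `n_input`, `n_ge_min` (reads surviving the
#'   length filter) and `n_discarded`.
#' @export
preprocess_reads <- function(reads, adapter = TRUSEQ_3P_ADAPTER,
                             min_len = 16, min_overlap = 8, max_mm = 1) {
  trimmed <- trim_adapter(reads, adapter, min_overlap, max_mm)
  flt <- filter_min_length(trimmed, min_len)
  collapsed <- collapse_reads(flt$kept)
  n_input <- nrow(reads)
  stopifnot(n_input == flt$n_discarded + sum(collapsed$count))
  structure(list(collapsed = collapsed, n_input = n_input,
                 n_ge_min = n_input - flt$n_discarded,
                 n_discarded = flt$n_discarded, min_len = min_len),
            class = "srna_preprocess")
}

#' @export
print.srna_preprocess <- function(x, ...) {
  cat(sprintf(
    "<srna_preprocess> %d reads in; %d >= %d nt (%d discarded); %d unique sequences\n",
    x$n_input, x$n_ge_min, x$min_len, x$n_discarded, nrow(x$collapsed)))
  invisible(x)
}
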