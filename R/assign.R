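#' Enumerate all ungapped placements of read sequences
#'
#' Finds every full-length, ungapped placement of each sequence on both
#' strands of every reference with Hamming distance at most `max_mm`. `N`
#' never matches any base, in read or reference. Coordinates are 1-based
#' inclusive on the plus strand; a minus-strand placement's 5' end is its
#' `end` coordinate. Output order is deterministic: reference (input
#' order), then start, then `+` before `-`.
#'
#' Exact search (`max_mm = 0`) is accelerated by a 12-mer seed index over
#' the references (an exact full-length match pins the read's leading
#' 12-mer); mismatch tiers 1-2 use an exhaustive early-exit scan, since a
#' clean seed window is not guaranteed on 16-23-nt reads carrying two
#' mismatches. Both paths return identical results to a naive per-position
#' Hamming scan.
#'
#' @param sequences Character vector of read sequences (each >= 16 nt for
#'   meaningful use; shorter sequences are allowed and searched
#'   exhaustively).
#' @param references Reference tibble ([reference_set()]).
#' @param max_mm Maximum mismatches: 0, 1 or 2.
#' @return Tibble with columns `sequence`, `ref_id`, `strand`, `start`,
#'   `end`, `mismatches`, `five_prime`.
#' @export
enumerate_placements <- function(sequences, references, max_mm = 0) {
  stopifnot(max_mm %in% 0:2)
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  check_dna(sequences)
  hits <- cpp_enumerate_placements(sequences, references$sequence,
                                   as.integer(max_mm))
  len <- nchar(sequences)[hits$read]
  tibble::tibble(
    sequence = sequences[hits$read],
    ref_id = references$id[hits$ref],
    strand = ifelse(hits$minus == 1L, "-", "+"),
    start = hits$start,
    end = hits$start + len - 1L,
    mismatches = hits$mismatches,
    five_prime = ifelse(hits$minus == 1L, hits$start + len - 1L,
                        hits$start)
  )
}

#' Hierarchically assign collapsed reads to host and viral references
#'
#' The assignment cascade of a host-first small RNA-Seq analysis: at each
#' mismatch tier (in order), reads with any placement on the host reference
#' set are assigned `human` (with a `human_mirna` sub-flag when any
#' placement lies on a pre-miRNA reference, regardless of genome
#' placements); only the reads still unassigned are then tested against
#' each viral species independently. A read matching two or more viral
#' species at the same tier is counted once per species and flagged
#' cross-species ambiguous. Reads surviving every tier are `unknown`.
#' Host priority is absolute: a read matching host and virus is never
#' counted viral.
#'
#' @param collapsed Tibble with `sequence` and `count`
#'   ([collapse_reads()]).
#' @param references Reference tibble holding the host set (species
#'   `"host"`, roles genome/transcriptome/pre_mirna) and one or more viral
#'   species.
#' @param tiers Strictly increasing mismatch schedule from \{0,1,2\};
#'   the default `0` matches an analysis run at zero mismatches.
#' @return An `srna_assignment` object: a list with
#'   \describe{
#'     \item{records}{tibble: `sequence`, `count`, `category` (`human`,
#'       `virus:<species>` — comma-joined when cross-species — or
#'       `unknown`), `human_mirna`, `cross_species`, `tier`,
#'       `n_placements`, canonical placement columns (`canonical_ref`,
#'       `canonical_strand`, `canonical_five_prime`) and `group` (the
#'       equivalence-group id, one per read sequence).}
#'     \item{placements}{long tibble of all placements at the assigned
#'       tier on the assigned species, keyed by `sequence`, with `count`
#'       and `group` joined in.}
#'   }
#' @export
assign_reads <- function(collapsed, references, tiers = 0) {
  stopifnot(is.data.frame(collapsed), all(tiers %in% 0:2),
            !is.unsorted(tiers, strictly = TRUE))
  host <- dplyr::filter(references, .data$species == "host")
  viral_species <- setdiff(unique(references$species), "host")

  n <- nrow(collapsed)
  records <- tibble::tibble(
    sequence = collapsed$sequence, count = collapsed$count,
    category = NA_character_, human_mirna = FALSE, cross_species = FALSE,
    tier = NA_integer_, n_placements = 0L)
  placements <- list()
  unassigned <- rep(TRUE, n)

  for (t in tiers) {
    if (!any(unassigned)) break
    seqs <- records$sequence[unassigned]

    if (nrow(host) > 0) {
      ph <- enumerate_placements(seqs, host, t)
      if (nrow(ph) > 0) {
        hit_seqs <- unique(ph$sequence)
        idx <- which(records$sequence %in% hit_seqs)
        records$category[idx] <- "human"
        records$tier[idx] <- t
        mirna_refs <- host$id[host$role == "pre_mirna"]
        mirna_seqs <- unique(ph$sequence[ph$ref_id %in% mirna_refs])
        records$human_mirna[records$sequence %in% mirna_seqs] <- TRUE
        placements[[length(placements) + 1L]] <- ph
        unassigned[idx] <- FALSE
        seqs <- records$sequence[unassigned]
      }
    }

    if (length(seqs) > 0 && length(viral_species) > 0) {
      sp_hits <- list()
      for (sp in viral_species) {
        refs_sp <- dplyr::filter(references, .data$species == sp)
        pv <- enumerate_placements(seqs, refs_sp, t)
        if (nrow(pv) > 0) sp_hits[[sp]] <- pv
      }
      if (length(sp_hits) > 0) {
        seq_species <- lapply(sp_hits, function(p) unique(p$sequence))
        all_hit <- unique(unlist(seq_species))
        for (s in all_hit) {
          sps <- names(seq_species)[vapply(seq_species, function(v)
            s %in% v, logical(1))]
          i <- which(records$sequence == s)
          records$category[i] <- paste0("virus:",
                                        paste(sps, collapse = ","))
          records$cross_species[i] <- length(sps) > 1
          records$tier[i] <- t
        }
        placements <- c(placements, unname(sp_hits))
        unassigned[records$sequence %in% all_hit] <- FALSE
      }
    }
  }

  records$category[is.na(records$category)] <- "unknown"
  records$group <- seq_len(n)

  pl <- if (length(placements)) dplyr::bind_rows(placements) else
    tibble::tibble(sequence = character(), ref_id = character(),
                   strand = character(), start = integer(),
                   end = integer(), mismatches = integer(),
                   five_prime = integer())
  ref_order <- references$id
  pl <- dplyr::arrange(pl, match(.data$sequence, records$sequence),
                       match(.data$ref_id, ref_order), .data$start,
                       .data$strand)
  pl <- dplyr::left_join(
    pl, records[, c("sequence", "count", "group")], by = "sequence")

  # canonical representative per equivalence group: lowest reference (input
  # order), then lowest five_prime, '+' preferred over '-'
  if (nrow(pl) > 0) {
    canon <- pl |>
      dplyr::group_by(.data$sequence) |>
      dplyr::arrange(match(.data$ref_id, ref_order), .data$five_prime,
                     .data$strand, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup()
    np <- dplyr::count(pl, .data$sequence, name = "n_placements")
    records <- records |>
      dplyr::select(-"n_placements") |>
      dplyr::left_join(np, by = "sequence") |>
      dplyr::left_join(
        dplyr::select(canon, "sequence", canonical_ref = "ref_id",
                      canonical_strand = "strand",
                      canonical_five_prime = "five_prime"),
        by = "sequence") |>
      dplyr::mutate(n_placements = dplyr::coalesce(.data$n_placements, 0L))
  } else {
    records$canonical_ref <- NA_character_
    records$canonical_strand <- NA_character_
    records$canonical_five_prime <- NA_integer_
  }

  structure(list(records = records, placements = pl,
                 references = references[, c("id", "species", "role",
                                             "length")],
                 tiers = tiers),
            class = "srna_assignment")
}

#' @export
print.srna_assignment <- function(x, ...) {
  counts <- tapply(x$records$count, x$records$category, sum)
  cat(sprintf("<srna_assignment> %d sequences, %d reads; tiers [%s]\n",
              nrow(x$records), sum(x$records$count),
              paste(x$tiers, collapse = ",")))
  for (nm in names(counts)) cat(sprintf("  %-14s %d\n", nm, counts[[nm]]))
  invisible(x)
}

#' @describeIn assign_reads `tidy()` returns the per-sequence record
#'   tibble.
#' @param x An `srna_assignment`.
#' @param ... Unused.
#' @export
tidy.srna_assignment <- function(x, ...) x$records

#' @describeIn assign_reads `glance()` returns a one-row read-count
#'   summary.
#' @export
glance.srna_assignment <- function(x, ...) {
  r <- x$records
  tibble::tibble(
    n_sequences = nrow(r), n_reads = sum(r$count),
    human = sum(r$count[r$category == "human"]),
    human_mirna = sum(r$count[r$human_mirna]),
    viral = sum(r$count[startsWith(r$category, "virus:")]),
    unknown = sum(r$count[r$category == "unknown"]),
    cross_species = sum(r$count[r$cross_species]))
}

#' Group the placements of each read into equivalence classes
#'
#' All placements of one read sequence form one equivalence group (the
#' ambiguity class created by e.g. the two copies and internal palindrome of
#' an inverted terminal repeat). The canonical representative is the
#' placement with the lowest reference (in `ref_order`), then the lowest 5'
#' coordinate, with `+` preferred over `-`.
#'
#' @param placements Placement tibble ([enumerate_placements()]), possibly
#'   covering several sequences.
#' @param ref_order Character vector fixing reference precedence; defaults
#'   to order of appearance.
#' @return The placements with `group` (integer id per sequence),
#'   `group_size` and `canonical` (logical) columns added.
#' @export
equivalence_classes <- function(placements, ref_order = NULL) {
  if (is.null(ref_order)) ref_order <- unique(placements$ref_id)
  placements |>
    dplyr::mutate(group = match(.data$sequence,
                                unique(.data$sequence))) |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(match(.data$ref_id, ref_order), .data$five_prime,
                   .data$strand, .by_group = TRUE) |>
    dplyr::mutate(group_size = dplyr::n(),
                  canonical = dplyr::row_number() == 1L) |>
    dplyr::ungroup()
}

#' Summarise an assignment in the study's accounting convention
#'
#' One row per sample: total reads, reads passing the length filter, human
#' reads (genome + transcriptome + miRNA), the human-miRNA subset, one
#' column of read counts per viral species (a cross-species read counts in
#' every species it matches and is additionally reported under
#' `cross_species`), and unknown reads. Counts are raw read counts
#' (multiplicities re-expanded).
#'
#' @param assignment An `srna_assignment`.
#' @param n_total Total reads sequenced (before length filtering).
#' @param n_ge16 Reads at/above the minimum length; must equal the
#'   assignment's total read count (the categories partition them).
#' @param sample Sample label.
#' @return One-row tibble suitable for [render_summary()].
#' @export
assignment_summary <- function(assignment, n_total, n_ge16,
                               sample = "sample") {
  r <- assignment$records
  if (sum(r$count) != n_ge16) {
    stop("categories do not partition the length-filtered reads: ",
         sum(r$count), " assigned vs n_ge16 = ", n_ge16, call. = FALSE)
  }
  viral_species <- setdiff(unique(assignment$references$species), "host")
  out <- tibble::tibble(
    sample = sample, total_reads = n_total, n_ge16 = n_ge16,
    human = sum(r$count[r$category == "human"]),
    human_mirna = sum(r$count[r$human_mirna]))
  for (sp in viral_species) {
    in_sp <- startsWith(r$category, "virus:") &
      vapply(strsplit(sub("^virus:", "", r$category), ","),
             function(v) sp %in% v, logical(1))
    out[[sp]] <- sum(r$count[in_sp])
  }
  out$unknown <- sum(r$count[r$category == "unknown"])
  out$cross_species <- sum(r$count[r$cross_species])
  out
}
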